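---
title: "Methods: MHC compatibility, relatedness and inbreeding in mare-foal pairs"
author: "placmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MHC compatibility, relatedness and inbreeding in mare-foal pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placmatch)
```

## The scientific question

Retained fetal membranes (RFM) — failure of the allantochorion to detach
within about three hours of foaling — is common in draft mares. One
hypothesis holds that parturition resembles a graft-rejection reaction: if
the foal's major histocompatibility complex (MHC) antigens are too similar
to the mare's, the inflammatory cascade that frees the fetal membranes may
be blunted, and the membranes retained.

`placmatch` implements the full analysis pipeline for testing this
hypothesis with MHC-linked microsatellites: nine loci inside the MHC region
of equine chromosome 20 (three in the class I region, six in class II) are
typed in each mare and foal, mare-foal pairs are classified by allele
containment into compatibility categories, and the association between
category and RFM is tested by logistic regression, alongside a relatedness
analysis, pedigree inbreeding coefficients, and locus-level quality
control.

## Compatibility classification

At one locus, let $M$ and $F$ be the sets of distinct alleles of the mare
and foal. The per-locus containment flags are $F \subseteq M$ (the mare's
immune system sees no foreign allele) and $M \subseteq F$ (the foal's
sees none). Containment deliberately uses sets, not multisets: a mare
$\{a,b\}$ contains a foal $\{a,a\}$, because recognition is about the
presence of a foreign antigen, not about dosage.

Within an MHC class the flags aggregate to one of four mutually exclusive
categories:

* **MFC** — both containments hold at every locus of the class;
* **MC** — foal-in-mare holds at every locus, but not MFC;
* **FC** — mare-in-foal holds at every locus, but not MFC;
* **NC** — otherwise (at least one locus breaks each containment).

A single discordant locus therefore pushes the pair to NC for that class,
which makes NC the dominant category whenever allelic diversity is
appreciable.

Missing genotypes are not discussed in the source protocol, so the
classifier exposes a policy: the default classifies on the testable loci
and records how many were used; a strict mode refuses to classify a pair
with any untestable locus. Null alleles are invisible here — a null
heterozygote looks like a homozygote and is classified at face value. The
QC module's null-allele estimates are the mitigation, flagging loci where
this is likely.

## The logistic model

RFM (0/1) is modelled by binomial maximum likelihood with an intercept and,
for each MHC class, two indicators: "MC + FC" (one-way compatibility,
collapsed) and "MFC", with NC as the referent — five parameters, matching a
residual df of 38 at 43 pairs. Reported per term: log-odds estimate, Wald
SE, odds ratio, symmetric Wald 95% CI on the log scale, and p-value.
Model summary: null and residual deviance, $AIC = D + 2k$,
$BIC = D + k\ln n$, likelihood-ratio $\chi^2$, and four pseudo-$R^2$
measures — McFadden $1 - \ell_1/\ell_0$, Cox–Snell
$1 - e^{-\chi^2_{LR}/n}$, Nagelkerke (Cox–Snell over its attainable
maximum $1 - e^{2\ell_0/n}$), and Tjur's coefficient of discrimination
(difference of mean fitted probability between outcome groups).

Three degenerate regimes are handled explicitly, because they are routine
at $n = 43$ with sparse categories:

* an **unobserved category** (an all-zero indicator) is inestimable; the
  term is kept in the output with `NA` estimates;
* an **aliased term** (e.g. both indicators of a class summing to the
  intercept because no pair of that class is NC) is dropped the same way by
  `fit_rfm_logistic()`; the lower-level `fit_logistic()` treats it as an
  error unless told otherwise;
* **quasi-separation** (a pure small cell driving one estimate to
  $\pm\infty$) is flagged per term (`separated`) with a warning — the fit
  is still reported, with the enormous SE and an all-covering CI speaking
  for themselves — while **complete separation** (the design predicts the
  outcome perfectly) is an error, since no maximum-likelihood fit exists.

## Relatedness

MHC similarity on a continuous scale is measured by the Queller–Goodnight
moment estimator. For genotypes $x = (a,b)$, $y = (c,d)$ and reference
allele frequencies $p$, with $S_{uv}$ the allele-identity indicator,

$$N_{x \to y} = \tfrac12 (S_{ac} + S_{ad} + S_{bc} + S_{bd}) - p_a - p_b,
\qquad D_{x \to y} = 1 + S_{ab} - p_a - p_b,$$

and the multilocus estimate pools numerators and denominators over loci and
both directions:
$r_{xy} = (\sum N_{x \to y} + \sum N_{y \to x}) /
          (\sum D_{x \to y} + \sum D_{y \to x})$.
This symmetrised ratio-of-sums is the standard multilocus weighting; it
gives $r = 1$ for identical multilocus genotypes by construction and is
symmetric in its arguments. Reference frequencies default to the pooled
full sample (mares and foals), the common practice when no external
reference panel exists; any subset can be supplied instead for sensitivity
analysis.

One behaviour of this estimator matters for interpretation and for
testing. The ratio of sums is asymptotically unbiased as informative loci
accumulate, but it is *not* unbiased locus by locus: exact enumeration
shows that at a single locus with four common alleles the expectation for a
true parent-offspring pair is about 0.43, not 0.5, and the gap shrinks
only slowly with allele count. Within the MHC the nine loci are in such
strong linkage disequilibrium that they behave almost as one locus, so the
multilocus averaging that normally removes this small-sample ratio bias is
defeated: under the package's default tightly linked generator the measured
parent-offspring mean is about 0.48. For this reason the estimator's
unbiasedness oracle (mean $r \approx 0.5$ over simulated parent-offspring
pairs, mean $\approx 0$ over unrelated pairs) is run under
`linkage_equilibrium_pool()` — a large pool with independently drawn
per-locus alleles and free recombination — where the asymptotic argument
applies and the measured mean is 0.50 within Monte-Carlo error.

Group comparison uses the two-sided pooled-variance t-test, with a
Shapiro–Wilk normality check recorded in the report to document that
choice; inbreeding coefficients, which are far from normal, are compared
with the Mann–Whitney U test instead (U reported as $\min(U_a, U_b)$;
exact enumeration for small tie-free samples, otherwise the normal
approximation with tie and continuity corrections).

## Pedigree inbreeding

$F$ of an individual is the Malécot kinship of its parents, computed by the
classic recursion ($f(i,i) = \tfrac12(1+f(s_i,d_i))$; for distinct
individuals, recurse through the parents of the one further from the
founders), memoised over the pedigree, with unknown parents contributing 0
— the convention for pedigrees of variable depth. The recursion is
validated against textbook closed forms (full-sib offspring 0.25, half-sib
offspring 0.125) and against a gene-dropping simulation on a looped
pedigree.

## Locus quality control

* **Hardy–Weinberg**: the conditional exact probability test — the p-value
  is the total probability, given the observed allele counts, of all
  genotype arrays no more probable than the observed one, the same test
  GENEPOP applies by default. Small arrays are enumerated exhaustively;
  larger ones are evaluated by Monte Carlo. The Monte-Carlo sampler pairs
  the observed $2n$ gene copies at random, which draws genotype arrays
  i.i.d. from the exact conditional null — a simplification over
  Markov-chain samplers (no dememorisation or batching is needed, and the
  add-one p-value estimate $(\#\{p_{\mathrm{arr}} \le p_{\mathrm{obs}}\}+1)/(B+1)$
  is valid as drawn). Enumeration and Monte Carlo agree within binomial
  error wherever both run.
* **Genotypic LD**: permutation exact test on the two-locus genotype
  contingency table using the log-likelihood-ratio $G$ statistic,
  permuting one locus's genotypes among individuals (both margins
  preserved), add-one p-values.
* **Null alleles**: three estimators of the frequency of a non-amplifying
  allele — Chakraborty $(H_e - H_o)/(H_e + H_o)$ and Brookfield-1
  $(H_e - H_o)/(1 + H_e)$ in closed form, and the default iterative
  estimator in the style of CERVUS: an EM that splits apparent homozygotes
  into true homozygotes and visible/null heterozygotes under
  Hardy–Weinberg, with the unobserved null/null class imputed (it presents
  as missing data, not as a genotype — omitting this imputation biases the
  fixed point to $r/(1+r)$). Iteration stops when the estimate moves by
  less than $10^{-10}$. Negative closed-form estimates (heterozygote
  excess) are returned as-is. $H_e$ is Nei's unbiased expected
  heterozygosity.

## The synthetic-data generator

No genotypes ship with the package; every pipeline stage is exercised on
data from `simulate_study()`, whose defaults emulate the study design:

* **43 mare-foal pairs** (with stallions simulated explicitly so family
  trios can be checked), RFM drawn from a logistic model whose default
  intercept is $\mathrm{logit}(14/43)$ with all compatibility effects 0 —
  the null finding — giving ~33% prevalence;
* **9 linked loci** with the panel's amplicon size ranges; founder
  chromosomes are drawn from a finite pool of 16 multilocus haplotypes,
  which induces the strong pairwise LD of a conserved MHC region without
  any pairwise-LD parameterisation. Sixteen haplotypes (not fewer) are
  used so each locus segregates the allele counts microsatellites of these
  size ranges actually show; with markedly fewer haplotypes the
  relatedness estimator's parent-offspring expectation drops visibly below
  0.5 (see above), which would misrepresent the population being emulated.
  Haplotype frequencies decay geometrically (common haplotypes plus a rare
  tail);
* **recombination** 0.01 per adjacent-locus gap — tight linkage across a
  few megabases of MHC;
* **null alleles** at 0.14 (COR110) and 0.15 (TKY3324), the two loci
  flagged in the source data, implemented as heritable observation
  masking: the null copy travels through meiosis, a visible/null genotype
  is *observed* as a homozygote, and null/null is observed as missing —
  the mechanism CERVUS-style estimators assume, never missing-at-random;
* **pedigrees**: outbred founders by default; a `loops(target_F)` scenario
  makes a fraction $target_F/0.125$ of mare-stallion pairs paternal half
  sibs, so foal inbreeding averages `target_F`. The loops shape the
  pedigree only — founder genotypes are still drawn independently from the
  pool, so genotypic and pedigree relatedness are decoupled in that
  scenario.

Determinism: one seed drives everything, with per-component sub-streams
derived arithmetically so that, e.g., adding pedigree loops does not
perturb the genotype draws. The same seed reproduces a study byte for
byte.

What the generator does **not** emulate: microsatellite mutation,
selection on MHC, population structure beyond the haplotype pool,
calibrated compatibility-category proportions (the observed category
mix follows from the pool, and is NC-heavier than the source data's), and
genotype-pedigree coupling in the loops scenario. Passing tests therefore
demonstrate correctness of the algorithms under a faithful null model of
the design — not that the generator reproduces every marginal of the real
population.

## Numerical and design choices

* Allele labels are raw fragment lengths in bp; compatibility and
  relatedness need only label identity, so no repeat-unit binning is done.
  GenePop export recodes to 3-digit codes by ascending length per locus
  (lengths exceed three digits), with a sidecar code-to-bp map making the
  round trip lossless; `000` is the missing code at the format boundary
  only — internally missing is `NA`, never 0.
* HWE enumeration switches to Monte Carlo past a feasibility screen (allele
  count versus sample size) with a hard node budget as backstop; stochastic
  p-values take an explicit seed everywhere.
* The exact test's discreteness makes it conservative: its type-I error at
  $\alpha = 0.05$ is below nominal, and the test suite asserts
  one-sidedly (rate $\le$ nominal within Monte-Carlo error).
* Tests are two-sided at $\alpha = 0.05$ throughout.
* Problem sizes in the test-suite oracles — 1,000 pairs for the
  relatedness means, 10,000 individuals for null-allele recovery, 5,000
  pairs for logistic parameter recovery, 1,000 replicates for type-I error
  — were chosen so each Monte-Carlo standard error is small against the
  effect being measured.

## Known limitations

* Compatibility from microsatellites is an indirect proxy for MHC antigen
  identity; haplotype phasing or assignment to named serological
  haplotypes is out of scope.
* The null-allele model allows one null allele per locus; other
  genotyping-error modes (allelic dropout gradients, stutter
  miscalls) are not modelled.
* Pedigree inbreeding is only as deep as the supplied pedigree; truncated
  ancestries underestimate F.
* At 43 pairs the logistic model is underpowered for odds ratios of the
  size reported in comparable studies (the test suite demonstrates < 50%
  power for an OR of 2.65 on a ~16% exposure), so a non-significant result
  at this scale is weak evidence of absence.
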