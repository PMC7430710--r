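#' Default founder haplotype pool
#'
#' A small pool of multilocus haplotypes spanning the nine panel loci.
#' Drawing founder chromosomes from a finite pool induces the strong
#' pairwise linkage disequilibrium characteristic of a conserved MHC region
#' without any pairwise LD parameterisation. Alleles are placed on a 2-bp
#' lattice inside each locus's amplicon size range, with neighbouring
#' haplotypes sharing alleles so that every locus segregates several alleles
#' at unequal frequencies.
#'
#' The pool size (16) and per-locus allele counts were fixed so the
#' generator reproduces the allelic diversity microsatellites of this size
#' range show in practice; with markedly fewer haplotypes (and so <= 4-6
#' alleles per locus) the Queller-Goodnight ratio estimator's finite-sample
#' expectation for true parent-offspring pairs drops well below its
#' asymptotic value of 0.5, which no longer matches the study population
#' being emulated.
#'
#' @param panel A [locus_panel()].
#' @param n_haplotypes Pool size.
#' @return List with `haplotypes` (matrix n_haplotypes x loci, allele bp)
#'   and `freq` (haplotype frequencies summing to 1).
#' @export
default_haplotype_pool <- function(panel = default_mhc_panel(),
                                   n_haplotypes = 16) {
  loci <- panel$name
  hap <- matrix(0L, n_haplotypes, length(loci),
                dimnames = list(NULL, loci))
  strides <- c(1L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L)
  for (l in seq_along(loci)) {
    k <- (panel$size_max[l] - panel$size_min[l]) %/% 2L + 1L
    # stride must be coprime to the lattice size or alleles collapse
    cand <- strides[1L + ((l - 1L):(l + 7L)) %% length(strides)]
    s <- cand[which(vapply(cand, function(x) gcd2(x, k) == 1L, TRUE))[1]]
    for (h in seq_len(n_haplotypes)) {
      hap[h, l] <- panel$size_min[l] + 2L * ((h * s + l) %% k)
    }
  }
  # mildly skewed frequencies: common haplotypes plus a tail of rare ones
  freq <- 0.87^seq_len(n_haplotypes)
  freq <- freq / sum(freq)
  list(haplotypes = hap, freq = freq)
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

#' Linkage-equilibrium validation pool
#'
#' A large haplotype pool whose alleles are drawn independently per locus
#' from the marginal allele frequencies of a base pool, so founders built
#' from it are in approximate linkage equilibrium across loci. This is the
#' right background for validating statistical properties whose derivations
#' assume (quasi-)independent loci — in particular the asymptotic
#' unbiasedness of the Queller-Goodnight ratio estimator, whose multilocus
#' averaging is defeated when tightly linked loci behave as a single locus.
#'
#' @param panel A [locus_panel()].
#' @param base_pool Pool supplying the per-locus allele frequencies
#'   (default [default_haplotype_pool()]).
#' @param n_haplotypes Pool size (large, so haplotypes are near-unique).
#' @param seed Seed for the independent per-locus draws.
#' @return A pool list as in [default_haplotype_pool()], equifrequent.
#' @export
linkage_equilibrium_pool <- function(panel = default_mhc_panel(),
                                     base_pool = default_haplotype_pool(panel),
                                     n_haplotypes = 500, seed = 1L) {
  marg <- pool_allele_frequencies(base_pool)
  set.seed(seed)
  hap <- sapply(panel$name, function(loc) {
    alleles <- as.integer(names(marg[[loc]]$freq))
    sample(alleles, n_haplotypes, replace = TRUE, prob = marg[[loc]]$freq)
  })
  colnames(hap) <- panel$name
  list(haplotypes = hap, freq = rep(1 / n_haplotypes, n_haplotypes))
}

#' Configuration for a synthetic study
#'
#' Bundles every knob of the generator with defaults matching the study
#' design it emulates: 43 mare-foal pairs genotyped at the nine-locus MHC
#' panel, founders drawn from a six-haplotype pool, tight linkage
#' (recombination 0.01 per adjacent-locus gap), null alleles at 0.14 for
#' COR110 and 0.15 for TKY3324, and a logistic RFM model whose intercept
#' reproduces the observed 14/43 prevalence with no compatibility effect.
#'
#' @param n_pairs Number of mare-foal pairs.
#' @param panel A [locus_panel()].
#' @param haplotype_pool List with `haplotypes` and `freq` (see
#'   [default_haplotype_pool()]).
#' @param recombination_rates Numeric vector, one probability in \[0, 0.5\]
#'   per adjacent-locus gap (length = loci - 1).
#' @param null_allele_freq Named numeric vector of per-locus null-allele
#'   frequencies in \[0, 1).
#' @param rfm_model List of log-odds coefficients: `beta0`, `beta_mcfc_I`,
#'   `beta_mfc_I`, `beta_mcfc_II`, `beta_mfc_II` (indicator effects of the
#'   foal-dam compatibility category per MHC class, NC as referent).
#' @param pedigree_scenario `"outbred"` (all founders unrelated) or
#'   `list(type = "loops", target_F = ...)`, which makes a fraction of
#'   mare-stallion pairs paternal half sibs so foal inbreeding averages
#'   `target_F`.
#' @param seed Integer seed; the same seed yields an identical study.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_pairs = 43,
                              panel = default_mhc_panel(),
                              haplotype_pool = default_haplotype_pool(panel),
                              recombination_rates =
                                rep(0.01, nrow(panel) - 1),
                              null_allele_freq = c(COR110 = 0.14,
                                                   TKY3324 = 0.15),
                              rfm_model = list(beta0 = stats::qlogis(14 / 43),
                                               beta_mcfc_I = 0,
                                               beta_mfc_I = 0,
                                               beta_mcfc_II = 0,
                                               beta_mfc_II = 0),
                              pedigree_scenario = "outbred",
                              seed = 1L) {
  if (is.null(haplotype_pool$haplotypes) ||
      nrow(haplotype_pool$haplotypes) == 0) {
    stop("empty haplotype pool", call. = FALSE)
  }
  if (abs(sum(haplotype_pool$freq) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  }
  if (length(recombination_rates) != nrow(panel) - 1 ||
      any(recombination_rates < 0 | recombination_rates > 0.5)) {
    stop("recombination_rates: one value in [0, 0.5] per locus gap",
         call. = FALSE)
  }
  nulls <- stats::setNames(rep(0, nrow(panel)), panel$name)
  if (length(null_allele_freq)) {
    bad <- setdiff(names(null_allele_freq), panel$name)
    if (length(bad)) stop("null_allele_freq for unknown loci: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(null_allele_freq < 0 | null_allele_freq >= 1)) {
      stop("null_allele_freq must lie in [0, 1)", call. = FALSE)
    }
    nulls[names(null_allele_freq)] <- null_allele_freq
  }
  structure(list(n_pairs = as.integer(n_pairs), panel = panel,
                 haplotype_pool = haplotype_pool,
                 recombination_rates = recombination_rates,
                 null_allele_freq = nulls, rfm_model = rfm_model,
                 pedigree_scenario = pedigree_scenario,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-component sub-seed so adding a component leaves the
# draws of the others untouched
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

draw_gamete <- function(hap_pair, null_pair, rates) {
  n_loci <- length(hap_pair[[1]])
  cur <- sample.int(2, 1)
  allele <- integer(n_loci)
  nul <- logical(n_loci)
  for (l in seq_len(n_loci)) {
    if (l > 1 && stats::runif(1) < rates[l - 1]) cur <- 3L - cur
    allele[l] <- hap_pair[[cur]][l]
    nul[l] <- null_pair[[cur]][l]
  }
  list(allele = allele, null = nul)
}

#' Simulate a study-like dataset
#'
#' Generates mare/stallion/foal trios at the panel loci. Founders receive
#' two haplotypes drawn from the pool; foal gametes are formed by
#' recombining each parent's haplotypes at the configured per-gap rates, so
#' every foal allele is Mendelian. Null alleles are attached to individual
#' gene copies at the configured per-locus frequency and are inherited; a
#' visible/null heterozygote is observed as a homozygote and a null/null
#' genotype as missing — observation masking, never missing-at-random. RFM
#' is drawn from the logistic model applied to the foal-dam true (unmasked)
#' compatibility categories.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_study` list: `genotypes` (a [genotype_table()] of
#'   observed calls for all mares, stallions and foals), `pairs`
#'   (`mare_id`, `foal_id`, `rfm`), `pedigree` (a [pedigree()]), and
#'   `truth` (per-pair true compatibility categories and RFM probabilities,
#'   per-individual true allele and null-flag matrices, and the config).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_pairs
  panel <- config$panel
  loci <- panel$name
  n_loci <- length(loci)
  pool <- config$haplotype_pool
  nulls <- config$null_allele_freq

  ids <- list(mare = sprintf("M%03d", seq_len(n)),
              stallion = sprintf("S%03d", seq_len(n)),
              foal = sprintf("F%03d", seq_len(n)))

  # founders: two pool haplotypes each, null flags attached per gene copy
  set.seed(sub_seed(config$seed, 1))
  founder <- function() {
    idx <- sample.int(nrow(pool$haplotypes), 2, replace = TRUE,
                      prob = pool$freq)
    haps <- lapply(idx, function(i) pool$haplotypes[i, ])
    nls <- lapply(1:2, function(i) stats::runif(n_loci) < nulls)
    list(hap = haps, null = nls)
  }
  mares <- replicate(n, founder(), simplify = FALSE)
  stallions <- replicate(n, founder(), simplify = FALSE)

  set.seed(sub_seed(config$seed, 2))
  foals <- lapply(seq_len(n), function(i) {
    gm <- draw_gamete(mares[[i]]$hap, mares[[i]]$null,
                      config$recombination_rates)
    gs <- draw_gamete(stallions[[i]]$hap, stallions[[i]]$null,
                      config$recombination_rates)
    list(hap = list(gm$allele, gs$allele), null = list(gm$null, gs$null))
  })

  everyone <- c(mares, stallions, foals)
  all_ids <- c(ids$mare, ids$stallion, ids$foal)

  true1 <- t(vapply(everyone, function(x) x$hap[[1]], integer(n_loci)))
  true2 <- t(vapply(everyone, function(x) x$hap[[2]], integer(n_loci)))
  null1 <- t(vapply(everyone, function(x) x$null[[1]], logical(n_loci)))
  null2 <- t(vapply(everyone, function(x) x$null[[2]], logical(n_loci)))
  dimnames(true1) <- dimnames(true2) <- dimnames(null1) <-
    dimnames(null2) <- list(all_ids, loci)

  # observed calls: null copies are invisible
  obs1 <- true1; obs2 <- true2
  obs1[null1 & null2] <- NA_integer_; obs2[null1 & null2] <- NA_integer_
  one_null <- null1 & !null2
  obs1[one_null] <- true2[one_null]          # appears homozygous
  two_null <- !null1 & null2
  obs2[two_null] <- true1[two_null]
  genotypes <- genotype_table(all_ids, obs1, obs2, panel)

  # true foal-dam compatibility categories from unmasked alleles
  cat_of <- function(i, class_loci) {
    m <- rbind(true1[ids$mare[i], class_loci], true2[ids$mare[i], class_loci])
    f <- rbind(true1[ids$foal[i], class_loci], true2[ids$foal[i], class_loci])
    fim <- mif <- logical(length(class_loci))
    for (l in seq_along(class_loci)) {
      ms <- unique(m[, l]); fs <- unique(f[, l])
      fim[l] <- all(fs %in% ms); mif[l] <- all(ms %in% fs)
    }
    if (all(fim) && all(mif)) "MFC" else if (all(fim)) "MC"
    else if (all(mif)) "FC" else "NC"
  }
  loci_I <- intersect(loci, panel_loci(panel, "I"))
  loci_II <- intersect(loci, panel_loci(panel, "II"))
  cat_I <- vapply(seq_len(n), cat_of, character(1), class_loci = loci_I)
  cat_II <- vapply(seq_len(n), cat_of, character(1), class_loci = loci_II)

  set.seed(sub_seed(config$seed, 3))
  b <- config$rfm_model
  lp <- b$beta0 +
    b$beta_mcfc_I * (cat_I %in% c("MC", "FC")) +
    b$beta_mfc_I * (cat_I == "MFC") +
    b$beta_mcfc_II * (cat_II %in% c("MC", "FC")) +
    b$beta_mfc_II * (cat_II == "MFC")
  p_rfm <- stats::plogis(lp)
  rfm <- stats::rbinom(n, 1, p_rfm) == 1

  # pedigree: foals always have recorded parents; the loops scenario makes
  # a fraction of mare-stallion pairs paternal half sibs (foal F = 0.125)
  set.seed(sub_seed(config$seed, 4))
  ped_id <- c(ids$foal)
  ped_sire <- c(ids$stallion)
  ped_dam <- c(ids$mare)
  extra_id <- extra_sire <- extra_dam <- character(0)
  founder_sire <- stats::setNames(rep(NA_character_, 2 * n),
                                  c(ids$mare, ids$stallion))
  sc <- config$pedigree_scenario
  if (is.list(sc) && identical(sc$type, "loops")) {
    if (sc$target_F > 0.125) {
      stop("loops scenario supports target_F <= 0.125", call. = FALSE)
    }
    q <- sc$target_F / 0.125
    looped <- stats::runif(n) < q
    for (i in which(looped)) {
      g <- sprintf("G%03d", i)
      extra_id <- c(extra_id, g)
      extra_sire <- c(extra_sire, NA_character_)
      extra_dam <- c(extra_dam, NA_character_)
      founder_sire[ids$mare[i]] <- g
      founder_sire[ids$stallion[i]] <- g
    }
  } else if (!identical(sc, "outbred")) {
    stop("unknown pedigree scenario", call. = FALSE)
  }
  ped <- pedigree(
    id = c(ped_id, names(founder_sire), extra_id),
    sire = c(ped_sire, unname(founder_sire), extra_sire),
    dam = c(ped_dam, rep(NA_character_, 2 * n), extra_dam)
  )

  pairs <- data.frame(mare_id = ids$mare, foal_id = ids$foal, rfm = rfm,
                      stringsAsFactors = FALSE)
  truth <- list(
    categories = data.frame(mare_id = ids$mare, stallion_id = ids$stallion,
                            foal_id = ids$foal, cat_I = cat_I,
                            cat_II = cat_II, p_rfm = p_rfm, rfm = rfm,
                            stringsAsFactors = FALSE),
    true_allele1 = true1, true_allele2 = true2,
    null1 = null1, null2 = null2,
    config = config
  )
  structure(list(genotypes = genotypes, pairs = pairs, pedigree = ped,
                 truth = truth),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated study:", nrow(x$pairs), "mare-foal pairs,",
      length(x$genotypes$individuals), "genotyped individuals,",
      sum(x$pairs$rfm), "RFM\n")
  invisible(x)
}

#' Population allele frequencies implied by a haplotype pool
#'
#' The exact generating allele frequencies: at each locus, the frequency of
#' an allele is the total frequency of the pool haplotypes carrying it.
#' Useful as an unbiased reference for relatedness estimation on simulated
#' data.
#'
#' @param pool A haplotype pool (see [default_haplotype_pool()]).
#' @return An `allele_freq_table`.
#' @export
pool_allele_frequencies <- function(pool) {
  out <- list()
  for (loc in colnames(pool$haplotypes)) {
    freq <- tapply(pool$freq, pool$haplotypes[, loc], sum)
    out[[loc]] <- list(freq = as.numeric(freq), n_copies = Inf)
    names(out[[loc]]$freq) <- names(freq)
  }
  structure(out, class = "allele_freq_table")
}

#' Write a simulated study to disk
#'
#' Emits `genotypes.csv`, `genotypes.gen` (GenePop plus its sidecar allele
#' map), `pairs.csv`, `pedigree.csv` and `truth.json`; the genotype files
#' round-trip losslessly through [read_genotypes()].
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
emit_study_files <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir,
                                     call. = FALSE)
  paths <- c(
    genotypes_csv = file.path(dir, "genotypes.csv"),
    genepop = file.path(dir, "genotypes.gen"),
    allele_map = file.path(dir, "genotypes.gen.alleles.tsv"),
    pairs = file.path(dir, "pairs.csv"),
    pedigree = file.path(dir, "pedigree.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_genotypes_csv(study$genotypes, paths["genotypes_csv"])
  write_genepop(study$genotypes, paths["genepop"],
                allele_map = paths["allele_map"])
  utils::write.csv(study$pairs, paths["pairs"], row.names = FALSE)
  ped <- as.data.frame(study$pedigree)[, c("id", "sire", "dam")]
  utils::write.csv(ped, paths["pedigree"], row.names = FALSE, na = "")
  truth <- study$truth
  truth$config$panel <- as.data.frame(truth$config$panel)
  jsonlite::write_json(
    list(categories = truth$categories,
         config = truth$config[c("n_pairs", "recombination_rates",
                                 "null_allele_freq", "rfm_model", "seed")]),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
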