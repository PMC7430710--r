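test_that("HWE enumeration equals independent 2-allele oracle", {
  cases <- list(c(2, 1, 2), c(1, 3, 1), c(4, 1, 0), c(3, 4, 3), c(0, 5, 0),
                c(10, 2, 8))
  for (cs in cases) {
    counts <- matrix(c(cs[1], cs[2], cs[2], cs[3]), 2, 2,
                     dimnames = list(c(100, 102), c(100, 102)))
    got <- hwe_exact_test(counts, method = "enumerate")
    expect_equal(got$p, oracle_hwe_2allele(cs[1], cs[2], cs[3]),
                 tolerance = 1e-10)
  }
})

test_that("HWE enumeration handles 3-allele arrays (sums conditional
           probabilities over the full array space)", {
  # observed: 2x aa, 1x ab, 1x bc, 1x cc
  counts <- matrix(0L, 3, 3, dimnames = list(1:3, 1:3))
  counts[1, 1] <- 2; counts[1, 2] <- counts[2, 1] <- 1
  counts[2, 3] <- counts[3, 2] <- 1; counts[3, 3] <- 1
  got <- hwe_exact_test(counts, method = "enumerate")
  expect_true(got$p > 0 && got$p <= 1)
  # total conditional probability over all arrays must be 1: check by
  # enumerating with an observed array of maximal probability
  total <- 0
  st <- placmatch:::counts_to_stats(counts)
  placmatch:::enumerate_arrays(st$allele_counts, function(arr) {
    total <<- total +
      exp(placmatch:::log_array_prob(arr, st$allele_counts, st$n))
  })
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("Monte-Carlo HWE p agrees with enumeration within 3 binomial SE", {
  counts <- matrix(c(3, 4, 4, 3), 2, 2, dimnames = list(1:2, 1:2))
  exact <- hwe_exact_test(counts, method = "enumerate")$p
  mc <- hwe_exact_test(counts, method = "monte_carlo", mc_reps = 20000,
                       seed = 4)
  expect_lt(abs(mc$p - exact), 3 * sqrt(exact * (1 - exact) / 20000) + 1e-4)

  counts3 <- matrix(0L, 3, 3, dimnames = list(1:3, 1:3))
  counts3[1, 1] <- 3; counts3[2, 2] <- 2; counts3[1, 3] <- counts3[3, 1] <- 2
  counts3[2, 3] <- counts3[3, 2] <- 1
  exact3 <- hwe_exact_test(counts3, method = "enumerate")$p
  mc3 <- hwe_exact_test(counts3, method = "monte_carlo", mc_reps = 20000,
                        seed = 5)
  expect_lt(abs(mc3$p - exact3), 3 * sqrt(exact3 * (1 - exact3) / 20000) + 1e-4)
})

test_that("monomorphic locus is untestable with p = 1 and invalid
           parameters are rejected", {
  counts <- matrix(7L, 1, 1, dimnames = list(100, 100))
  res <- hwe_exact_test(counts)
  expect_equal(res$p, 1)
  expect_false(res$testable)
  counts2 <- matrix(c(3, 1, 1, 2), 2, 2, dimnames = list(1:2, 1:2))
  expect_error(hwe_exact_test(counts2, mc_reps = 0), "positive")
})

test_that("duplicated locus shows strong genotypic LD; monomorphic locus
           is untestable", {
  panel <- toy_panel(2)
  set.seed(31)
  g <- replicate(20, sort(sample(c(100L, 102L, 104L), 2, replace = TRUE)),
                 simplify = FALSE)
  tab <- make_table(stats::setNames(
    lapply(seq_len(20), function(i) list(g[[i]], g[[i]])),
    paste0("i", 1:20)), panel)
  res <- ld_genotypic_test(tab, "L1", "L2", n_perm = 999, seed = 7)
  expect_lt(res$p, 0.05)

  tab2 <- make_table(stats::setNames(
    lapply(seq_len(10), function(i) list(c(100L, 100L), g[[i]])),
    paste0("j", 1:10)), panel)
  res2 <- ld_genotypic_test(tab2, "L1", "L2", n_perm = 99)
  expect_equal(res2$p, 1)
  expect_false(res2$testable)
})

test_that("LD permutation test holds its type-I error on independent loci", {
  panel <- toy_panel(2)
  n_rep <- 300
  set.seed(99)
  rej <- 0
  for (r in seq_len(n_rep)) {
    draw <- function() sort(sample(c(100L, 102L, 104L), 2, replace = TRUE,
                                   prob = c(0.5, 0.3, 0.2)))
    calls <- lapply(seq_len(25), function(i) list(draw(), draw()))
    tab <- make_table(stats::setNames(calls, paste0("i", seq_len(25))), panel)
    p <- ld_genotypic_test(tab, "L1", "L2", n_perm = 99)$p
    if (p <= 0.05) rej <- rej + 1
  }
  rate <- rej / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(rate, 0.05 + 3 * se)  # permutation tests may be conservative
})

test_that("null-allele estimators match closed forms and vanish without
           homozygote excess", {
  # construct counts with H_exp ~ 0.8, H_obs = 0.6: 50 individuals
  # chakraborty = (He - Ho)/(He + Ho), brookfield1 = (He - Ho)/(1 + He)
  make_counts <- function(n_hom, n_het, k = 5) {
    counts <- matrix(0L, k, k, dimnames = list(1:k, 1:k))
    hom_alleles <- rep(1:k, length.out = n_hom)
    for (a in hom_alleles) counts[a, a] <- counts[a, a] + 1L
    hets <- utils::combn(k, 2)
    for (i in seq_len(n_het)) {
      pr <- hets[, 1 + (i - 1) %% ncol(hets)]
      counts[pr[1], pr[2]] <- counts[pr[1], pr[2]] + 1L
      counts[pr[2], pr[1]] <- counts[pr[2], pr[1]] + 1L
    }
    counts
  }
  counts <- make_counts(20, 30)
  h <- heterozygosity(counts)
  expect_equal(null_allele_frequency(counts, "chakraborty"),
               (h$H_exp - h$H_obs) / (h$H_exp + h$H_obs))
  expect_equal(null_allele_frequency(counts, "brookfield1"),
               (h$H_exp - h$H_obs) / (1 + h$H_exp))
  # spec arithmetic: He = 0.8, Ho = 0.6 -> chakraborty = 0.1429
  expect_equal(round((0.8 - 0.6) / (0.8 + 0.6), 4), 0.1429)

  # a sample at Hardy-Weinberg proportions: no null signal
  hwe_counts <- matrix(c(25L, 50L, 50L, 25L), 2, 2,
                       dimnames = list(1:2, 1:2))
  expect_lt(abs(null_allele_frequency(hwe_counts, "summers_amos")), 0.02)
  # heterozygote excess: closed forms go negative, returned as-is
  excess <- matrix(c(1L, 20L, 20L, 1L), 2, 2, dimnames = list(1:2, 1:2))
  expect_lt(null_allele_frequency(excess, "chakraborty"), 0)
})

test_that("iterative estimator recovers a true null frequency of 0.15", {
  cfg <- simulation_config(n_pairs = 10000,
                           null_allele_freq = c(COR110 = 0.15), seed = 17)
  st <- simulate_study(cfg)
  mares <- grep("^M", st$genotypes$individuals, value = TRUE)
  counts <- genotype_counts(st$genotypes, "COR110", mares)
  est <- null_allele_frequency(counts, "summers_amos")
  expect_lt(abs(est - 0.15), 0.02)
})

test_that("locus_qc reports every locus with statistics in range", {
  st <- simulate_study(simulation_config(seed = 2))
  qc <- locus_qc(st$genotypes, seed = 11, mc_reps = 2000)
  expect_equal(qc$locus, st$genotypes$loci)
  expect_true(all(qc$H_obs >= 0 & qc$H_obs <= 1, na.rm = TRUE))
  expect_true(all(qc$H_exp >= 0 & qc$H_exp <= 1, na.rm = TRUE))
  expect_true(all(qc$hwe_p > 0 & qc$hwe_p <= 1, na.rm = TRUE))
  expect_true(all(qc$n <= length(st$genotypes$individuals)))
})
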