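#' Genotype counts at one locus
#'
#' @param table A [genotype_table()].
#' @param locus Locus name.
#' @param individuals Optional subset of ids.
#' @return Symmetric integer matrix of genotype counts, rows/columns named by
#'   allele bp (counts stored in the upper triangle convention `i <= j` and
#'   mirrored).
#' @export
genotype_counts <- function(table, locus, individuals = NULL) {
  if (is.null(individuals)) individuals <- table$individuals
  a1 <- table$allele1[individuals, locus]
  a2 <- table$allele2[individuals, locus]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  m <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (i in seq_along(a1)) {
    r <- match(a1[i], alleles); c <- match(a2[i], alleles)
    m[r, c] <- m[r, c] + 1L
    if (r != c) m[c, r] <- m[c, r] + 1L
  }
  m
}

counts_to_stats <- function(counts) {
  # counts: symmetric genotype count matrix; n_ij for i != j appears twice
  k <- nrow(counts)
  n <- sum(counts[upper.tri(counts, diag = TRUE)])
  allele_counts <- rowSums(counts) + diag(counts)  # copies of each allele
  list(k = k, n = n, allele_counts = allele_counts,
       het = n - sum(diag(counts)))
}

#' Observed and unbiased expected heterozygosity
#'
#' `H_obs` is the proportion of heterozygous individuals; `H_exp` is Nei's
#' unbiased expected heterozygosity \eqn{\frac{2n}{2n-1}(1 - \sum_i p_i^2)}.
#'
#' @param counts Genotype count matrix from [genotype_counts()].
#' @return List with `H_obs`, `H_exp`, `n`.
#' @export
heterozygosity <- function(counts) {
  st <- counts_to_stats(counts)
  if (st$n == 0) stop("no genotypes", call. = FALSE)
  p <- st$allele_counts / (2 * st$n)
  h_exp <- if (st$n > 1) (2 * st$n / (2 * st$n - 1)) * (1 - sum(p^2)) else
    1 - sum(p^2)
  list(H_obs = st$het / st$n, H_exp = h_exp, n = st$n)
}

log_array_prob <- function(counts, allele_counts, n) {
  # conditional probability of a genotype array given allele counts:
  # P = n! prod(m_i!) 2^het / ( (2n)! prod_{i<=j} n_ij! )
  het <- sum(counts[upper.tri(counts)])
  nij <- c(diag(counts), counts[upper.tri(counts)])
  lgamma(n + 1) + sum(lgamma(allele_counts + 1)) + het * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(nij + 1))
}

enumerate_arrays <- function(allele_counts, fun, max_nodes = 2e6) {
  # Depth-first enumeration of symmetric genotype arrays with the given
  # allele (gene-copy) counts; calls fun(counts) for each complete array.
  k <- length(allele_counts)
  pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  nodes <- 0L
  counts <- matrix(0L, k, k)
  recur <- function(idx, remaining) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) stop("enumeration space too large", call. = FALSE)
    if (idx > nrow(pairs)) {
      if (all(remaining == 0)) fun(counts)
      return(invisible())
    }
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    cap <- if (i == j) remaining[i] %/% 2 else min(remaining[i], remaining[j])
    for (x in 0:cap) {
      rem <- remaining
      if (i == j) rem[i] <- rem[i] - 2L * x else {
        rem[i] <- rem[i] - x; rem[j] <- rem[j] - x
      }
      counts[i, j] <<- x
      if (i != j) counts[j, i] <<- x
      # prune: allele i is exhausted after its last pair
      if (j == k && rem[i] != 0) { next }
      recur(idx + 1L, rem)
    }
    counts[i, j] <<- 0L
    if (i != j) counts[j, i] <<- 0L
    invisible()
  }
  recur(1L, as.integer(allele_counts))
  invisible(nodes)
}

sample_array <- function(copies, k) {
  # random pairing of the 2n gene copies: draws one genotype array from the
  # exact conditional null distribution given allele counts
  perm <- sample(copies)
  i <- perm[seq(1, length(perm), by = 2)]
  j <- perm[seq(2, length(perm), by = 2)]
  m <- matrix(0L, k, k)
  for (t in seq_along(i)) {
    m[i[t], j[t]] <- m[i[t], j[t]] + 1L
    if (i[t] != j[t]) m[j[t], i[t]] <- m[j[t], i[t]] + 1L
  }
  m
}

#' Hardy-Weinberg exact probability test
#'
#' Conditional exact test of Hardy-Weinberg proportions: the p-value is the
#' total conditional probability, given the observed allele counts, of all
#' genotype arrays no more probable than the observed array. Small problems
#' are solved by full enumeration of the array space; larger ones by Monte
#' Carlo, drawing arrays from the exact conditional null by random pairing of
#' the observed gene copies (each draw is independent, so no burn-in or
#' batching is required).
#'
#' @param counts Genotype count matrix from [genotype_counts()].
#' @param method `"auto"` enumerates when the array space fits under
#'   `max_nodes`, else falls back to Monte Carlo.
#' @param mc_reps Monte Carlo draws.
#' @param max_nodes Enumeration budget (search-tree nodes).
#' @param seed Optional seed for the Monte Carlo path.
#' @return List with `p`, `method` used, `testable` (`FALSE` and `p = 1` for
#'   a monomorphic locus), and `se` (binomial SE, Monte Carlo only).
#' @export
hwe_exact_test <- function(counts,
                           method = c("auto", "enumerate", "monte_carlo"),
                           mc_reps = 10000, max_nodes = 2e6, seed = NULL) {
  method <- match.arg(method)
  if (mc_reps <= 0 || max_nodes <= 0) {
    stop("mc_reps and max_nodes must be positive", call. = FALSE)
  }
  st <- counts_to_stats(counts)
  if (st$n < 1) stop("no genotypes", call. = FALSE)
  if (st$k < 2) {
    return(list(p = 1, method = "degenerate", testable = FALSE, se = 0))
  }
  if (st$n < 2) stop("need >= 2 individuals", call. = FALSE)
  obs_lp <- log_array_prob(counts, st$allele_counts, st$n)
  tol <- 1e-9
  # cheap feasibility screen so "auto" does not burn the enumeration budget
  # walking a huge search tree before falling back to Monte Carlo
  feasible <- st$k == 2 || (st$k == 3 && st$n <= 100) ||
    (st$k == 4 && st$n <= 30) || (st$k <= 6 && st$n <= 12)
  if (method == "auto" && !feasible) method <- "monte_carlo"
  if (method != "monte_carlo") {
    p_sum <- 0
    ok <- tryCatch({
      enumerate_arrays(st$allele_counts, function(arr) {
        lp <- log_array_prob(arr, st$allele_counts, st$n)
        if (lp <= obs_lp + tol) p_sum <<- p_sum + exp(lp)
      }, max_nodes = max_nodes)
      TRUE
    }, error = function(e) {
      if (method == "enumerate") stop(e)
      FALSE
    })
    if (ok) {
      return(list(p = min(p_sum, 1), method = "enumerate",
                  testable = TRUE, se = 0))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  copies <- rep(seq_len(st$k), times = st$allele_counts)
  hits <- 0L
  for (r in seq_len(mc_reps)) {
    arr <- sample_array(copies, st$k)
    if (log_array_prob(arr, st$allele_counts, st$n) <= obs_lp + tol) {
      hits <- hits + 1L
    }
  }
  p <- (hits + 1) / (mc_reps + 1)
  list(p = p, method = "monte_carlo", testable = TRUE,
       se = sqrt(p * (1 - p) / mc_reps))
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Monte-Carlo exact test of independence between the genotype distributions
#' at two loci. The observed two-locus genotype contingency table's
#' log-likelihood-ratio statistic (G) is compared with its permutation
#' distribution obtained by shuffling one locus's genotypes among
#' individuals, which preserves both single-locus distributions.
#'
#' @param table A [genotype_table()].
#' @param locus_a,locus_b Locus names.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return List with `p` (add-one permutation p-value), `G`, `testable`.
#' @export
ld_genotypic_test <- function(table, locus_a, locus_b, n_perm = 1000,
                              seed = NULL) {
  if (n_perm <= 0) stop("n_perm must be positive", call. = FALSE)
  ga <- paste(table$allele1[, locus_a], table$allele2[, locus_a])
  gb <- paste(table$allele1[, locus_b], table$allele2[, locus_b])
  keep <- !is.na(table$allele1[, locus_a]) & !is.na(table$allele1[, locus_b])
  ga <- ga[keep]; gb <- gb[keep]
  if (length(ga) < 2) stop("need >= 2 shared typed individuals", call. = FALSE)
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2) {
    return(list(p = 1, G = 0, testable = FALSE))
  }
  g_stat <- function(a, b) {
    tab <- table(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    2 * sum(tab[nz] * log(tab[nz] / e[nz]))
  }
  g_obs <- g_stat(ga, gb)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    if (g_stat(ga, sample(gb)) >= g_obs - 1e-12) hits <- hits + 1L
  }
  list(p = (hits + 1) / (n_perm + 1), G = g_obs, testable = TRUE)
}

#' Null-allele frequency estimators
#'
#' Estimates the frequency of a non-amplifying (null) allele from the excess
#' of apparent homozygotes:
#' \describe{
#'   \item{chakraborty}{\eqn{(H_e - H_o) / (H_e + H_o)}.}
#'   \item{brookfield1}{\eqn{(H_e - H_o) / (1 + H_e)}.}
#'   \item{summers_amos}{Iterative (EM) estimate: apparent homozygotes are
#'     treated as a mixture of true homozygotes and visible/null
#'     heterozygotes under Hardy-Weinberg, and the null frequency is
#'     iterated to a fixed point (|change| < 1e-10).}
#' }
#' Negative estimates (heterozygote excess) are returned as-is.
#'
#' @param counts Genotype count matrix from [genotype_counts()].
#' @param estimator Which estimator.
#' @return Numeric estimate.
#' @export
null_allele_frequency <- function(counts,
                                  estimator = c("summers_amos", "chakraborty",
                                                "brookfield1")) {
  estimator <- match.arg(estimator)
  h <- heterozygosity(counts)
  if (h$H_exp <= 0) {
    stop("H_exp = 0: null-allele frequency undefined", call. = FALSE)
  }
  if (estimator == "chakraborty") {
    return((h$H_exp - h$H_obs) / (h$H_exp + h$H_obs))
  }
  if (estimator == "brookfield1") {
    return((h$H_exp - h$H_obs) / (1 + h$H_exp))
  }
  # summers_amos: EM over the latent split of apparent homozygotes into
  # true homozygotes and visible/null heterozygotes, with the unobserved
  # null/null class imputed (it presents as missing data, not as a genotype)
  st <- counts_to_stats(counts)
  hom <- diag(counts)                       # apparent homozygote counts
  het_copies <- rowSums(counts) - diag(counts)  # copies in heterozygotes
  n <- st$n
  r <- 0.1                                  # fixed point 0 is absorbing
  p <- st$allele_counts / (2 * n) * (1 - r)
  for (iter in 1:10000) {
    # P(true i/null | apparent ii) = 2r / (p_i + 2r) under HWE
    w <- ifelse(p + 2 * r > 0, 2 * r / (p + 2 * r), 0)
    m <- n * r^2 / (1 - r^2)                # imputed null/null individuals
    total <- 2 * (n + m)
    null_copies <- sum(hom * w) + 2 * m
    vis_copies <- het_copies + hom * (2 - w)
    r_new <- null_copies / total
    p_new <- vis_copies / total
    delta <- abs(r_new - r)
    r <- r_new; p <- p_new
    if (delta < 1e-10) break
  }
  r
}

#' Per-locus quality-control report
#'
#' Heterozygosities, Hardy-Weinberg exact p-values and the three null-allele
#' estimates for every locus of a genotype table.
#'
#' @param table A [genotype_table()].
#' @param seed Seed for Monte-Carlo HWE p-values.
#' @param mc_reps Monte Carlo draws for loci too large to enumerate.
#' @return Data.frame with columns `locus`, `n`, `H_obs`, `H_exp`, `hwe_p`,
#'   `hwe_method`, `null_chakraborty`, `null_brookfield1`,
#'   `null_summers_amos`.
#' @export
locus_qc <- function(table, seed = NULL, mc_reps = 10000) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(table$loci, function(loc) {
    cnt <- genotype_counts(table, loc)
    if (nrow(cnt) == 0) {
      return(data.frame(locus = loc, n = 0L, H_obs = NA, H_exp = NA,
                        hwe_p = NA, hwe_method = "untyped",
                        null_chakraborty = NA, null_brookfield1 = NA,
                        null_summers_amos = NA, stringsAsFactors = FALSE))
    }
    h <- heterozygosity(cnt)
    hw <- hwe_exact_test(cnt, mc_reps = mc_reps)
    nulls <- if (h$H_exp > 0) {
      c(null_allele_frequency(cnt, "chakraborty"),
        null_allele_frequency(cnt, "brookfield1"),
        null_allele_frequency(cnt, "summers_amos"))
    } else c(NA, NA, NA)
    data.frame(locus = loc, n = h$n, H_obs = h$H_obs, H_exp = h$H_exp,
               hwe_p = hw$p, hwe_method = hw$method,
               null_chakraborty = nulls[1], null_brookfield1 = nulls[2],
               null_summers_amos = nulls[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
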