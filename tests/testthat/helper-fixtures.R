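# Shared fixtures and independent oracles for the test suite.

toy_panel <- function(n_loci = 3, classes = NULL) {
  if (is.null(classes)) classes <- rep(c("I", "II"), length.out = n_loci)
  locus_panel(
    name = paste0("L", seq_len(n_loci)),
    mhc_class = classes,
    size_min = rep(100L, n_loci),
    size_max = rep(140L, n_loci),
    multiplex = rep(1L, n_loci)
  )
}

# build a genotype table from a named list id -> list of length-2 allele
# vectors (one per locus, NULL = missing)
make_table <- function(calls, panel) {
  ids <- names(calls)
  n_loci <- nrow(panel)
  a1 <- a2 <- matrix(NA_integer_, length(ids), n_loci,
                     dimnames = list(ids, panel$name))
  for (i in seq_along(ids)) {
    for (l in seq_len(n_loci)) {
      g <- calls[[i]][[l]]
      if (!is.null(g)) {
        a1[i, l] <- g[1]
        a2[i, l] <- g[2]
      }
    }
  }
  genotype_table(ids, a1, a2, panel)
}

# independent brute-force compatibility oracle: containment on allele sets,
# category by direct definition over the per-locus flag vectors
oracle_category <- function(mare_genos, foal_genos) {
  fim <- mif <- logical(length(mare_genos))
  for (l in seq_along(mare_genos)) {
    ms <- unique(mare_genos[[l]])
    fs <- unique(foal_genos[[l]])
    fim[l] <- length(setdiff(fs, ms)) == 0
    mif[l] <- length(setdiff(ms, fs)) == 0
  }
  if (all(fim & mif)) return("MFC")
  if (all(fim)) return("MC")
  if (all(mif)) return("FC")
  "NC"
}

# independent HWE exact-test oracle for a 2-allele locus: enumerate every
# genotype array with the observed allele counts directly via the number of
# heterozygotes (which fixes the whole array), probabilities from factorials
oracle_hwe_2allele <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  m1 <- 2 * n11 + n12
  m2 <- 2 * n22 + n12
  prob <- function(h) {
    # h heterozygotes; needs same parity as m1 and both homozygote counts >= 0
    a <- (m1 - h) / 2
    b <- (m2 - h) / 2
    if (h < 0 || a < 0 || b < 0 || a != round(a) || b != round(b)) return(NA)
    exp(lfactorial(n) + lfactorial(m1) + lfactorial(m2) + h * log(2) -
          lfactorial(2 * n) - lfactorial(a) - lfactorial(h) - lfactorial(b))
  }
  probs <- vapply(0:min(m1, m2), prob, numeric(1))
  probs <- probs[!is.na(probs)]
  p_obs <- prob(n12)
  sum(probs[probs <= p_obs + 1e-12])
}

# gene-dropping kinship oracle: drop unique founder alleles through the
# pedigree and estimate P(two random alleles IBD) by Monte Carlo
oracle_gene_drop <- function(ped, ids, n_rep = 2000) {
  ord <- ped$id  # already parents-before-offspring
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  k <- length(ids)
  acc <- matrix(0, k, k, dimnames = list(ids, ids))
  next_allele <- 0L
  for (r in seq_len(n_rep)) {
    al <- list()
    for (x in ord) {
      get <- function(p) {
        if (is.na(p)) {
          next_allele <<- next_allele + 1L
          next_allele
        } else {
          al[[p]][sample.int(2, 1)]
        }
      }
      al[[x]] <- c(get(sire[[x]]), get(dam[[x]]))
    }
    for (a in seq_len(k)) for (b in a:k) {
      sh <- mean(outer(al[[ids[a]]], al[[ids[b]]], "==")) # 4 pick pairs
      acc[a, b] <- acc[a, b] + sh
      acc[b, a] <- acc[a, b]
    }
  }
  acc / n_rep
}

# exact two-sided Mann-Whitney oracle by full enumeration of group labels
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_of <- function(sel) {
    x <- pooled[sel]
    y <- pooled[-sel]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n_a))
  us <- apply(idx, 2, u_of)
  mu <- n_a * (length(pooled) - n_a) / 2
  # two-sided: double the smaller tail (the convention of exact rank tests)
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else if (u_obs < mu)
    2 * mean(us <= u_obs) else 1
  min(p, 1)
}
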