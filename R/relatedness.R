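#' Queller-Goodnight pairwise relatedness
#'
#' Moment estimator of relatedness between two individuals from multilocus
#' genotypes and reference allele frequencies. Identity-by-state sharing is
#' corrected for the sharing expected by chance given the reference
#' frequencies. Per locus, for x = (a, b) and y = (c, d) with S(u, v) = 1
#' when u and v carry the same allele label,
#' \deqn{N_{x \to y} = \tfrac12(S_{ac}+S_{ad}+S_{bc}+S_{bd}) - p_a - p_b,
#'       \quad D_{x \to y} = 1 + S_{ab} - p_a - p_b,}
#' and the multilocus estimate pools both directions:
#' \deqn{r_{xy} = \frac{\sum_L N_{x \to y} + \sum_L N_{y \to x}}
#'                     {\sum_L D_{x \to y} + \sum_L D_{y \to x}}.}
#' By construction \eqn{r_{xy} = 1} whenever the two genotypes are identical
#' at every used locus, and the estimator is symmetric in its arguments.
#' Loci missing in either individual are skipped.
#'
#' @param table A [genotype_table()].
#' @param id_x,id_y Individual ids.
#' @param freqs An [allele_frequencies()] table providing the reference
#'   frequencies; every allele carried by either individual at a used locus
#'   must appear in it.
#' @param loci Loci to use (default: all loci present in `freqs`).
#' @return List with `id_x`, `id_y`, `r_xy` (`NA` with a warning when the
#'   pooled denominator is 0) and `loci_used`.
#' @export
qg_rxy <- function(table, id_x, id_y, freqs, loci = NULL) {
  if (is.null(loci)) loci <- intersect(table$loci, names(freqs))
  num <- den <- 0
  used <- 0L
  for (loc in loci) {
    x <- genotype_call(table, id_x, loc)
    y <- genotype_call(table, id_y, loc)
    if (is.null(x) || is.null(y)) next
    pf <- freqs[[loc]]$freq
    for (al in unique(c(x, y))) {
      if (!as.character(al) %in% names(pf)) {
        stop(sprintf("allele %d at locus '%s' absent from reference frequencies",
                     al, loc), call. = FALSE)
      }
    }
    p <- function(al) pf[[as.character(al)]]
    dir_terms <- function(u, v) {
      s <- outer(u, v, "==")
      c(num = 0.5 * sum(s) - p(u[1]) - p(u[2]),
        den = 1 + (u[1] == u[2]) - p(u[1]) - p(u[2]))
    }
    xy <- dir_terms(x, y)
    yx <- dir_terms(y, x)
    num <- num + xy["num"] + yx["num"]
    den <- den + xy["den"] + yx["den"]
    used <- used + 1L
  }
  if (used == 0L) {
    stop(sprintf("no shared typed loci for pair %s/%s", id_x, id_y),
         call. = FALSE)
  }
  r <- if (abs(den) < 1e-12) {
    warning(sprintf("pooled denominator 0 for pair %s/%s; r_xy undefined",
                    id_x, id_y), call. = FALSE)
    NA_real_
  } else as.numeric(num / den)
  list(id_x = id_x, id_y = id_y, r_xy = r, loci_used = used)
}

#' Relatedness for every mare-foal pair
#'
#' @param table A [genotype_table()].
#' @param pairs Data.frame with `mare_id`, `foal_id`, `rfm`.
#' @param freqs Reference [allele_frequencies()]; defaults to frequencies
#'   pooled over all individuals in `table`.
#' @return Data.frame: `mare_id`, `foal_id`, `rfm`, `r_xy`, `loci_used`.
#' @export
pairwise_relatedness <- function(table, pairs, freqs = NULL) {
  validate_pairs(pairs, table)
  if (is.null(freqs)) freqs <- allele_frequencies(table)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- qg_rxy(table, pairs$mare_id[i], pairs$foal_id[i], freqs)
    data.frame(mare_id = pairs$mare_id[i], foal_id = pairs$foal_id[i],
               rfm = pairs$rfm[i], r_xy = r$r_xy, loci_used = r$loci_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group summary of pairwise relatedness
#'
#' Arithmetic mean and sample SD of r_xy per outcome group, plus pooled.
#'
#' @param rxy Output of [pairwise_relatedness()].
#' @return Data.frame with `group`, `n`, `mean`, `sd`.
#' @export
group_relatedness_summary <- function(rxy) {
  if (any(is.na(rxy$r_xy))) {
    stop("undefined r_xy present; summarise only defined pairs", call. = FALSE)
  }
  groups <- list(RFM = rxy$r_xy[rxy$rfm], control = rxy$r_xy[!rxy$rfm],
                 pooled = rxy$r_xy)
  if (any(vapply(groups[1:2], length, 1L) == 0)) {
    stop("empty group", call. = FALSE)
  }
  data.frame(group = names(groups),
             n = vapply(groups, length, 1L),
             mean = vapply(groups, mean, 1),
             sd = vapply(groups, stats::sd, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
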