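#' Construct a pedigree
#'
#' A pedigree maps each individual to its sire and dam. Unknown parents are
#' `NA`; a parent referenced but not listed as an individual is added as a
#' founder. The pedigree must be acyclic (no individual is its own
#' ancestor).
#'
#' @param id Character vector of individual ids.
#' @param sire,dam Character vectors of parent ids (`NA` or `""` = unknown).
#' @return A `pedigree` object: data.frame `id`, `sire`, `dam` in an order
#'   with parents before offspring, plus a `depth` attribute.
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  sire[!is.na(sire) & sire == ""] <- NA
  dam[!is.na(dam) & dam == ""] <- NA
  if (anyDuplicated(id)) stop("duplicate ids in pedigree", call. = FALSE)
  extra <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(extra)) {
    id <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  # topological depth; cycle check
  depth <- stats::setNames(rep(NA_integer_, nrow(ped)), ped$id)
  get_depth <- function(x, path = character(0)) {
    if (is.na(x)) return(-1L)
    if (x %in% path) {
      stop("pedigree cycle involving: ",
           paste(c(path[which(path == x):length(path)], x), collapse = " -> "),
           call. = FALSE)
    }
    if (!is.na(depth[[x]])) return(depth[[x]])
    i <- match(x, ped$id)
    d <- 1L + max(get_depth(ped$sire[i], c(path, x)),
                  get_depth(ped$dam[i], c(path, x)))
    depth[[x]] <<- d
    d
  }
  for (x in ped$id) get_depth(x)
  ped <- ped[order(depth[ped$id]), ]
  rownames(ped) <- NULL
  attr(ped, "depth") <- depth
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a pedigree from CSV
#'
#' Expected columns: `id`, `sire`, `dam`; empty cells mark unknown parents.
#'
#' @param path CSV file.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("id", "sire", "dam") %in% names(df))) {
    stop("pedigree CSV needs columns id, sire, dam", call. = FALSE)
  }
  pedigree(df$id, df$sire, df$dam)
}

#' Malecot kinship coefficient
#'
#' Probability that a random allele drawn from each of two individuals is
#' identical by descent, by the standard recursion: for a single individual
#' \eqn{f(i,i) = \tfrac12 (1 + f(s_i, d_i))}; for two distinct individuals
#' the recursion descends through the parents of the one further from the
#' founders, \eqn{f(i,j) = \tfrac12 (f(s_i, j) + f(d_i, j))}; kinship with an
#' unknown parent is 0. Results are memoised over the pedigree.
#'
#' @param ped A [pedigree()].
#' @param i,j Individual ids.
#' @param cache Optional environment reused across calls to share the
#'   memoisation table.
#' @return Kinship coefficient in \[0, 1\].
#' @export
kinship <- function(ped, i, j, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  depth <- attr(ped, "depth")
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  f <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- if (a <= b) paste0(a, "\r", b) else paste0(b, "\r", a)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      0.5 * (1 + f(sire[[a]], dam[[a]]))
    } else if (depth[[a]] >= depth[[b]]) {
      0.5 * (f(sire[[a]], b) + f(dam[[a]], b))
    } else {
      0.5 * (f(sire[[b]], a) + f(dam[[b]], a))
    }
    cache[[key]] <- val
    val
  }
  for (x in c(i, j)) {
    if (!x %in% ped$id) stop("id not in pedigree: ", x, call. = FALSE)
  }
  f(i, j)
}

#' Kinship matrix for a set of individuals
#'
#' @param ped A [pedigree()].
#' @param ids Ids (default: all pedigree members).
#' @return Symmetric numeric matrix of kinship coefficients.
#' @export
kinship_matrix <- function(ped, ids = ped$id) {
  cache <- new.env(parent = emptyenv())
  k <- length(ids)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  for (a in seq_len(k)) {
    for (b in a:k) {
      m[a, b] <- m[b, a] <- kinship(ped, ids[a], ids[b], cache)
    }
  }
  m
}

#' Pedigree inbreeding coefficient
#'
#' \eqn{F_i} is the kinship of the parents; 0 when either parent is unknown.
#'
#' @param ped A [pedigree()].
#' @param ids Ids to report (default all).
#' @return Named numeric vector of F values.
#' @export
inbreeding_coefficient <- function(ped, ids = ped$id) {
  cache <- new.env(parent = emptyenv())
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  out <- vapply(ids, function(x) {
    if (!x %in% ped$id) stop("id not in pedigree: ", x, call. = FALSE)
    s <- sire[[x]]; d <- dam[[x]]
    if (is.na(s) || is.na(d)) 0 else kinship(ped, s, d, cache)
  }, numeric(1))
  names(out) <- ids
  out
}

#' Group comparison of inbreeding coefficients
#'
#' Median and interquartile range of F per group with a Mann-Whitney U
#' comparison, reported separately for mares and foals as in the study
#' design.
#'
#' @param f_values Named numeric vector from [inbreeding_coefficient()].
#' @param pairs Data.frame with `mare_id`, `foal_id`, `rfm`.
#' @return List with `mares` and `foals`, each holding per-group
#'   `median`/`iqr`/`n` and the Mann-Whitney result.
#' @export
inbreeding_group_comparison <- function(f_values, pairs) {
  one <- function(ids, rfm) {
    x <- f_values[ids[rfm]]
    y <- f_values[ids[!rfm]]
    mw <- mann_whitney_u(x, y)
    list(rfm = list(median = stats::median(x), iqr = stats::IQR(x),
                    n = length(x)),
         control = list(median = stats::median(y), iqr = stats::IQR(y),
                        n = length(y)),
         test = mw)
  }
  list(mares = one(pairs$mare_id, pairs$rfm),
       foals = one(pairs$foal_id, pairs$rfm))
}
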