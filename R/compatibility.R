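#' Per-locus containment flags between a mare and a foal call
#'
#' Compatibility is a presence/absence criterion on the distinct alleles of
#' each call: the foal is contained in the mare at a locus when the foal
#' carries no allele the mare lacks, and vice versa. A mare heterozygote
#' \{a,b\} therefore contains a foal homozygote \{a,a\}. A missing call on
#' either side makes the locus untestable.
#'
#' @param mare_call,foal_call Length-2 integer vectors (allele bp) or `NULL`
#'   for a missing call.
#' @return List with `foal_in_mare`, `mare_in_foal` (logical, `NA` when
#'   untestable) and `testable`.
#' @export
locus_flags <- function(mare_call, foal_call) {
  if (is.null(mare_call) || is.null(foal_call)) {
    return(list(foal_in_mare = NA, mare_in_foal = NA, testable = FALSE))
  }
  m <- unique(mare_call)
  f <- unique(foal_call)
  list(foal_in_mare = all(f %in% m),
       mare_in_foal = all(m %in% f),
       testable = TRUE)
}

#' Classify a mare-foal pair within one MHC class
#'
#' Aggregates the per-locus containment flags over every locus of the given
#' MHC class into one of four mutually exclusive categories:
#' \describe{
#'   \item{MFC}{mare-foal compatible: both containments hold at every locus.}
#'   \item{MC}{mare compatible: the foal is contained in the mare at every
#'     locus, but not MFC — the mare's immune system sees no foreign allele.}
#'   \item{FC}{foal compatible: the mare is contained in the foal at every
#'     locus, but not MFC.}
#'   \item{NC}{not compatible: at least one locus breaks each containment.}
#' }
#' A single locus failing a containment is enough to break that category for
#' the whole class.
#'
#' @param table A [genotype_table()].
#' @param mare_id,foal_id Individual ids.
#' @param mhc_class `"I"` or `"II"`.
#' @param missing_policy `"ignore"` classifies on the testable loci of the
#'   class; `"strict"` refuses to classify when any class locus is
#'   untestable.
#' @return List with `mare_id`, `foal_id`, `mhc_class`,
#'   `category` (factor in MC/FC/MFC/NC) and `loci_used`.
#' @export
classify_pair <- function(table, mare_id, foal_id,
                          mhc_class = c("I", "II"),
                          missing_policy = c("ignore", "strict")) {
  mhc_class <- match.arg(mhc_class)
  missing_policy <- match.arg(missing_policy)
  loci <- intersect(panel_loci(table$panel, mhc_class), table$loci)
  if (!length(loci)) {
    stop("no MHC class ", mhc_class, " loci in table", call. = FALSE)
  }
  fim <- mif <- logical(0)
  untestable <- 0L
  for (loc in loci) {
    fl <- locus_flags(genotype_call(table, mare_id, loc),
                      genotype_call(table, foal_id, loc))
    if (!fl$testable) {
      untestable <- untestable + 1L
      next
    }
    fim <- c(fim, fl$foal_in_mare)
    mif <- c(mif, fl$mare_in_foal)
  }
  if (missing_policy == "strict" && untestable > 0L) {
    stop(sprintf("pair %s/%s undetermined for MHC %s: %d untestable loci",
                 mare_id, foal_id, mhc_class, untestable), call. = FALSE)
  }
  if (!length(fim)) {
    stop(sprintf("pair %s/%s undetermined for MHC %s: zero testable loci",
                 mare_id, foal_id, mhc_class), call. = FALSE)
  }
  category <- if (all(fim) && all(mif)) "MFC"
              else if (all(fim)) "MC"
              else if (all(mif)) "FC"
              else "NC"
  list(mare_id = mare_id, foal_id = foal_id, mhc_class = mhc_class,
       category = factor(category, levels = c("MC", "FC", "MFC", "NC")),
       loci_used = length(fim))
}

#' Classify every mare-foal pair for both MHC classes
#'
#' @param table A [genotype_table()].
#' @param pairs Data.frame with columns `mare_id`, `foal_id`, `rfm`
#'   (logical).
#' @param missing_policy Passed to [classify_pair()].
#' @return Data.frame with one row per pair x MHC class: `mare_id`,
#'   `foal_id`, `rfm`, `mhc_class`, `category`, `loci_used`.
#' @export
classify_pairs <- function(table, pairs, missing_policy = "ignore") {
  validate_pairs(pairs, table)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    do.call(rbind, lapply(c("I", "II"), function(cl) {
      call <- classify_pair(table, pairs$mare_id[i], pairs$foal_id[i],
                            cl, missing_policy)
      data.frame(mare_id = call$mare_id, foal_id = call$foal_id,
                 rfm = pairs$rfm[i], mhc_class = cl,
                 category = as.character(call$category),
                 loci_used = call$loci_used, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = c("MC", "FC", "MFC", "NC"))
  rownames(out) <- NULL
  out
}

validate_pairs <- function(pairs, table = NULL) {
  need <- c("mare_id", "foal_id", "rfm")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns mare_id, foal_id, rfm", call. = FALSE)
  }
  if (nrow(pairs) == 0) stop("pairs table is empty", call. = FALSE)
  if (any(pairs$mare_id == pairs$foal_id)) {
    stop("mare_id must differ from foal_id", call. = FALSE)
  }
  if (any(is.na(pairs$rfm))) stop("rfm undefined for some pairs", call. = FALSE)
  if (!is.null(table)) {
    ids <- unique(c(pairs$mare_id, pairs$foal_id))
    absent <- setdiff(ids, table$individuals)
    if (length(absent)) {
      stop("pair ids not genotyped: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(pairs)
}

#' Tabulate compatibility categories by outcome group and MHC class
#'
#' Produces counts and integer-rounded percentages in the shape of a
#' group x MHC class x category contingency table; within each group and
#' class the four category counts partition the group.
#'
#' @param calls Output of [classify_pairs()].
#' @return Data.frame with columns `group` ("RFM"/"control"), `mhc_class`,
#'   `category`, `n`, `pct`, plus a `group_n` column with the group size.
#' @export
tabulate_compatibility <- function(calls) {
  calls$group <- ifelse(calls$rfm, "RFM", "control")
  out <- expand.grid(group = c("RFM", "control"), mhc_class = c("I", "II"),
                     category = c("MC", "FC", "MFC", "NC"),
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(g, cl, cat) {
    sum(calls$group == g & calls$mhc_class == cl & calls$category == cat)
  }, out$group, out$mhc_class, out$category)
  grp_n <- tapply(calls$mare_id[calls$mhc_class == "I"],
                  calls$group[calls$mhc_class == "I"], length)
  out$group_n <- as.integer(grp_n[out$group])
  out$group_n[is.na(out$group_n)] <- 0L
  out$pct <- ifelse(out$group_n > 0, round(100 * out$n / out$group_n), NA)
  out <- out[order(out$group, out$mhc_class), ]
  rownames(out) <- NULL
  out
}
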