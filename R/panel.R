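#' Define a microsatellite locus panel
#'
#' A locus panel describes the microsatellite loci a genotype table may
#' contain: locus name, MHC class region (I or II), the expected amplicon
#' size range in base pairs, and the multiplex PCR group.
#'
#' @param name Character vector of unique locus names.
#' @param mhc_class Character vector, one of `"I"` or `"II"` per locus.
#' @param size_min,size_max Integer vectors, expected product size range (bp).
#' @param multiplex Integer vector, multiplex PCR group of each locus.
#'
#' @return A `locus_panel`: a data.frame with one row per locus.
#' @seealso [default_mhc_panel()]
#' @export
locus_panel <- function(name, mhc_class, size_min, size_max, multiplex) {
  stopifnot(length(name) >= 1, !anyDuplicated(name))
  mhc_class <- as.character(mhc_class)
  if (!all(mhc_class %in% c("I", "II"))) {
    stop("mhc_class must be 'I' or 'II' for every locus", call. = FALSE)
  }
  panel <- data.frame(
    name = as.character(name),
    mhc_class = mhc_class,
    size_min = as.integer(size_min),
    size_max = as.integer(size_max),
    multiplex = as.integer(multiplex),
    stringsAsFactors = FALSE
  )
  if (any(panel$size_min > panel$size_max)) {
    stop("size_min must not exceed size_max", call. = FALSE)
  }
  class(panel) <- c("locus_panel", "data.frame")
  panel
}

#' The default nine-locus equine MHC microsatellite panel
#'
#' Nine microsatellites within the MHC region on equine chromosome 20:
#' three in the class I region (COR110, TAMU30593, UMN-JH38) and six in the
#' class II region (ABGe9030, TKY3324, COR112, COR113, COR114, UM011), with
#' their amplicon size ranges and multiplex PCR groups.
#'
#' @return A [locus_panel()] with 9 rows.
#' @export
#' @examples
#' default_mhc_panel()
default_mhc_panel <- function() {
  locus_panel(
    name      = c("ABGe9030", "TKY3324", "COR110", "COR112", "TAMU30593",
                  "COR113", "COR114", "UM011", "UMN-JH38"),
    mhc_class = c("II", "II", "I", "II", "I", "II", "II", "II", "I"),
    size_min  = c(193, 239, 197, 230, 329, 248, 225, 158, 149),
    size_max  = c(209, 261, 214, 260, 345, 272, 245, 173, 157),
    multiplex = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L)
  )
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("Microsatellite locus panel:", nrow(x), "loci (",
      sum(x$mhc_class == "I"), "MHC class I,",
      sum(x$mhc_class == "II"), "class II )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

panel_loci <- function(panel, mhc_class = NULL) {
  if (is.null(mhc_class)) return(panel$name)
  panel$name[panel$mhc_class == mhc_class]
}
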