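#' Construct a multilocus genotype table
#'
#' Diploid microsatellite calls for a set of individuals over the loci of a
#' panel. Alleles are integer fragment lengths in base pairs; a homozygote is
#' the same length twice. Missing calls are `NA` in both allele slots; a call
#' with exactly one `NA` slot is rejected.
#'
#' @param individuals Character vector of unique individual ids.
#' @param allele1,allele2 Integer matrices (individuals x loci) of allele
#'   lengths; column names are locus names. `NA` = missing (both slots).
#' @param panel A [locus_panel()]; every column must be a panel locus.
#'
#' @return A `genotype_table` with components `individuals`, `loci`,
#'   `allele1`, `allele2` (allele order per call normalised so
#'   `allele1 <= allele2`), and `panel`.
#' @export
genotype_table <- function(individuals, allele1, allele2, panel) {
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) {
    stop("duplicate individual ids", call. = FALSE)
  }
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"; storage.mode(allele2) <- "integer"
  if (!identical(dim(allele1), dim(allele2))) {
    stop("allele matrices must have identical dimensions", call. = FALSE)
  }
  loci <- colnames(allele1)
  if (is.null(loci) || !identical(loci, colnames(allele2))) {
    stop("allele matrices need matching locus column names", call. = FALSE)
  }
  unknown <- setdiff(loci, panel$name)
  if (length(unknown)) {
    stop("loci not in panel: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("single-allele call for individual '%s' at locus '%s'",
                 individuals[bad[1]], loci[bad[2]]), call. = FALSE)
  }
  if (any(allele1 <= 0, na.rm = TRUE) || any(allele2 <= 0, na.rm = TRUE)) {
    stop("allele labels must be positive integers", call. = FALSE)
  }
  # normalise within-call order so identical genotypes compare equal
  lo <- pmin(allele1, allele2)
  hi <- pmax(allele1, allele2)
  dimnames(lo) <- dimnames(hi) <- list(individuals, loci)
  structure(
    list(individuals = individuals, loci = loci,
         allele1 = lo, allele2 = hi, panel = panel),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- sum(is.na(x$allele1))
  cat("Genotype table:", length(x$individuals), "individuals x",
      length(x$loci), "loci;", miss, "missing calls\n")
  invisible(x)
}

#' Extract one diploid call
#'
#' @param table A [genotype_table()].
#' @param id Individual id.
#' @param locus Locus name.
#' @return Integer vector of length 2 (sorted allele lengths) or `NULL` when
#'   the call is missing.
#' @export
genotype_call <- function(table, id, locus) {
  a <- table$allele1[id, locus]
  if (is.na(a)) return(NULL)
  c(a, table$allele2[id, locus])
}

#' Read a genotype table from CSV or GenePop
#'
#' The CSV dialect has one row per individual, an `id` column, and two
#' columns per locus named `<locus>_1` / `<locus>_2`; empty cells mark a
#' missing call (both columns must then be empty). The GenePop dialect is the
#' classic 3-digit-coded format written by [write_genepop()]; it requires the
#' sidecar allele map to translate codes back to fragment lengths in bp.
#'
#' @param path File to read.
#' @param format `"csv"` or `"genepop"`.
#' @param panel A [locus_panel()] the loci must belong to.
#' @param allele_map For `format = "genepop"`, path to the sidecar TSV
#'   (columns locus, code, bp) written alongside the GenePop file.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("csv", "genepop"), panel,
                           allele_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    read_genotypes_csv(path, panel)
  } else {
    if (is.null(allele_map)) {
      allele_map <- paste0(path, ".alleles.tsv")
    }
    read_genotypes_genepop(path, panel, allele_map)
  }
}

read_genotypes_csv <- function(path, panel) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!"id" %in% names(df)) stop("csv must have an 'id' column", call. = FALSE)
  cols <- setdiff(names(df), "id")
  base <- unique(sub("_[12]$", "", cols))
  for (loc in base) {
    need <- paste0(loc, c("_1", "_2"))
    if (!all(need %in% cols)) {
      stop("locus '", loc, "' must have both _1 and _2 columns", call. = FALSE)
    }
  }
  unknown <- setdiff(base, panel$name)
  if (length(unknown)) {
    stop("loci not in panel: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  parse_col <- function(v, colname) {
    v <- trimws(v)
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop(sprintf("cannot parse allele '%s' in column '%s', data row %d",
                   v[bad[1]], colname, bad[1]), call. = FALSE)
    }
    out
  }
  a1 <- sapply(base, function(l) parse_col(df[[paste0(l, "_1")]],
                                           paste0(l, "_1")))
  a2 <- sapply(base, function(l) parse_col(df[[paste0(l, "_2")]],
                                           paste0(l, "_2")))
  if (nrow(df) == 1L) {  # sapply drops to vector
    a1 <- matrix(a1, nrow = 1, dimnames = list(NULL, base))
    a2 <- matrix(a2, nrow = 1, dimnames = list(NULL, base))
  }
  genotype_table(df$id, a1, a2, panel)
}

#' Write a genotype table as CSV
#'
#' Inverse of the CSV dialect of [read_genotypes()].
#'
#' @param table A [genotype_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(table, path) {
  df <- data.frame(id = table$individuals, stringsAsFactors = FALSE)
  for (loc in table$loci) {
    df[[paste0(loc, "_1")]] <- table$allele1[, loc]
    df[[paste0(loc, "_2")]] <- table$allele2[, loc]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a genotype table in GenePop format
#'
#' Alleles are recoded per locus to 3-digit codes assigned by ascending
#' fragment length (001, 002, ...); `000` is the GenePop missing code. The
#' code-to-bp mapping is written to a sidecar TSV (`<path>.alleles.tsv` by
#' default) so [read_genotypes()] can reconstruct the original lengths.
#'
#' @param table A [genotype_table()].
#' @param path Output GenePop file.
#' @param title Title line for the file.
#' @param allele_map Path for the sidecar map TSV.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, title = "placmatch export",
                          allele_map = paste0(path, ".alleles.tsv")) {
  if (length(table$individuals) == 0) stop("no individuals", call. = FALSE)
  maps <- lapply(table$loci, function(loc) {
    alleles <- sort(unique(stats::na.omit(c(table$allele1[, loc],
                                            table$allele2[, loc]))))
    if (length(alleles) > 999) {
      stop("locus '", loc, "' has > 999 distinct alleles; cannot encode",
           call. = FALSE)
    }
    alleles
  })
  names(maps) <- table$loci
  code <- function(loc, bp) {
    ifelse(is.na(bp), "000",
           sprintf("%03d", match(bp, maps[[loc]])))
  }
  lines <- c(title, table$loci, "Pop")
  for (i in seq_along(table$individuals)) {
    gts <- vapply(table$loci, function(loc) {
      paste0(code(loc, table$allele1[i, loc]),
             code(loc, table$allele2[i, loc]))
    }, character(1))
    lines <- c(lines, paste0(table$individuals[i], " , ",
                             paste(gts, collapse = " ")))
  }
  writeLines(lines, path)
  map_df <- do.call(rbind, lapply(table$loci, function(loc) {
    if (!length(maps[[loc]])) return(NULL)
    data.frame(locus = loc, code = sprintf("%03d", seq_along(maps[[loc]])),
               bp = maps[[loc]], stringsAsFactors = FALSE)
  }))
  utils::write.table(map_df, allele_map, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_genotypes_genepop <- function(path, panel, allele_map) {
  if (!file.exists(allele_map)) {
    stop("allele map not found: ", allele_map, call. = FALSE)
  }
  map <- utils::read.table(allele_map, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "integer"))
  lines <- readLines(path)
  pop_at <- which(trimws(lines) %in% c("Pop", "POP", "pop"))[1]
  if (is.na(pop_at)) stop("no 'Pop' line in GenePop file", call. = FALSE)
  loci <- trimws(lines[2:(pop_at - 1)])
  # allow the comma-separated single-line locus list variant
  if (length(loci) == 1 && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  unknown <- setdiff(loci, panel$name)
  if (length(unknown)) {
    stop("loci not in panel: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  body <- lines[(pop_at + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  decode <- function(loc, code) {
    if (code == "000") return(NA_integer_)
    hit <- map$bp[map$locus == loc & map$code == code]
    if (!length(hit)) {
      stop(sprintf("code '%s' at locus '%s' missing from allele map",
                   code, loc), call. = FALSE)
    }
    hit
  }
  ids <- character(length(body))
  a1 <- a2 <- matrix(NA_integer_, length(body), length(loci),
                     dimnames = list(NULL, loci))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], ",")[[1]]
    if (length(parts) != 2) {
      stop("malformed GenePop individual line ", i + pop_at, call. = FALSE)
    }
    ids[i] <- trimws(parts[1])
    gts <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(gts) != length(loci)) {
      stop(sprintf("line %d: expected %d genotypes, found %d",
                   i + pop_at, length(loci), length(gts)), call. = FALSE)
    }
    for (j in seq_along(loci)) {
      if (!grepl("^[0-9]{6}$", gts[j])) {
        stop(sprintf("line %d: malformed genotype '%s'", i + pop_at, gts[j]),
             call. = FALSE)
      }
      a1[i, j] <- decode(loci[j], substr(gts[j], 1, 3))
      a2[i, j] <- decode(loci[j], substr(gts[j], 4, 6))
    }
  }
  genotype_table(ids, a1, a2, panel)
}

#' Per-locus allele frequencies
#'
#' Frequencies are allele-copy counts divided by the number of non-missing
#' gene copies at each locus, optionally restricted to a subset of
#' individuals. Loci with no non-missing call in the (sub)sample are dropped
#' with a warning.
#'
#' @param table A [genotype_table()].
#' @param individuals Optional character vector restricting the sample.
#' @return An `allele_freq_table`: named list per locus with components
#'   `freq` (named numeric, names = allele bp) and `n_copies`.
#' @export
allele_frequencies <- function(table, individuals = NULL) {
  if (is.null(individuals)) individuals <- table$individuals
  missing_ids <- setdiff(individuals, table$individuals)
  if (length(missing_ids)) {
    stop("ids not in table: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (loc in table$loci) {
    copies <- c(table$allele1[individuals, loc],
                table$allele2[individuals, loc])
    copies <- copies[!is.na(copies)]
    if (!length(copies)) {
      warning("locus '", loc, "' has no non-missing calls; excluded",
              call. = FALSE)
      next
    }
    tab <- table(copies)
    out[[loc]] <- list(freq = as.numeric(tab) / length(copies),
                       n_copies = length(copies))
    names(out[[loc]]$freq) <- names(tab)
  }
  structure(out, class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("Allele frequencies for", length(x), "loci\n")
  for (loc in names(x)) {
    cat(sprintf("  %-10s %d alleles, %d gene copies\n",
                loc, length(x[[loc]]$freq), x[[loc]]$n_copies))
  }
  invisible(x)
}

#' Mendelian consistency of a family trio
#'
#' A locus is consistent when the offspring's two alleles can be split into
#' one allele present in the dam and one present in the sire. Loci with a
#' missing call in any of the three individuals are marked untestable.
#' Inconsistent loci flag candidate null alleles or typing errors.
#'
#' @param table A [genotype_table()] containing all three individuals.
#' @param foal,dam,sire Individual ids.
#' @return A data.frame with columns `locus`, `testable`, `consistent`
#'   (`NA` when untestable).
#' @export
check_trio_consistency <- function(table, foal, dam, sire) {
  for (id in c(foal, dam, sire)) {
    if (!id %in% table$individuals) {
      stop("id not in table: ", id, call. = FALSE)
    }
  }
  res <- data.frame(locus = table$loci, testable = FALSE,
                    consistent = NA, stringsAsFactors = FALSE)
  for (k in seq_along(table$loci)) {
    loc <- table$loci[k]
    f <- genotype_call(table, foal, loc)
    d <- genotype_call(table, dam, loc)
    s <- genotype_call(table, sire, loc)
    if (is.null(f) || is.null(d) || is.null(s)) next
    res$testable[k] <- TRUE
    res$consistent[k] <- (f[1] %in% d && f[2] %in% s) ||
                         (f[2] %in% d && f[1] %in% s)
  }
  res
}
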