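#' Run the full mare-foal MHC analysis
#'
#' Orchestrates every stage of the study analysis on validated inputs:
#' locus quality control (heterozygosity, Hardy-Weinberg exact tests,
#' null-allele estimates, optional pairwise genotypic LD), mare-foal
#' compatibility classification for both MHC classes with a Table-style
#' tabulation, the logistic regression of RFM on compatibility,
#' Queller-Goodnight relatedness with group summaries and a pooled
#' t-test (documented by a Shapiro-Wilk normality check of r_xy), the
#' Clopper-Pearson incidence interval, and — when a pedigree is supplied —
#' inbreeding coefficients with a Mann-Whitney group comparison.
#'
#' @param genotypes A [genotype_table()] (or path to a genotype CSV).
#' @param pairs Data.frame `mare_id`, `foal_id`, `rfm` (or path to CSV).
#' @param pedigree Optional [pedigree()] (or path to a pedigree CSV).
#' @param panel A [locus_panel()]; used when reading `genotypes` from file.
#' @param seed Seed for the stochastic stages (Monte-Carlo HWE, LD).
#' @param ld Logical: also run all pairwise genotypic LD tests (slower).
#' @param freqs Optional reference [allele_frequencies()] for r_xy
#'   (default: pooled over all genotyped individuals).
#' @return A `study_report` list with sections `incidence`, `qc`, `ld`,
#'   `compatibility` (calls + counts), `logistic`, `relatedness`,
#'   `inbreeding` (or `NULL`) and `meta`.
#' @export
run_full_analysis <- function(genotypes, pairs, pedigree = NULL,
                              panel = default_mhc_panel(), seed = 42L,
                              ld = FALSE, freqs = NULL) {
  meta <- list(seed = seed, package_version =
                 as.character(utils::packageVersion("placmatch")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               input_hashes = list())
  if (is.character(genotypes)) {
    meta$input_hashes$genotypes <- unname(tools::md5sum(genotypes))
    genotypes <- read_genotypes(genotypes, "csv", panel)
  }
  if (is.character(pairs)) {
    meta$input_hashes$pairs <- unname(tools::md5sum(pairs))
    pairs <- utils::read.csv(pairs, stringsAsFactors = FALSE)
    pairs$rfm <- as.logical(pairs$rfm)
  }
  if (is.character(pedigree)) {
    meta$input_hashes$pedigree <- unname(tools::md5sum(pedigree))
    pedigree <- read_pedigree(pedigree)
  }
  validate_pairs(pairs, genotypes)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  incidence <- stage("incidence",
                     clopper_pearson(sum(pairs$rfm), nrow(pairs)))
  qc <- stage("qc", locus_qc(genotypes, seed = seed))
  ld_tab <- NULL
  if (ld) {
    ld_tab <- stage("ld", {
      combos <- utils::combn(genotypes$loci, 2)
      do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
        res <- ld_genotypic_test(genotypes, combos[1, k], combos[2, k],
                                 seed = sub_seed(seed, 100 + k))
        data.frame(locus_a = combos[1, k], locus_b = combos[2, k],
                   G = res$G, p = res$p, testable = res$testable,
                   stringsAsFactors = FALSE)
      }))
    })
  }
  calls <- stage("classify", classify_pairs(genotypes, pairs))
  counts <- stage("tabulate", tabulate_compatibility(calls))
  logistic <- stage("logistic", fit_rfm_logistic(calls))
  rxy <- stage("relatedness", pairwise_relatedness(genotypes, pairs, freqs))
  rxy_summary <- stage("relatedness", group_relatedness_summary(rxy))
  shapiro <- if (nrow(rxy) >= 3 && stats::sd(rxy$r_xy) > 0) {
    stats::shapiro.test(rxy$r_xy)$p.value
  } else NA_real_
  rxy_test <- stage("relatedness",
                    students_t_test(rxy$r_xy[rxy$rfm], rxy$r_xy[!rxy$rfm]))
  inbreeding <- NULL
  if (!is.null(pedigree)) {
    inbreeding <- stage("inbreeding", {
      f <- inbreeding_coefficient(pedigree,
                                  unique(c(pairs$mare_id, pairs$foal_id)))
      list(F = f, comparison = inbreeding_group_comparison(f, pairs))
    })
  }
  structure(list(incidence = incidence, qc = qc, ld = ld_tab,
                 compatibility = list(calls = calls, counts = counts),
                 logistic = logistic,
                 relatedness = list(per_pair = rxy, summary = rxy_summary,
                                    t_test = rxy_test,
                                    shapiro_p = shapiro),
                 inbreeding = inbreeding, meta = meta),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}

#' Render a study report as Markdown
#'
#' @param report A [run_full_analysis()] result.
#' @return Character vector of Markdown lines.
#' @export
render_report_md <- function(report) {
  out <- c("# Mare-foal MHC compatibility study report", "")
  ci <- report$incidence
  out <- c(out, "## Incidence of RFM",
           sprintf("%d/%d mares (%.0f%%); Clopper-Pearson %.3f (%.0f%% CI %.3f-%.3f)",
                   ci$x, ci$n, 100 * ci$point, ci$point, 100 * ci$level,
                   ci$lower, ci$upper), "")
  out <- c(out, "## Locus QC",
           "| locus | n | H_obs | H_exp | HWE p | null (S-A) |",
           "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(report$qc))) {
    q <- report$qc[i, ]
    out <- c(out, sprintf("| %s | %d | %.2f | %.2f | %.4f | %.3f |",
                          q$locus, q$n, q$H_obs, q$H_exp, q$hwe_p,
                          q$null_summers_amos))
  }
  out <- c(out, "", "## Compatibility by group and MHC class",
           "| group | class | MC | FC | MFC | NC |", "|---|---|---|---|---|---|")
  cnt <- report$compatibility$counts
  for (g in unique(cnt$group)) for (cl in c("I", "II")) {
    row <- cnt[cnt$group == g & cnt$mhc_class == cl, ]
    cells <- vapply(c("MC", "FC", "MFC", "NC"), function(cat) {
      sprintf("%d (%d)", row$n[row$category == cat],
              row$pct[row$category == cat])
    }, character(1))
    out <- c(out, sprintf("| %s (n = %d) | MHC %s | %s |", g,
                          row$group_n[1], cl, paste(cells, collapse = " | ")))
  }
  s <- report$logistic$summary
  out <- c(out, "", "## Logistic regression of RFM on compatibility",
           "| term | estimate | SE | OR | 95% CI | p |", "|---|---|---|---|---|---|")
  t <- report$logistic$terms
  for (i in seq_len(nrow(t))) {
    out <- c(out, sprintf("| %s | %.2f | %.2f | %.2f | %.2f-%.2f | %.2f |",
                          t$term[i], t$estimate[i], t$se[i], t$OR[i],
                          t$ci_lower[i], t$ci_upper[i], t$p[i]))
  }
  out <- c(out, sprintf(
    "deviance %.2f (null %.2f), AIC %.2f, BIC %.2f, LR X2 %.2f (p = %.2f), McFadden %.2f, Cox-Snell %.2f, Nagelkerke %.2f, Tjur %.2f",
    s$deviance_model, s$deviance_null, s$AIC, s$BIC, s$LR_chi2, s$LR_p,
    s$mcfadden, s$cox_snell, s$nagelkerke, s$tjur), "")
  rs <- report$relatedness$summary
  tt <- report$relatedness$t_test
  out <- c(out, "## Relatedness (Queller-Goodnight r_xy)")
  for (i in seq_len(nrow(rs))) {
    out <- c(out, sprintf("- %s: mean %.2f +/- %.2f (n = %d)", rs$group[i],
                          rs$mean[i], rs$sd[i], rs$n[i]))
  }
  out <- c(out, sprintf("- t = %.2f (df %d), p = %.2f; Shapiro-Wilk p = %.2f",
                        tt$t, tt$df, tt$p, report$relatedness$shapiro_p), "")
  if (!is.null(report$inbreeding)) {
    out <- c(out, "## Inbreeding coefficients")
    for (who in c("mares", "foals")) {
      cmp <- report$inbreeding$comparison[[who]]
      out <- c(out, sprintf(
        "- %s: RFM median %.3f (IQR %.3f), control median %.3f (IQR %.3f); U = %g, p = %.2f",
        who, cmp$rfm$median, cmp$rfm$iqr, cmp$control$median,
        cmp$control$iqr, cmp$test$U, cmp$test$p))
    }
    out <- c(out, "")
  }
  out <- c(out, sprintf("_seed %s, placmatch %s_", report$meta$seed,
                        report$meta$package_version))
  out
}

#' Serialise a study report to JSON
#'
#' Writes a machine-readable report; [jsonlite::read_json()] restores the
#' same numbers.
#'
#' @param report A [run_full_analysis()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  r <- report
  r$logistic <- list(terms = r$logistic$terms, summary = r$logistic$summary)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
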