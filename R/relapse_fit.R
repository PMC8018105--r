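#' Fit the paired primary-vs-relapse methylome comparison
#'
#' The package's central estimator. Given an aligned dataset (betas, probe
#' annotation, sample sheet, optional intensities), it
#' \enumerate{
#'   \item forms one primary/relapse pair per patient,
#'   \item tests every probe's mean paired M-value difference against zero
#'     (ordinary or empirical-Bayes moderated paired t, BH-adjusted), for
#'     the whole cohort and within each molecular subgroup,
#'   \item compares mean beta values between primary and relapse per
#'     CpG-island substructure (islands, shores, shelves),
#'   \item decomposes probes significant at `alpha` into hypo- and
#'     hypermethylated fractions per substructure, and
#'   \item when intensities are present, computes per-patient copy-number
#'     log2 ratios and selects the `top_k` most variable loci.
#' }
#'
#' @param dataset a `meth_dataset` from [align_inputs()],
#'   [simulate_dataset()] or [read_fixture()].
#' @param alpha significance level for the fraction decomposition.
#' @param policy pairing policy, see [make_pairs()].
#' @param moderate empirical-Bayes variance moderation for the probe test?
#' @param test_mode substructure test, see [substructure_status()].
#' @param per_subgroup also run the probe test and fractions per subgroup?
#' @param top_k loci kept for the CNV view (default 1000).
#' @param cnv_criterion locus ranking, see [top_k_loci()].
#' @param variance_floor,epsilon see [run_dmp()].
#' @return object of class `relapse_fit`: list with elements `pairs`,
#'   `partition`, `group_means`, `dmp` (cohort table; per-subgroup tables
#'   under `dmp_subgroups`), `substructure`, `fractions` (cohort;
#'   per-subgroup under `fractions_subgroups`), `cnv` (or `NULL`), `alpha`
#'   and the matched `call`.
#' @seealso [summary.relapse_fit()], [plot.relapse_fit()]
#' @export
relapse_fit <- function(dataset, alpha = 0.05,
                        policy = c("first_relapse", "all_relapses_averaged"),
                        moderate = FALSE,
                        test_mode = c("paired_over_probes",
                                      "welch_over_probes"),
                        per_subgroup = TRUE, top_k = 1000,
                        cnv_criterion = "variance",
                        variance_floor = 1e-8, epsilon = 1e-3) {
  policy <- match.arg(policy)
  test_mode <- match.arg(test_mode)
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0,1)")
  pairs <- make_pairs(dataset$sheet, policy = policy)
  partition <- partition_probes(dataset$annotation)
  gm <- group_means(dataset$beta, dataset$sheet,
                    by_subgroup = per_subgroup)

  m <- beta_to_m(dataset$beta, epsilon = epsilon)
  dmp <- dmp_table(m, pairs, moderate, variance_floor)
  dmp_sub <- NULL
  frac_sub <- NULL
  if (per_subgroup) {
    dmp_sub <- lapply(split(seq_len(nrow(pairs)), pairs$subgroup),
                      function(idx) {
                        if (length(idx) < 2) return(dmp_empty_table())
                        dmp_table(m, pairs[idx, , drop = FALSE], moderate,
                                  variance_floor)
                      })
    frac_sub <- lapply(dmp_sub, function(tab) {
      if (nrow(tab) == 0) return(NULL)
      suppressWarnings(fraction_analysis(tab, partition, alpha = alpha))
    })
  }
  status <- substructure_status(gm, partition, test_mode = test_mode)
  status_sub <- NULL
  if (per_subgroup) {
    status_sub <- lapply(gm$subgroups, substructure_status,
                         partition = partition, test_mode = test_mode)
  }
  fractions <- suppressWarnings(fraction_analysis(dmp, partition,
                                                  alpha = alpha))
  cnv <- NULL
  if (!is.null(dataset$intensities)) {
    totals <- total_intensity(dataset$intensities)
    full <- patient_logfc(totals, pairs, dataset$annotation)
    top <- top_k_loci(full, k = top_k, criterion = cnv_criterion)
    summ <- cnv_report(top, dataset$sheet)
    cnv <- list(logfc = full, top = top, summary = summ)
  }
  structure(list(
    pairs = pairs, partition = partition, group_means = gm,
    dmp = dmp, dmp_subgroups = dmp_sub,
    substructure = status, substructure_subgroups = status_sub,
    fractions = fractions, fractions_subgroups = frac_sub,
    cnv = cnv, alpha = alpha, policy = policy, test_mode = test_mode,
    moderate = moderate, call = match.call()
  ), class = "relapse_fit")
}

#' @export
print.relapse_fit <- function(x, ...) {
  cat("Paired primary-vs-relapse methylome comparison\n")
  cat(sprintf("  %d probes (%d mapped), %d patient pairs, policy %s\n",
              x$partition$n_total, x$partition$n_total - x$partition$n_undefined,
              nrow(x$pairs), x$policy))
  n_raw <- sum(x$dmp$p_raw < x$alpha, na.rm = TRUE)
  n_adj <- sum(x$dmp$p_adj < x$alpha, na.rm = TRUE)
  cat(sprintf("  probes with p < %.3g: %d raw, %d BH-adjusted\n",
              x$alpha, n_raw, n_adj))
  cat(sprintf("  CNV: %s\n", if (is.null(x$cnv)) "not computed (no intensities)"
              else sprintf("top %d loci", nrow(x$cnv$top))))
  invisible(x)
}

#' Summarize a relapse fit
#'
#' @param object a [relapse_fit()] result.
#' @param ... unused.
#' @return `summary.relapse_fit` object: significance counts, substructure
#'   status rows, fraction table and CNV subgroup summary.
#' @export
summary.relapse_fit <- function(object, ...) {
  tot <- attr(object$fractions, "totals")
  out <- list(
    n_pairs = nrow(object$pairs),
    partition_counts = object$partition$counts,
    n_sig_raw = sum(object$dmp$p_raw < object$alpha, na.rm = TRUE),
    n_sig_adj = sum(object$dmp$p_adj < object$alpha, na.rm = TRUE),
    alpha = object$alpha,
    substructure = object$substructure,
    fractions = object$fractions,
    fraction_totals = tot,
    cnv_summary = if (is.null(object$cnv)) NULL else object$cnv$summary
  )
  class(out) <- "summary.relapse_fit"
  out
}

#' @export
print.summary.relapse_fit <- function(x, ...) {
  cat(sprintf("Pairs: %d;  probes with raw p < %.3g: %d (BH: %d)\n",
              x$n_pairs, x$alpha, x$n_sig_raw, x$n_sig_adj))
  cat("\nSubstructure methylation status (mean beta):\n")
  print(format(x$substructure, digits = 4), row.names = FALSE)
  cat("\nHypo/hyper fractions of significant probes (%):\n")
  print(format(x$fractions, digits = 4), row.names = FALSE)
  if (!is.null(x$cnv_summary)) {
    cat("\nCNV per-subgroup summary (top loci):\n")
    print(format(x$cnv_summary, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Per-probe paired M-value differences (logFC) of a fit
#'
#' @param object a [relapse_fit()].
#' @param ... unused.
#' @return named vector of cohort logFC values.
#' @export
coef.relapse_fit <- function(object, ...) {
  stats::setNames(object$dmp$logFC, object$dmp$probe_id)
}

#' Plot a relapse fit
#'
#' `type = "fractions"` draws the per-substructure hypo/hyper percentage
#' bars; `type = "substructure"` the primary vs relapse mean betas per
#' substructure; `type = "volcano"` the probe-level logFC vs -log10 p.
#'
#' @param x a [relapse_fit()].
#' @param type which view.
#' @param ... passed to the underlying graphics call.
#' @return `x`, invisibly.
#' @export
plot.relapse_fit <- function(x, type = c("fractions", "substructure",
                                         "volcano"), ...) {
  type <- match.arg(type)
  if (type == "fractions") {
    f <- x$fractions
    h <- rbind(hypo = f$pct_hypo, hyper = f$pct_hyper)
    colnames(h) <- f$substructure
    graphics::barplot(h, beside = TRUE, col = c("steelblue", "firebrick"),
                      ylab = "% of class", las = 2,
                      legend.text = c("hypomethylated", "hypermethylated"),
                      ...)
  } else if (type == "substructure") {
    s <- x$substructure
    h <- rbind(primary = s$mean_primary, relapse = s$mean_relapse)
    colnames(h) <- s$substructure
    graphics::barplot(h, beside = TRUE, col = c("grey60", "firebrick"),
                      ylab = "mean beta", las = 2,
                      legend.text = c("primary", "relapse"), ...)
  } else {
    graphics::plot(x$dmp$logFC, -log10(x$dmp$p_raw), pch = ".",
                   xlab = "logFC (paired M difference)",
                   ylab = "-log10 raw p", ...)
    graphics::abline(h = -log10(x$alpha), lty = 2)
  }
  invisible(x)
}
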