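#' Partition probes into epigenomic substructures
#'
#' Total, disjoint partition of the annotated probes into the six
#' categories; `UNDEFINED` (unmapped/open sea) probes are counted but
#' excluded from downstream substructure analyses.
#'
#' @param annotation a [probe_annotation()] table.
#' @return list of class `substructure_partition` with `map` (named factor
#'   probe_id -> substructure), `counts` (all six categories), `n_undefined`
#'   and `n_total`.
#' @export
partition_probes <- function(annotation) {
  map <- annotation$substructure
  names(map) <- annotation$probe_id
  counts <- table(factor(map, levels = SUBSTRUCTURES))
  structure(list(
    map = map,
    counts = stats::setNames(as.integer(counts), names(counts)),
    n_undefined = as.integer(counts[["UNDEFINED"]]),
    n_total = length(map)
  ), class = "substructure_partition")
}

#' @export
print.substructure_partition <- function(x, ...) {
  cat(sprintf("substructure partition of %d probes:\n", x$n_total))
  print(x$counts)
  invisible(x)
}

#' Compare group mean betas between primary and relapse per substructure
#'
#' For each mapped substructure, the per-probe mean betas over primary and
#' over relapse samples (from [group_means()]) restricted to that
#' substructure are compared with a two-sided t-test: `"paired_over_probes"`
#' (default) pairs the two means of each probe; `"welch_over_probes"`
#' treats the two mean vectors as independent samples. Substructures with
#' fewer than 2 probes get a flagged row without a statistic.
#'
#' @param gm a [group_means()] result.
#' @param partition a [partition_probes()] result.
#' @param test_mode `"paired_over_probes"` or `"welch_over_probes"`.
#' @return `data.frame` of class `substructure_status`: one row per mapped
#'   substructure with `mean_primary`, `mean_relapse`, `t_stat`, `p_value`,
#'   `n_probes`, `flagged`.
#' @export
substructure_status <- function(gm, partition,
                                test_mode = c("paired_over_probes",
                                              "welch_over_probes")) {
  test_mode <- match.arg(test_mode)
  probes <- names(partition$map)
  if (all(partition$map == "UNDEFINED"))
    stop_validation("no mapped probes: all probes are UNDEFINED")
  rows <- lapply(MAPPED_SUBSTRUCTURES, function(ss) {
    idx <- probes[partition$map == ss]
    x <- gm$primary[idx]
    y <- gm$relapse[idx]
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 2) {
      return(data.frame(substructure = ss, mean_primary = mean(x),
                        mean_relapse = mean(y), t_stat = NA_real_,
                        p_value = NA_real_, n_probes = n, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    ht <- if (test_mode == "paired_over_probes") {
      if (stats::sd(y - x) == 0) {
        list(statistic = 0, p.value = 1)  # identical mean profiles
      } else stats::t.test(y, x, paired = TRUE)
    } else {
      if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
        list(statistic = 0, p.value = 1)
      } else stats::t.test(y, x, var.equal = FALSE)
    }
    data.frame(substructure = ss, mean_primary = mean(x),
               mean_relapse = mean(y),
               t_stat = unname(ht$statistic), p_value = ht$p.value,
               n_probes = n, flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "test_mode") <- test_mode
  class(out) <- c("substructure_status", "data.frame")
  out
}

#' Classify probes as hypo-/hypermethylated by the sign of logFC
#'
#' Probes with negative logFC (relapse less methylated than primary) are
#' `HYPO`, positive logFC `HYPER`; an exact zero falls in neither class
#' (`NONE`) and is excluded from fraction denominators.
#'
#' @param logFC signed M-scale paired differences (finite).
#' @return factor with levels `HYPO`, `HYPER`, `NONE`.
#' @export
classify_probe <- function(logFC) {
  if (any(!is.finite(logFC)))
    stop_domain("logFC must be finite")
  factor(ifelse(logFC < 0, "HYPO", ifelse(logFC > 0, "HYPER", "NONE")),
         levels = c("HYPO", "HYPER", "NONE"))
}

#' Hypo-/hypermethylated fractions per substructure
#'
#' Selects probes significant at `alpha` (raw p by default, matching the
#' screening use of unadjusted p-values; adjusted on request), drops
#' `UNDEFINED` probes, classifies the rest by the sign of logFC, and
#' reports per-substructure percentages of (a) all selected probes,
#' (b) hypomethylated and (c) hypermethylated probes, alongside the counts.
#'
#' @param dmp a `dmp_table` from [run_dmp()].
#' @param partition a [partition_probes()] result.
#' @param alpha significance level (default 0.05).
#' @param use_adjusted select on `p_adj` instead of `p_raw`?
#' @return `data.frame` of class `fraction_table`: one row per mapped
#'   substructure with counts `n_selected`, `n_hypo`, `n_hyper` and
#'   percentages `pct_all`, `pct_hypo`, `pct_hyper`. Totals (including the
#'   count of zero-logFC probes excluded from the classes) are attached as
#'   attributes.
#' @export
fraction_analysis <- function(dmp, partition, alpha = 0.05,
                              use_adjusted = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0,1)")
  p <- if (use_adjusted) dmp$p_adj else dmp$p_raw
  sel <- !is.na(p) & p < alpha
  ss <- partition$map[dmp$probe_id]
  mapped <- !is.na(ss) & ss != "UNDEFINED"
  sel <- sel & mapped
  if (!any(sel)) {
    warning("no significant probes selected", call. = FALSE)
    out <- data.frame(substructure = MAPPED_SUBSTRUCTURES, n_selected = 0L,
                      n_hypo = 0L, n_hyper = 0L, pct_all = NA_real_,
                      pct_hypo = NA_real_, pct_hyper = NA_real_,
                      stringsAsFactors = FALSE)
    class(out) <- c("fraction_table", "data.frame")
    return(out)
  }
  cls <- classify_probe(dmp$logFC[sel])
  sub <- factor(as.character(ss[sel]), levels = MAPPED_SUBSTRUCTURES)
  n_sel <- table(sub)
  n_hypo <- table(sub[cls == "HYPO"])
  n_hyper <- table(sub[cls == "HYPER"])
  pct <- function(cnt) {
    tot <- sum(cnt)
    if (tot == 0) rep(NA_real_, length(cnt)) else 100 * as.numeric(cnt) / tot
  }
  out <- data.frame(
    substructure = MAPPED_SUBSTRUCTURES,
    n_selected = as.integer(n_sel),
    n_hypo = as.integer(n_hypo),
    n_hyper = as.integer(n_hyper),
    pct_all = pct(n_sel),
    pct_hypo = pct(n_hypo),
    pct_hyper = pct(n_hyper),
    stringsAsFactors = FALSE
  )
  attr(out, "totals") <- list(
    selected = sum(out$n_selected),
    hypo = sum(out$n_hypo),
    hyper = sum(out$n_hyper),
    none = sum(cls == "NONE"),
    alpha = alpha,
    use_adjusted = use_adjusted
  )
  class(out) <- c("fraction_table", "data.frame")
  out
}
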