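#' Form primary/relapse pairs per patient
#'
#' Builds one (primary, relapse) pair per patient. With policy
#' `"first_relapse"` the relapse member is the sample with the smallest
#' relapse index; with `"all_relapses_averaged"` a patient's relapse
#' values are averaged over all of that patient's relapse samples
#' downstream. Patients lacking a primary or a relapse sample are dropped
#' and counted.
#'
#' @param sheet a [sample_sheet()].
#' @param policy pairing policy.
#' @return `data.frame` of class `pairing` with columns `patient_id`,
#'   `subgroup`, `primary` (sample id) and a list column `relapse`
#'   (character vector of relapse sample ids per patient; length 1 under
#'   `first_relapse`). The number of dropped patients is in the
#'   `n_dropped` attribute.
#' @export
make_pairs <- function(sheet,
                       policy = c("first_relapse", "all_relapses_averaged")) {
  policy <- match.arg(policy)
  by_pat <- split(seq_len(nrow(sheet)), sheet$patient_id)
  rows <- lapply(by_pat, function(idx) {
    s <- sheet[idx, ]
    prim <- s$sample_id[s$status == "PRIMARY"]
    rel <- s[s$status == "RELAPSE", ]
    if (length(prim) == 0 || nrow(rel) == 0) return(NULL)
    rel <- rel[order(rel$relapse_index), ]
    list(patient_id = s$patient_id[1], subgroup = s$subgroup[1],
         primary = prim[1],
         relapse = if (policy == "first_relapse") rel$sample_id[1]
                   else rel$sample_id)
  })
  kept <- !vapply(rows, is.null, logical(1))
  if (!any(kept)) stop_validation("no complete primary/relapse pairs")
  rows <- rows[kept]
  out <- data.frame(
    patient_id = vapply(rows, `[[`, "", "patient_id"),
    subgroup = vapply(rows, `[[`, "", "subgroup"),
    primary = vapply(rows, `[[`, "", "primary"),
    stringsAsFactors = FALSE
  )
  out$relapse <- lapply(rows, `[[`, "relapse")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!kept)
  attr(out, "policy") <- policy
  class(out) <- c("pairing", "data.frame")
  out
}

#' Per-pair differences of a probes x samples matrix
#'
#' For each pair, relapse minus primary; under the averaging policy the
#' relapse member is the mean over the patient's relapse samples
#' (pairwise-complete).
#'
#' @param m probes x samples matrix (typically M values).
#' @param pairs a [make_pairs()] result.
#' @return probes x patients matrix of differences.
#' @export
paired_differences <- function(m, pairs) {
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    rel <- m[, pairs$relapse[[i]], drop = FALSE]
    rowMeans(rel, na.rm = TRUE) - m[, pairs$primary[i]]
  }, numeric(nrow(m)))
  d <- matrix(d, nrow = nrow(m),
              dimnames = list(rownames(m), pairs$patient_id))
  d[is.nan(d)] <- NA_real_
  d
}

#' Vectorized one-sample (paired) t statistics over probes
#'
#' For each row of `d` (per-pair differences for one probe), computes the
#' mean difference (logFC), the one-sample t statistic against zero with a
#' variance floor, degrees of freedom, and the two-sided Student-t p-value.
#' Rows with fewer than 2 non-missing differences get `NA` statistics and
#' are flagged. A row with mean 0 and variance 0 yields t = 0, p = 1.
#'
#' @param d probes x pairs matrix of differences (a vector is treated as a
#'   single probe).
#' @param variance_floor lower bound on the sample variance (default 1e-8)
#'   so constant probes do not produce infinite t.
#' @return `data.frame` with columns `logFC`, `t_stat`, `df`, `p_raw`,
#'   `n_pairs`.
#' @export
paired_t <- function(d, variance_floor = 1e-8) {
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  n <- rowSums(!is.na(d))
  mean_d <- rowMeans(d, na.rm = TRUE)
  mean_d[n == 0] <- NA_real_
  ss <- rowSums((d - mean_d)^2, na.rm = TRUE)
  s2 <- ifelse(n > 1, ss / (n - 1), NA_real_)
  s2f <- pmax(s2, variance_floor)
  tt <- mean_d / sqrt(s2f / n)
  df <- n - 1
  p <- 2 * stats::pt(-abs(tt), df)
  bad <- n < 2
  tt[bad] <- NA_real_; p[bad] <- NA_real_
  if (any(bad))
    message(sprintf("%d probe(s) with < 2 complete pairs excluded", sum(bad)))
  data.frame(probe_id = rownames(d) %||% as.character(seq_len(nrow(d))),
             logFC = mean_d, t_stat = tt, df = ifelse(bad, NA, df),
             p_raw = p, n_pairs = n, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function (solve trigamma(y) = x)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes shrinkage of per-probe variances
#'
#' Fits the scaled-inverse-chi-square prior `s^2 ~ s0^2 * chisq(d0)/d0` by
#' moment matching on the log variances (mean and variance of
#' `log s^2`, corrected by digamma/trigamma terms) and returns the
#' posterior variances `(d0*s0^2 + df*s^2) / (d0 + df)`. A moderated t
#' built on these gains `d0` degrees of freedom. If moment matching yields
#' a non-finite prior df, the prior collapses to a point
#' (`d0 = Inf`, all posterior variances `s0^2`) with a warning.
#'
#' @param s2 per-probe sample variances (> 0; apply a variance floor first).
#' @param df per-probe residual degrees of freedom (>= 1), scalar or vector.
#' @return list with `d0` (prior df), `s0_2` (prior variance) and
#'   `s2_post` (posterior variances).
#' @export
moderate_variances <- function(s2, df) {
  df <- rep(df, length.out = length(s2))
  ok <- is.finite(s2) & df >= 1
  if (sum(ok) < 10)
    stop_validation("need >= 10 probes with df >= 1 for moderation")
  if (all(s2[ok] == 0))
    stop_validation("all variances are zero; increase variance_floor")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2) * n / (n - 1) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion: point prior at the average variance
    d0 <- Inf
    s0_2 <- mean(s2[ok])
  }
  if (!is.finite(d0)) {
    if (!identical(d0, Inf)) {
      warning("moment matching gave a non-finite prior df; using d0 = Inf",
              call. = FALSE)
      d0 <- Inf
    }
    s2_post <- rep(s0_2, length(s2))
  } else {
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
  }
  s2_post[!ok] <- NA_real_
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Benjamini-Hochberg adjustment of raw p-values
#'
#' Step-up FDR adjustment: in sorted order,
#' `p_adj(i) = min over j >= i of m * p(j) / j`, capped at 1 and mapped
#' back to the input order. Delegates to [stats::p.adjust()].
#'
#' @param p_raw raw p-values in \[0,1\] (`NA` allowed, propagated).
#' @param method only `"bh"`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p_raw, method = c("bh")) {
  method <- match.arg(method)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop_domain("p-values must lie in [0,1]")
  stats::p.adjust(p_raw, method = "BH")
}

# per-probe paired DMP table on the M scale for one set of pairs
dmp_table <- function(m_values, pairs, moderate = FALSE,
                      variance_floor = 1e-8) {
  d <- paired_differences(m_values, pairs)
  tab <- suppressMessages(paired_t(d, variance_floor = variance_floor))
  if (moderate) {
    n <- tab$n_pairs
    ok <- n >= 2
    mean_d <- tab$logFC
    # recover floored variances from t: s2f = n * (logFC / t)^2; recompute directly
    ss <- rowSums((d - rowMeans(d, na.rm = TRUE))^2, na.rm = TRUE)
    s2 <- ifelse(n > 1, pmax(ss / (n - 1), variance_floor), NA_real_)
    mod <- moderate_variances(s2[ok], tab$df[ok])
    t_mod <- mean_d[ok] / sqrt(mod$s2_post / n[ok])
    df_mod <- tab$df[ok] + mod$d0
    tab$t_stat[ok] <- t_mod
    tab$df[ok] <- df_mod
    tab$p_raw[ok] <- 2 * stats::pt(-abs(t_mod), df_mod)
    attr(tab, "moderation") <- list(d0 = mod$d0, s0_2 = mod$s0_2)
  }
  tab$p_adj <- adjust_pvalues(tab$p_raw)
  n_excluded <- sum(tab$n_pairs < 2)
  attr(tab, "n_excluded") <- n_excluded
  class(tab) <- c("dmp_table", "data.frame")
  tab
}

#' Per-probe paired differential methylation (relapse vs primary)
#'
#' Converts betas to M values, forms per-patient pairs, and tests each
#' probe's mean paired M difference against zero with a (optionally
#' empirical-Bayes moderated) one-sample t, followed by Benjamini-Hochberg
#' adjustment. With `scope = "per_subgroup"` the analysis is repeated
#' within each molecular subgroup; subgroups with fewer than 2 complete
#' pairs yield an empty table with a warning.
#'
#' @param dataset a `meth_dataset`.
#' @param scope `"cohort"` or `"per_subgroup"`.
#' @param policy pairing policy, see [make_pairs()].
#' @param moderate use empirical-Bayes variance moderation?
#' @param variance_floor see [paired_t()].
#' @param epsilon beta clipping bound for the M conversion.
#' @return for `"cohort"`, a `dmp_table` data.frame (`probe_id`, `logFC`,
#'   `t_stat`, `df`, `p_raw`, `p_adj`, `n_pairs`); for `"per_subgroup"`, a
#'   named list of such tables.
#' @export
run_dmp <- function(dataset, scope = c("cohort", "per_subgroup"),
                    policy = "first_relapse", moderate = FALSE,
                    variance_floor = 1e-8, epsilon = 1e-3) {
  scope <- match.arg(scope)
  m <- beta_to_m(dataset$beta, epsilon = epsilon)
  pairs <- make_pairs(dataset$sheet, policy = policy)
  if (scope == "cohort")
    return(dmp_table(m, pairs, moderate, variance_floor))
  tabs <- lapply(split(seq_len(nrow(pairs)), pairs$subgroup), function(idx) {
    if (length(idx) < 2) {
      warning(sprintf("subgroup '%s' has < 2 complete pairs; empty table",
                      pairs$subgroup[idx[1]]), call. = FALSE)
      empty <- dmp_empty_table()
      return(empty)
    }
    dmp_table(m, pairs[idx, , drop = FALSE], moderate, variance_floor)
  })
  tabs
}

dmp_empty_table <- function() {
  tab <- data.frame(probe_id = character(0), logFC = numeric(0),
                    t_stat = numeric(0), df = numeric(0),
                    p_raw = numeric(0), n_pairs = integer(0),
                    p_adj = numeric(0), stringsAsFactors = FALSE)
  class(tab) <- c("dmp_table", "data.frame")
  tab
}
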