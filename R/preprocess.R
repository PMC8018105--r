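#' Convert beta values to M values
#'
#' The M value is the log2 ratio of methylated to unmethylated signal,
#' `log2(beta / (1 - beta))`. Betas are clipped into
#' `[epsilon, 1 - epsilon]` first so the logit stays finite at fully
#' (un)methylated probes.
#'
#' @param beta numeric vector/matrix of methylation fractions in \[0,1\].
#' @param epsilon clip bound before the logit (default 1e-3).
#' @return M values, same shape as `beta`; `NA` propagates.
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop_domain("beta values must lie in [0,1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}

#' Convert M values back to beta values
#'
#' Inverse logistic transform `2^m / (1 + 2^m)`; inverse of [beta_to_m()]
#' away from the clipping bound.
#'
#' @param m numeric vector/matrix of M values.
#' @return methylation fractions in (0,1).
#' @export
m_to_beta <- function(m) {
  # computed as plogis in base 2 for numerical stability at large |m|
  stats::plogis(m * log(2))
}

#' Per-probe mean beta by primary/relapse status
#'
#' Computes, for each probe, the arithmetic mean beta over all PRIMARY
#' samples and over all RELAPSE samples (pairwise-complete: missing values
#' are dropped per probe and the effective n recorded). With
#' `by_subgroup = TRUE` the computation is repeated within each molecular
#' subgroup.
#'
#' @param beta beta matrix (probes x samples).
#' @param sheet a [sample_sheet()] covering the matrix columns.
#' @param by_subgroup also return one result per subgroup?
#' @return list of class `group_mean_beta` with per-probe vectors
#'   `primary`, `relapse`, `n_primary`, `n_relapse`; when `by_subgroup`,
#'   an additional `subgroups` element holds one such list per subgroup.
#' @export
group_means <- function(beta, sheet, by_subgroup = FALSE) {
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$sample_id)))
    stop_validation("sample sheet does not cover all matrix columns")
  one <- function(cols_p, cols_r) {
    if (length(cols_p) == 0 || length(cols_r) == 0)
      stop_validation("a status group is empty")
    bp <- beta[, cols_p, drop = FALSE]
    br <- beta[, cols_r, drop = FALSE]
    structure(list(
      primary = rowMeans(bp, na.rm = TRUE),
      relapse = rowMeans(br, na.rm = TRUE),
      n_primary = rowSums(!is.na(bp)),
      n_relapse = rowSums(!is.na(br))
    ), class = "group_mean_beta")
  }
  res <- one(which(sheet$status == "PRIMARY"),
             which(sheet$status == "RELAPSE"))
  if (by_subgroup) {
    res$subgroups <- lapply(split(seq_len(nrow(sheet)), sheet$subgroup),
                            function(idx) {
                              s <- sheet[idx, ]
                              one(idx[s$status == "PRIMARY"],
                                  idx[s$status == "RELAPSE"])
                            })
  }
  res
}
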