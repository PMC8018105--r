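#' Total probe intensity
#'
#' Sum of the methylated and unmethylated channel per (probe, sample).
#' Probes with zero total in a sample carry no copy-number signal and are
#' dropped later by [patient_logfc()].
#'
#' @param intensities `list(methylated=, unmethylated=)` non-negative
#'   matrices of equal shape.
#' @return probes x samples matrix of totals.
#' @export
total_intensity <- function(intensities) {
  m <- intensities$methylated
  u <- intensities$unmethylated
  if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE))
    stop_domain("intensities must be non-negative")
  if (!identical(dim(m), dim(u)))
    stop_validation("methylated/unmethylated matrices differ in shape")
  m + u
}

#' Per-patient copy-number log2 ratios from total intensities
#'
#' For each paired patient and locus, `log2((I_relapse + c) / (I_primary +
#' c))` of total intensity, with pseudocount `c` guarding log of zero.
#' Under the averaging pairing policy a patient's relapse intensity is the
#' mean over their relapse samples. Loci with zero total in both pair
#' members are dropped with a message. By default each patient column is
#' median-centered so the genome-wide median log ratio is 0, removing
#' array-scale differences between the two hybridizations.
#'
#' @param totals probes x samples totals from [total_intensity()].
#' @param pairs a [make_pairs()] result.
#' @param annotation a [probe_annotation()] covering the rows (for genome
#'   ordering).
#' @param pseudocount added to both intensities (default 1).
#' @param center median-center each patient column? (default TRUE)
#' @return loci x patients matrix of class `cnv_matrix`, rows sorted by
#'   (chromosome, position); locus coordinates in the `loci` attribute.
#' @export
patient_logfc <- function(totals, pairs, annotation, pseudocount = 1,
                          center = TRUE) {
  if (nrow(pairs) < 1) stop_validation("no complete pairs")
  lfc <- vapply(seq_len(nrow(pairs)), function(i) {
    rel <- rowMeans(totals[, pairs$relapse[[i]], drop = FALSE], na.rm = TRUE)
    prim <- totals[, pairs$primary[i]]
    log2((rel + pseudocount) / (prim + pseudocount))
  }, numeric(nrow(totals)))
  lfc <- matrix(lfc, nrow = nrow(totals),
                dimnames = list(rownames(totals), pairs$patient_id))
  # drop loci with no signal in any pair member
  zero_both <- vapply(seq_len(nrow(pairs)), function(i) {
    rowMeans(totals[, pairs$relapse[[i]], drop = FALSE], na.rm = TRUE) == 0 &
      totals[, pairs$primary[i]] == 0
  }, logical(nrow(totals)))
  drop <- apply(matrix(zero_both, nrow = nrow(totals)), 1, all)
  if (any(drop)) {
    message(sprintf("%d locus/loci with zero total intensity dropped",
                    sum(drop)))
    lfc <- lfc[!drop, , drop = FALSE]
  }
  if (center) {
    med <- apply(lfc, 2, stats::median, na.rm = TRUE)
    lfc <- sweep(lfc, 2, med)
  }
  ann <- annotation[match(rownames(lfc), annotation$probe_id), , drop = FALSE]
  ord <- order(chrom_order(ann$chromosome), ann$position, rownames(lfc))
  lfc <- lfc[ord, , drop = FALSE]
  attr(lfc, "loci") <- data.frame(
    probe_id = rownames(lfc),
    chromosome = ann$chromosome[ord],
    position = ann$position[ord],
    stringsAsFactors = FALSE
  )
  attr(lfc, "centered") <- center
  class(lfc) <- c("cnv_matrix", class(lfc))
  lfc
}

#' Select the top-k most variable (or most extreme) loci
#'
#' Ranks loci by the chosen criterion — variance of the log ratio across
#' patients (default; highlights recurrent change) or maximum absolute log
#' ratio — and returns the top `k` in genome order. Ties are broken by
#' (chromosome, position), so the selection is deterministic.
#'
#' @param cnv a [patient_logfc()] matrix.
#' @param k number of loci (default 1000); if larger than available, all
#'   loci are returned with a warning.
#' @param criterion `"variance"` or `"max_abs"`.
#' @return `cnv_matrix` restricted to the selected loci, genome-ordered.
#' @export
top_k_loci <- function(cnv, k = 1000,
                       criterion = c("variance", "max_abs")) {
  criterion <- match.arg(criterion)
  if (k < 1) stop_validation("k must be >= 1")
  loci <- attr(cnv, "loci")
  score <- if (criterion == "variance") {
    apply(cnv, 1, stats::var, na.rm = TRUE)
  } else {
    apply(abs(cnv), 1, max, na.rm = TRUE)
  }
  if (k > nrow(cnv)) {
    warning(sprintf("k = %d exceeds %d available loci; returning all",
                    k, nrow(cnv)), call. = FALSE)
    k <- nrow(cnv)
  }
  ord <- order(-score, chrom_order(loci$chromosome), loci$position)
  keep <- sort(ord[seq_len(k)])  # back to genome order
  out <- cnv[keep, , drop = FALSE]
  attr(out, "loci") <- loci[keep, , drop = FALSE]
  attr(out, "centered") <- attr(cnv, "centered")
  attr(out, "criterion") <- criterion
  class(out) <- c("cnv_matrix", "matrix", "array")
  out
}

#' Per-subgroup copy-number summary and heatmap
#'
#' Groups patient columns by molecular subgroup, summarizes each
#' subgroup's mean absolute log2 ratio over the supplied loci, and
#' (optionally) draws a loci x patients heatmap with patients ordered and
#' gapped by subgroup and loci in genome order.
#'
#' @param cnv a `cnv_matrix` (typically [top_k_loci()] output).
#' @param sheet a [sample_sheet()] (subgroup lookup per patient).
#' @param file optional path for the heatmap (png); `NULL` skips drawing.
#' @return `data.frame` with per-subgroup `n_patients`, `mean_abs_logfc`,
#'   `mean_logfc`; the heatmap path (or `NA`) in the `figure` attribute.
#' @export
cnv_report <- function(cnv, sheet, file = NULL) {
  if (nrow(cnv) == 0) stop_validation("empty CNV matrix")
  pat_sub <- vapply(colnames(cnv), function(p) {
    hit <- sheet$subgroup[sheet$patient_id == p]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  if (any(is.na(pat_sub)))
    stop_validation("patient(s) missing from the sample sheet")
  groups <- split(seq_along(pat_sub), pat_sub)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    cols <- groups[[g]]
    data.frame(subgroup = g, n_patients = length(cols),
               mean_abs_logfc = mean(abs(cnv[, cols]), na.rm = TRUE),
               mean_logfc = mean(cnv[, cols], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  fig <- NA_character_
  if (!is.null(file)) {
    ord <- order(pat_sub, colnames(cnv))
    mat <- unclass(cnv)[, ord, drop = FALSE]
    gaps <- cumsum(table(pat_sub[ord]))
    gaps <- gaps[-length(gaps)]
    lim <- max(abs(mat), na.rm = TRUE)
    if (lim == 0) lim <- 1
    grDevices::png(file, width = 900, height = 700)
    pheatmap::pheatmap(
      t(mat), cluster_rows = FALSE, cluster_cols = FALSE,
      gaps_row = if (length(gaps)) gaps else NULL,
      show_colnames = FALSE,
      breaks = seq(-lim, lim, length.out = 101),
      color = grDevices::colorRampPalette(c("blue", "white", "red"))(100),
      main = sprintf("log2 intensity ratio, relapse vs primary (%d loci)",
                     nrow(mat))
    )
    grDevices::dev.off()
    fig <- file
  }
  attr(summ, "figure") <- fig
  summ
}
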