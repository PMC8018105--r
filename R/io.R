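#' Normalize substructure labels to the canonical six-category vocabulary
#'
#' Accepts the canonical labels (`ISLAND`, `N_SHORE`, `S_SHORE`, `N_SHELF`,
#' `S_SHELF`, `UNDEFINED`) plus common dialects: Illumina-manifest strings
#' (`"Island"`, `"N_Shore"`, `"S_Shelf"`, `"OpenSea"`, empty string) and the
#' `"N Shelve"`/`"S Shelve"` spelling. Unrecognized strings map to
#' `UNDEFINED` and the number of such probes is reported as a warning.
#'
#' @param x character vector of raw labels.
#' @return factor with levels [SUBSTRUCTURES].
#' @export
normalize_substructure <- function(x) {
  key <- toupper(gsub("[ _-]+", "_", trimws(as.character(x))))
  key[key == ""] <- "OPENSEA"
  map <- c(
    ISLAND = "ISLAND", CPG_ISLAND = "ISLAND",
    N_SHORE = "N_SHORE", S_SHORE = "S_SHORE",
    N_SHELF = "N_SHELF", S_SHELF = "S_SHELF",
    N_SHELVE = "N_SHELF", S_SHELVE = "S_SHELF",
    OPENSEA = "UNDEFINED", OPEN_SEA = "UNDEFINED",
    UNDEFINED = "UNDEFINED", UNMAPPED = "UNDEFINED", NONE = "UNDEFINED"
  )
  out <- unname(map[key])
  n_bad <- sum(is.na(out) & !is.na(x))
  if (n_bad > 0) {
    warning(sprintf("%d unknown substructure label(s) mapped to UNDEFINED",
                    n_bad), call. = FALSE)
    out[is.na(out) & !is.na(x)] <- "UNDEFINED"
  }
  factor(out, levels = SUBSTRUCTURES)
}

#' Construct and validate a probe annotation table
#'
#' @param probe_id character, unique probe identifiers.
#' @param chromosome character chromosome labels (`"chr1"`..`"chr22"`,
#'   `"chrX"`, `"chrY"`).
#' @param position 1-based base-pair coordinates, `>= 1`.
#' @param substructure labels coerced via [normalize_substructure()].
#' @return `data.frame` of class `probe_annotation` with columns
#'   `probe_id`, `chromosome`, `position`, `substructure`.
#' @export
probe_annotation <- function(probe_id, chromosome, position, substructure) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id))
    stop_validation("duplicate probe_id in annotation")
  position <- as.numeric(position)
  if (any(!is.finite(position) | position < 1))
    stop_validation("probe positions must be finite and >= 1")
  ann <- data.frame(
    probe_id = probe_id,
    chromosome = as.character(chromosome),
    position = position,
    substructure = normalize_substructure(substructure),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Read a probe annotation CSV
#'
#' Expects header columns `probe_id,chromosome,position,substructure`.
#' Unknown substructure strings are mapped to `UNDEFINED` with a warning.
#'
#' @param path CSV file path.
#' @return validated [probe_annotation()] table.
#' @export
read_probe_annotation <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_format("cannot parse annotation CSV '%s': %s",
                                    path, conditionMessage(e))
  )
  need <- c("probe_id", "chromosome", "position", "substructure")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_format("annotation '%s' missing column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0)
    stop_format("annotation '%s' contains no probes", path)
  probe_annotation(df$probe_id, df$chromosome, df$position, df$substructure)
}

#' Write a probe annotation CSV
#' @param annotation a [probe_annotation()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  utils::write.csv(annotation, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a probes x samples matrix TSV
#'
#' First column is `probe_id`; remaining columns are one per sample. Beta
#' matrices are checked against \[0,1\]: values outside by at most
#' `beta_tolerance` are clipped with a warning, larger excursions are an
#' error. Intensity matrices must be non-negative.
#'
#' @param path TSV file path.
#' @param kind `"beta"` or `"intensity"`.
#' @param missing_token string parsed as missing (default `"NA"`).
#' @param beta_tolerance clipping tolerance for beta values (default 1e-3).
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_matrix <- function(path, kind = c("beta", "intensity"),
                        missing_token = "NA", beta_tolerance = 1e-3) {
  kind <- match.arg(kind)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = missing_token, colClasses = NA,
                      fill = FALSE),
    error = function(e) stop_format("cannot parse matrix TSV '%s': %s",
                                    path, conditionMessage(e))
  )
  if (ncol(df) < 2)
    stop_format("matrix '%s' needs a probe_id column plus >= 1 sample", path)
  if (anyDuplicated(df[[1]]))
    stop_validation("duplicate probe_id in matrix '%s'", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (is.character(m)) {
    suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- is.na(num) & !is.na(m)
    if (any(bad))
      stop_format("non-numeric cell(s) in matrix '%s' (e.g. '%s')",
                  path, m[which(bad)[1]])
    m <- num
  }
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- names(df)[-1]
  if (anyDuplicated(colnames(m)))
    stop_validation("duplicate sample ids in matrix '%s'", path)
  validate_matrix_values(m, kind, beta_tolerance)
}

validate_matrix_values <- function(m, kind, beta_tolerance = 1e-3) {
  if (kind == "beta") {
    excess <- pmax(m - 1, -m, 0)
    if (any(excess > beta_tolerance, na.rm = TRUE))
      stop_validation("beta value(s) outside [0,1] beyond tolerance %g",
                      beta_tolerance)
    n_clip <- sum(excess > 0, na.rm = TRUE)
    if (n_clip > 0) {
      warning(sprintf("%d beta value(s) clipped into [0,1]", n_clip),
              call. = FALSE)
      m <- pmin(pmax(m, 0), 1)
    }
  } else {
    if (any(m < 0, na.rm = TRUE))
      stop_domain("negative intensity value(s)")
  }
  m
}

#' Write a probes x samples matrix TSV
#'
#' Inverse of [read_matrix()]: first column `probe_id`, one column per
#' sample, missing values written as `missing_token`. Numbers are written
#' with full (17 significant digit) precision so a read round-trip
#' reproduces values bit-identically.
#'
#' @param m numeric matrix with rownames and colnames.
#' @param path output TSV path.
#' @param missing_token token for missing values.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, missing_token = "NA") {
  df <- data.frame(probe_id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    col <- sprintf("%.17g", m[, j])
    col[is.na(m[, j])] <- missing_token
    df[[colnames(m)[j]]] <- col
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate a sample sheet
#'
#' @param sample_id unique sample identifiers.
#' @param patient_id patient identifiers linking paired samples.
#' @param status `"PRIMARY"` or `"RELAPSE"` per sample.
#' @param relapse_index 0 for primary samples, 1..k for successive relapses.
#' @param subgroup molecular subgroup label per sample.
#' @return `data.frame` of class `sample_sheet`; patients without a PRIMARY
#'   sample are flagged in the `unpaired_patients` attribute.
#' @export
sample_sheet <- function(sample_id, patient_id, status, relapse_index,
                         subgroup) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop_validation("duplicate sample_id")
  status <- toupper(as.character(status))
  if (!all(status %in% c("PRIMARY", "RELAPSE")))
    stop_validation("status must be PRIMARY or RELAPSE")
  relapse_index <- as.integer(relapse_index)
  if (any(is.na(relapse_index) | relapse_index < 0))
    stop_validation("relapse_index must be an integer >= 0")
  if (any(relapse_index[status == "PRIMARY"] != 0L))
    stop_validation("PRIMARY samples must have relapse_index 0")
  if (any(relapse_index[status == "RELAPSE"] < 1L))
    stop_validation("RELAPSE samples must have relapse_index >= 1")
  sheet <- data.frame(
    sample_id = sample_id,
    patient_id = as.character(patient_id),
    status = status,
    relapse_index = relapse_index,
    subgroup = as.character(subgroup),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sheet[, c("patient_id", "relapse_index")]))
    stop_validation("(patient_id, relapse_index) must be unique")
  has_primary <- tapply(sheet$status == "PRIMARY", sheet$patient_id, any)
  attr(sheet, "unpaired_patients") <- names(has_primary)[!has_primary]
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read a sample sheet CSV
#'
#' Expects columns `sample_id,patient_id,status,relapse_index,subgroup`.
#'
#' @param path CSV file path.
#' @return validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_format("cannot parse sample sheet '%s': %s",
                                    path, conditionMessage(e))
  )
  need <- c("sample_id", "patient_id", "status", "relapse_index", "subgroup")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_format("sample sheet '%s' missing column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  sample_sheet(df$sample_id, df$patient_id, df$status, df$relapse_index,
               df$subgroup)
}

#' Write a sample sheet CSV
#' @param sheet a [sample_sheet()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Align annotation, matrices and sample sheet on shared labels
#'
#' Restricts all components to the intersection of probes (annotation and
#' beta matrix) and samples (beta matrix and sheet), preserving the matrix
#' order. Intensity matrices, when given, are restricted to the same labels
#' and must cover them.
#'
#' @param annotation a [probe_annotation()] table.
#' @param beta beta matrix (probes x samples).
#' @param sheet a [sample_sheet()].
#' @param intensities optional `list(methylated=, unmethylated=)` matrices.
#' @return list of class `meth_dataset` with elements `annotation`, `beta`,
#'   `intensities` (or `NULL`), `sheet`, and a `dropped` element reporting
#'   the number of probes/samples discarded from each input.
#' @export
align_inputs <- function(annotation, beta, sheet, intensities = NULL) {
  probes <- intersect(rownames(beta), annotation$probe_id)
  samples <- intersect(colnames(beta), sheet$sample_id)
  if (length(probes) == 0)
    stop_validation("no probes shared between annotation and matrix")
  if (length(samples) == 0)
    stop_validation("no samples shared between matrix and sample sheet")
  # preserve matrix order
  probes <- rownames(beta)[rownames(beta) %in% probes]
  samples <- colnames(beta)[colnames(beta) %in% samples]
  dropped <- list(
    annotation_probes = nrow(annotation) - length(probes),
    matrix_probes = nrow(beta) - length(probes),
    matrix_samples = ncol(beta) - length(samples),
    sheet_samples = nrow(sheet) - length(samples)
  )
  ann <- annotation[match(probes, annotation$probe_id), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("probe_annotation", "data.frame")
  sh <- sheet[match(samples, sheet$sample_id), , drop = FALSE]
  rownames(sh) <- NULL
  attr(sh, "unpaired_patients") <- attr(sheet, "unpaired_patients")
  class(sh) <- c("sample_sheet", "data.frame")
  if (!is.null(intensities)) {
    for (ch in c("methylated", "unmethylated")) {
      if (!all(probes %in% rownames(intensities[[ch]])) ||
          !all(samples %in% colnames(intensities[[ch]])))
        stop_validation("intensity matrices do not cover the aligned labels")
    }
    intensities <- list(
      methylated = intensities$methylated[probes, samples, drop = FALSE],
      unmethylated = intensities$unmethylated[probes, samples, drop = FALSE]
    )
  }
  structure(
    list(annotation = ann, beta = beta[probes, samples, drop = FALSE],
         intensities = intensities, sheet = sh, dropped = dropped),
    class = "meth_dataset"
  )
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat(sprintf("meth_dataset: %d probes x %d samples (%d patients)\n",
              nrow(x$beta), ncol(x$beta), length(unique(x$sheet$patient_id))))
  cat(sprintf("  intensities: %s\n",
              if (is.null(x$intensities)) "absent" else "present"))
  tab <- table(x$sheet$status)
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
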