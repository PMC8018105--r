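#' Configuration for the paired-cohort simulator
#'
#' Builds and validates the parameter set for [simulate_dataset()]. The
#' defaults emulate a 450K-style paired primary/relapse ependymoma cohort:
#' five molecular subgroups of sizes 11/2/23/7/2 (45 patients, one primary
#' and one relapse each), substructure proportions matching the 450K
#' island/shore/shelf annotation, bimodal baseline betas (island probes
#' mostly unmethylated, open-sea probes mostly methylated), patient-level
#' and residual noise on the M scale, and log-normal total intensities.
#'
#' @param n_probes number of probes to simulate.
#' @param substructure_proportions named 6-vector of non-negative weights
#'   over [SUBSTRUCTURES], summing to 1.
#' @param subgroups named integer vector: patients per subgroup.
#' @param delta_island named per-subgroup beta-scale shift added to ISLAND
#'   probes in relapse samples (recycled if unnamed scalar).
#' @param delta_shelf named per-subgroup beta-scale shift added to shelf
#'   (N_SHELF/S_SHELF) probes in relapse samples.
#' @param patient_sd SD of the per-(probe, patient) random effect on the M
#'   scale (log2 units), shared between a patient's samples.
#' @param residual_sd SD of the within-sample residual noise on the M scale.
#' @param intensity_meanlog,intensity_sdlog parameters of the log-normal
#'   total-intensity distribution (natural-log scale).
#' @param cna_events list of copy-number events, each a list with elements
#'   `subgroup`, `chromosome`, `start`, `end`, `factor` (> 0); the factor
#'   multiplies total intensity at covered loci in relapse samples of that
#'   subgroup.
#' @param relapses_per_patient relapse samples per patient (scalar, or one
#'   value per patient in subgroup order).
#' @param n_chromosomes,chromosome_length synthetic genome: autosomes of
#'   equal length (bp).
#' @param seed integer seed; the same config and seed reproduce the dataset
#'   bit-identically.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 20000,
                       substructure_proportions = NULL,
                       subgroups = c("ST-EPN-RELA" = 11, "PF-SE" = 2,
                                     "PF-EPN-A" = 23, "PF-EPN-B" = 7,
                                     "SP-MPE" = 2),
                       delta_island = 0,
                       delta_shelf = 0,
                       patient_sd = 0.5,
                       residual_sd = 0.3,
                       intensity_meanlog = log(5000),
                       intensity_sdlog = 0.1,
                       cna_events = list(),
                       relapses_per_patient = 1,
                       n_chromosomes = 22,
                       chromosome_length = 1e8,
                       seed = 1L) {
  # accept YAML/JSON-style nested lists for the named-vector fields
  if (is.list(subgroups)) subgroups <- unlist(subgroups)
  if (is.list(delta_island)) delta_island <- unlist(delta_island)
  if (is.list(delta_shelf)) delta_shelf <- unlist(delta_shelf)
  if (is.list(substructure_proportions))
    substructure_proportions <- unlist(substructure_proportions)
  if (is.null(substructure_proportions)) {
    cnt <- hm450_substructure_counts()
    substructure_proportions <- cnt / sum(cnt)
  }
  p <- substructure_proportions
  if (length(p) != 6 || is.null(names(p)) || !setequal(names(p), SUBSTRUCTURES))
    stop_validation("substructure_proportions must be named over the 6 categories")
  p <- p[SUBSTRUCTURES]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_validation("substructure_proportions must be non-negative and sum to 1")
  if (!is.numeric(n_probes) || n_probes < 1)
    stop_validation("n_probes must be positive")
  if (length(subgroups) == 0 || any(subgroups < 1))
    stop_validation("subgroups must be a non-empty vector of positive counts")
  if (is.null(names(subgroups)))
    stop_validation("subgroups must be named")
  expand_delta <- function(d, what) {
    if (is.null(names(d))) {
      if (length(d) != 1)
        stop_validation("%s must be a named per-subgroup vector or a scalar", what)
      d <- stats::setNames(rep(d, length(subgroups)), names(subgroups))
    }
    out <- stats::setNames(rep(0, length(subgroups)), names(subgroups))
    out[intersect(names(d), names(subgroups))] <-
      d[intersect(names(d), names(subgroups))]
    out
  }
  if (residual_sd <= 0) stop_validation("residual_sd must be > 0")
  if (patient_sd < 0) stop_validation("patient_sd must be >= 0")
  for (ev in cna_events) {
    need <- c("subgroup", "chromosome", "start", "end", "factor")
    if (!all(need %in% names(ev)))
      stop_validation("each cna_event needs fields: %s",
                      paste(need, collapse = ", "))
    if (ev$factor <= 0) stop_validation("cna_event factor must be > 0")
  }
  n_pat <- sum(subgroups)
  rel <- rep(as.integer(relapses_per_patient), length.out = n_pat)
  if (any(rel < 1)) stop_validation("relapses_per_patient must be >= 1")
  structure(list(
    n_probes = as.integer(n_probes),
    substructure_proportions = p,
    subgroups = subgroups,
    delta_island = expand_delta(delta_island, "delta_island"),
    delta_shelf = expand_delta(delta_shelf, "delta_shelf"),
    patient_sd = patient_sd,
    residual_sd = residual_sd,
    intensity_meanlog = intensity_meanlog,
    intensity_sdlog = intensity_sdlog,
    cna_events = cna_events,
    relapses_per_patient = rel,
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Reference 450K substructure probe counts
#'
#' Per-category probe counts of the island/shore/shelf annotation of the
#' HumanMethylation450 array (485,577 probes in total); used as the default
#' substructure proportions of the simulator and as a desk-check fixture.
#'
#' @return named integer vector over [SUBSTRUCTURES].
#' @export
hm450_substructure_counts <- function() {
  c(ISLAND = 150254L, N_SHORE = 62870L, S_SHORE = 49197L,
    N_SHELF = 24844L, S_SHELF = 22300L, UNDEFINED = 176112L)
}

#' Build a synthetic annotation with prescribed per-category counts
#'
#' Expands a named vector of per-substructure probe counts into a full
#' [probe_annotation()] with synthetic probe ids and positions (probes laid
#' out consecutively along chr1). Useful for desk accounting checks of
#' [partition_probes()], e.g. on [hm450_substructure_counts()].
#'
#' @param counts named integer vector over (a subset of) [SUBSTRUCTURES].
#' @return a [probe_annotation()] with `sum(counts)` probes.
#' @export
annotation_from_counts <- function(counts) {
  if (is.null(names(counts)) || !all(names(counts) %in% SUBSTRUCTURES))
    stop_validation("counts must be named over the substructure categories")
  n <- sum(counts)
  probe_annotation(
    probe_id = sprintf("cg%08d", seq_len(n)),
    chromosome = "chr1",
    position = seq_len(n),
    substructure = rep(names(counts), times = counts)
  )
}

# probability that a probe's baseline beta comes from the low (unmethylated)
# mixture component, by substructure: islands are mostly unmethylated,
# shores intermediate, shelves and open sea mostly methylated
.low_component_prob <- c(ISLAND = 0.8, N_SHORE = 0.5, S_SHORE = 0.5,
                         N_SHELF = 0.15, S_SHELF = 0.15, UNDEFINED = 0.15)

#' Simulate a paired primary/relapse methylation array dataset
#'
#' Draws a synthetic cohort under the generative model described in the
#' package vignette: probes are assigned substructures by the configured
#' proportions and placed uniformly on equal-length synthetic autosomes;
#' baseline betas come from a two-component Beta mixture (component choice
#' depending on substructure); each patient carries a per-probe random
#' effect on the M scale shared between their samples; relapse samples add
#' the planted beta-scale shift for the probe's substructure and the
#' patient's subgroup; residual Normal noise is added on the M scale; total
#' intensities are log-normal, multiplied by the event factor at loci inside
#' a copy-number event of the sample's subgroup (relapse samples only).
#'
#' @param config a [sim_config()].
#' @return list of class `meth_dataset` (see [align_inputs()]) with an
#'   additional `truth` element: `beta_shift` and `cn_log2` matrices
#'   (probes x subgroups) of the planted effects.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  np <- config$n_probes
  sub_levels <- names(config$subgroups)

  substructure <- sample(SUBSTRUCTURES, np, replace = TRUE,
                         prob = config$substructure_proportions)
  chromosome <- paste0("chr", sample.int(config$n_chromosomes, np,
                                         replace = TRUE))
  position <- ceiling(stats::runif(np) * config$chromosome_length)
  probe_id <- sprintf("cg%08d", seq_len(np))
  ann <- probe_annotation(probe_id, chromosome, position, substructure)

  # baseline beta: bimodal mixture conditioned on substructure
  p_low <- .low_component_prob[substructure]
  is_low <- stats::runif(np) < p_low
  baseline <- ifelse(is_low, stats::rbeta(np, 1.5, 15),
                     stats::rbeta(np, 15, 1.5))

  # planted beta-scale relapse shifts per probe x subgroup
  beta_shift <- matrix(0, np, length(sub_levels),
                       dimnames = list(probe_id, sub_levels))
  for (g in sub_levels) {
    beta_shift[substructure == "ISLAND", g] <- config$delta_island[[g]]
    beta_shift[substructure %in% c("N_SHELF", "S_SHELF"), g] <-
      config$delta_shelf[[g]]
  }
  cn_log2 <- matrix(0, np, length(sub_levels),
                    dimnames = list(probe_id, sub_levels))
  for (ev in config$cna_events) {
    hit <- chromosome == ev$chromosome & position >= ev$start &
      position <= ev$end
    if (ev$subgroup %in% sub_levels)
      cn_log2[hit, ev$subgroup] <- cn_log2[hit, ev$subgroup] + log2(ev$factor)
  }

  # patients and samples
  pat_sub <- rep(sub_levels, times = config$subgroups)
  n_pat <- length(pat_sub)
  pat_id <- sprintf("PT%03d", seq_len(n_pat))
  n_rel <- config$relapses_per_patient
  sample_id <- character(0); s_pat <- character(0)
  s_status <- character(0); s_idx <- integer(0); s_sub <- character(0)
  for (i in seq_len(n_pat)) {
    ids <- c(paste0(pat_id[i], "_P"),
             paste0(pat_id[i], "_R", seq_len(n_rel[i])))
    sample_id <- c(sample_id, ids)
    s_pat <- c(s_pat, rep(pat_id[i], length(ids)))
    s_status <- c(s_status, "PRIMARY", rep("RELAPSE", n_rel[i]))
    s_idx <- c(s_idx, 0L, seq_len(n_rel[i]))
    s_sub <- c(s_sub, rep(pat_sub[i], length(ids)))
  }
  sheet <- sample_sheet(sample_id, s_pat, s_status, s_idx, s_sub)
  ns <- nrow(sheet)

  base_m <- beta_to_m(pmin(pmax(baseline, 1e-3), 1 - 1e-3))
  u_pat <- matrix(stats::rnorm(np * n_pat, 0, config$patient_sd), np, n_pat,
                  dimnames = list(probe_id, pat_id))

  beta <- matrix(NA_real_, np, ns, dimnames = list(probe_id, sample_id))
  meth <- unmeth <- beta
  for (j in seq_len(ns)) {
    pat <- sheet$patient_id[j]
    g <- sheet$subgroup[j]
    mu_beta <- baseline
    if (sheet$status[j] == "RELAPSE")
      mu_beta <- pmin(pmax(baseline + beta_shift[, g], 1e-3), 1 - 1e-3)
    mu_m <- if (sheet$status[j] == "RELAPSE")
      beta_to_m(mu_beta) else base_m
    m <- mu_m + u_pat[, pat] + stats::rnorm(np, 0, config$residual_sd)
    b <- pmin(pmax(m_to_beta(m), 0.001), 0.999)
    total <- stats::rlnorm(np, config$intensity_meanlog,
                           config$intensity_sdlog)
    if (sheet$status[j] == "RELAPSE")
      total <- total * 2^cn_log2[, g]
    beta[, j] <- b
    meth[, j] <- total * b
    unmeth[, j] <- total * (1 - b)
  }

  structure(list(
    annotation = ann,
    beta = beta,
    intensities = list(methylated = meth, unmethylated = unmeth),
    sheet = sheet,
    dropped = list(annotation_probes = 0L, matrix_probes = 0L,
                   matrix_samples = 0L, sheet_samples = 0L),
    truth = list(beta_shift = beta_shift, cn_log2 = cn_log2),
    config = config
  ), class = "meth_dataset")
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits the package's interchange formats: `annotation.csv`, `beta.tsv`,
#' `methylated.tsv`, `unmethylated.tsv`, `sample_sheet.csv`, and
#' `truth_beta_shift.csv` / `truth_cn_log2.csv` when ground truth is
#' attached. File contents are deterministic for a fixed dataset.
#'
#' @param dataset a `meth_dataset` (from [simulate_dataset()] or
#'   [align_inputs()]).
#' @param out_dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(dataset, out_dir) {
  if (ncol(dataset$beta) == 0)
    stop_validation("dataset has no samples")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", out_dir))
  paths <- c(
    annotation = file.path(out_dir, "annotation.csv"),
    beta = file.path(out_dir, "beta.tsv"),
    sample_sheet = file.path(out_dir, "sample_sheet.csv")
  )
  write_probe_annotation(dataset$annotation, paths[["annotation"]])
  write_matrix(dataset$beta, paths[["beta"]])
  write_sample_sheet(dataset$sheet, paths[["sample_sheet"]])
  if (!is.null(dataset$intensities)) {
    paths[["methylated"]] <- file.path(out_dir, "methylated.tsv")
    paths[["unmethylated"]] <- file.path(out_dir, "unmethylated.tsv")
    write_matrix(dataset$intensities$methylated, paths[["methylated"]])
    write_matrix(dataset$intensities$unmethylated, paths[["unmethylated"]])
  }
  if (!is.null(dataset$truth)) {
    for (nm in c("beta_shift", "cn_log2")) {
      p <- file.path(out_dir, sprintf("truth_%s.csv", nm))
      paths[[paste0("truth_", nm)]] <- p
      df <- data.frame(probe_id = rownames(dataset$truth[[nm]]),
                       dataset$truth[[nm]], check.names = FALSE)
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    }
  }
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir directory containing the fixture files.
#' @return aligned `meth_dataset`.
#' @export
read_fixture <- function(dir) {
  ann <- read_probe_annotation(file.path(dir, "annotation.csv"))
  beta <- read_matrix(file.path(dir, "beta.tsv"), "beta")
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.csv"))
  ints <- NULL
  if (file.exists(file.path(dir, "methylated.tsv"))) {
    ints <- list(
      methylated = read_matrix(file.path(dir, "methylated.tsv"), "intensity"),
      unmethylated = read_matrix(file.path(dir, "unmethylated.tsv"),
                                 "intensity")
    )
  }
  align_inputs(ann, beta, sheet, ints)
}
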