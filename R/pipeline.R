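#' Run the full analysis as one configurable pipeline
#'
#' Executes simulate (or load) -> preprocess -> probe-level paired test ->
#' substructure status + fractions -> CNV (when intensities exist) and
#' writes a machine-readable JSON report plus TSV tables. All stochastic
#' stages are governed by the single `seed` in the config.
#'
#' @param config a named list, or a path to a YAML/JSON file, with fields:
#'   \describe{
#'     \item{simulate}{list of [sim_config()] arguments (exclusive with
#'       `inputs`).}
#'     \item{inputs}{list of paths: `annotation`, `beta`, `sample_sheet`,
#'       optionally `methylated`, `unmethylated`.}
#'     \item{pairing}{pairing policy (default `"first_relapse"`).}
#'     \item{alpha}{significance level (default 0.05).}
#'     \item{test_mode}{substructure test (default `"paired_over_probes"`).}
#'     \item{moderate}{moderated probe test? (default `FALSE`)}
#'     \item{top_k}{CNV loci kept (default 1000).}
#'     \item{per_subgroup}{per-subgroup scope? (default `TRUE`)}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer seed.}
#'   }
#' @param out_dir overrides `config$out_dir`.
#' @return the report list, invisibly; files `report.json`, `dmp.tsv`,
#'   `substructure.tsv`, `fractions.tsv` and (with intensities)
#'   `cnv_top.tsv` + `cnv_top.bed` are written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  alpha <- config$alpha %||% 0.05
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must be in (0,1)")
  top_k <- config$top_k %||% 1000
  if (top_k < 1) stop_validation("top_k must be >= 1")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop_validation("an output directory is required")
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dataset <- if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    simulate_dataset(do.call(sim_config, sim_args))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    ints <- NULL
    if (!is.null(inp$methylated) && !is.null(inp$unmethylated)) {
      ints <- list(
        methylated = read_matrix(inp$methylated, "intensity"),
        unmethylated = read_matrix(inp$unmethylated, "intensity"))
    }
    align_inputs(read_probe_annotation(inp$annotation),
                 read_matrix(inp$beta, "beta"),
                 read_sample_sheet(inp$sample_sheet), ints)
  } else stop_validation("config needs either 'simulate' or 'inputs'")

  fit <- relapse_fit(
    dataset, alpha = alpha,
    policy = config$pairing %||% "first_relapse",
    moderate = isTRUE(config$moderate),
    test_mode = config$test_mode %||% "paired_over_probes",
    per_subgroup = !isFALSE(config$per_subgroup),
    top_k = top_k
  )

  report <- build_report(fit, config, seed)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  write_fit_tables(fit, out_dir)
  invisible(report)
}

read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

dmp_summary_entry <- function(tab, alpha) {
  list(n_probes = nrow(tab),
       n_sig_raw = sum(tab$p_raw < alpha, na.rm = TRUE),
       n_sig_adj = sum(tab$p_adj < alpha, na.rm = TRUE),
       n_excluded = attr(tab, "n_excluded") %||% 0L)
}

build_report <- function(fit, config, seed) {
  # the hash fingerprints the analysis configuration, not where it is written
  cfg <- config[setdiff(names(config), "out_dir")]
  config_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  skipped <- if (is.null(fit$cnv)) "cnv" else character(0)
  list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("epirelapse")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = fnv1a32(as.character(config_json)),
    partition = as.list(fit$partition$counts),
    dmp = c(list(cohort = dmp_summary_entry(fit$dmp, fit$alpha)),
            if (!is.null(fit$dmp_subgroups))
              list(subgroups = lapply(fit$dmp_subgroups,
                                      dmp_summary_entry, fit$alpha))),
    substructure_status = fit$substructure,
    fractions = fit$fractions,
    cnv = if (is.null(fit$cnv)) NULL else fit$cnv$summary,
    skipped_stages = as.list(skipped),
    alpha = fit$alpha,
    pairing = fit$policy
  )
}

write_fit_tables <- function(fit, out_dir) {
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(fit$dmp, "dmp.tsv")
  wt(fit$substructure, "substructure.tsv")
  wt(fit$fractions, "fractions.tsv")
  if (!is.null(fit$cnv)) {
    loci <- attr(fit$cnv$top, "loci")
    top_df <- cbind(loci, as.data.frame(unclass(fit$cnv$top)))
    wt(top_df, "cnv_top.tsv")
    score <- apply(fit$cnv$top, 1, stats::var, na.rm = TRUE)
    bed <- data.frame(chrom = loci$chromosome,
                      start = loci$position - 1L,
                      end = loci$position,
                      score = score)
    utils::write.table(bed, file.path(out_dir, "cnv_top.bed"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the required fields and their JSON types against the versioned
#' schema in `inst/schema/` (a structural subset of JSON Schema: `required`
#' and property `type`s, one level of nesting).
#'
#' @param report report list (as returned by [run_pipeline()]) or a path
#'   to a `report.json`.
#' @return `TRUE` if valid, otherwise an error listing the violations.
#' @export
validate_report <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  schema <- jsonlite::read_json(
    system.file("schema", "report-schema-1.0.json", package = "epirelapse"),
    simplifyVector = TRUE)
  problems <- character(0)
  for (field in schema$required) {
    if (!field %in% names(report)) {
      problems <- c(problems, sprintf("missing required field '%s'", field))
      next
    }
    want <- schema$properties[[field]]$type
    val <- report[[field]]
    ok <- switch(want,
                 string = is.character(val),
                 number = is.numeric(val),
                 integer = is.numeric(val),
                 object = is.list(val) || is.data.frame(val),
                 array = is.list(val) || is.vector(val),
                 TRUE)
    if (!ok)
      problems <- c(problems,
                    sprintf("field '%s' should have JSON type %s", field, want))
  }
  if (length(problems))
    stop_validation("report schema violations: %s",
                    paste(problems, collapse = "; "))
  TRUE
}
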