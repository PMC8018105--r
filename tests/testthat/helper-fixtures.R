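# small in-code fixtures shared across test files

tiny_annotation <- function() {
  probe_annotation(
    probe_id = c("cgA", "cgB", "cgC", "cgD", "cgE", "cgF"),
    chromosome = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr3"),
    position = c(100, 200, 100, 200, 100, 200),
    substructure = c("ISLAND", "N_SHORE", "S_SHORE", "N_SHELF", "S_SHELF",
                     "UNDEFINED")
  )
}

tiny_sheet <- function() {
  sample_sheet(
    sample_id = c("s1p", "s1r", "s2p", "s2r", "s3p", "s3r"),
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p3"),
    status = c("PRIMARY", "RELAPSE", "PRIMARY", "RELAPSE", "PRIMARY",
               "RELAPSE"),
    relapse_index = c(0, 1, 0, 1, 0, 1),
    subgroup = rep("PF-EPN-A", 6)
  )
}

tiny_beta <- function() {
  m <- matrix(runif(36, 0.1, 0.9), 6, 6,
              dimnames = list(tiny_annotation()$probe_id,
                              tiny_sheet()$sample_id))
  m
}

# write a matrix TSV from a literal character body (for parser edge cases)
write_tsv_literal <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

write_csv_literal <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# dmp-like table with prescribed significance/sign structure, spread over
# the mapped substructures of `partition`
accounting_dmp <- function(n_sig, n_hyper, n_null = 0) {
  n <- n_sig + n_null
  probe_id <- sprintf("cg%08d", seq_len(n))
  logFC <- c(rep(1, n_hyper), rep(-1, n_sig - n_hyper), rep(1, n_null))
  p_raw <- c(rep(0.01, n_sig), rep(0.5, n_null))
  tab <- data.frame(probe_id = probe_id, logFC = logFC, t_stat = logFC,
                    df = 10, p_raw = p_raw, n_pairs = 11L,
                    p_adj = p_raw, stringsAsFactors = FALSE)
  class(tab) <- c("dmp_table", "data.frame")
  tab
}
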