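make_totals <- function(values, samples, probes = paste0("cg", seq_len(nrow(values)))) {
  dimnames(values) <- list(probes, samples)
  values
}

cnv_fixture <- function(n = 50, n_pat = 4, seed = 81) {
  set.seed(seed)
  sheet <- sample_sheet(
    c(rbind(paste0("p", 1:n_pat, "_P"), paste0("p", 1:n_pat, "_R"))),
    rep(paste0("p", 1:n_pat), each = 2),
    rep(c("PRIMARY", "RELAPSE"), n_pat),
    rep(c(0, 1), n_pat),
    rep("G", 2 * n_pat))
  ann <- probe_annotation(paste0("cg", 1:n), rep(c("chr2", "chr1"), n / 2),
                          rep(1:(n / 2), each = 2), "ISLAND")
  totals <- matrix(rlnorm(n * 2 * n_pat, log(1000), 0.1), n, 2 * n_pat,
                   dimnames = list(paste0("cg", 1:n), sheet$sample_id))
  list(sheet = sheet, ann = ann, totals = totals,
       pairs = make_pairs(sheet))
}

test_that("total intensity is the channel sum and channel-symmetric", {
  ints <- list(methylated = matrix(300, 2, 2), unmethylated = matrix(700, 2, 2))
  expect_equal(total_intensity(ints), matrix(1000, 2, 2))
  swapped <- list(methylated = ints$unmethylated,
                  unmethylated = ints$methylated)
  expect_equal(total_intensity(ints), total_intensity(swapped))
  expect_equal(total_intensity(list(methylated = matrix(0, 1, 1),
                                    unmethylated = matrix(0, 1, 1))),
               matrix(0, 1, 1))
  expect_error(total_intensity(list(methylated = matrix(-1, 1, 1),
                                    unmethylated = matrix(1, 1, 1))),
               "non-negative")
})

test_that("log ratios honor the centering contract", {
  fx <- cnv_fixture()
  totals <- fx$totals
  # identical intensities in both pair members -> exactly 0 everywhere
  totals[, seq(2, 8, by = 2)] <- totals[, seq(1, 8, by = 2)]
  lfc <- patient_logfc(totals, fx$pairs, fx$ann)
  expect_true(all(lfc == 0))
  # relapse doubled at every locus: 0 centered, 1 uncentered
  totals2 <- fx$totals
  totals2[, seq(2, 8, by = 2)] <- 2 * totals2[, seq(1, 8, by = 2)]
  # pseudocount 0 makes the doubling exact
  lfc_c <- patient_logfc(totals2, fx$pairs, fx$ann, pseudocount = 0)
  expect_equal(unclass(lfc_c), unclass(lfc_c) * 0, ignore_attr = TRUE)
  lfc_u <- patient_logfc(totals2, fx$pairs, fx$ann, pseudocount = 0,
                         center = FALSE)
  expect_true(all(abs(lfc_u - 1) < 1e-12))
})

test_that("rows come back genome-sorted and zero loci are dropped", {
  fx <- cnv_fixture()
  lfc <- patient_logfc(fx$totals, fx$pairs, fx$ann)
  loci <- attr(lfc, "loci")
  key <- order(match(loci$chromosome, paste0("chr", 1:22)), loci$position)
  expect_equal(key, seq_len(nrow(loci)))
  tz <- fx$totals
  tz["cg7", ] <- 0
  expect_message(lfc2 <- patient_logfc(tz, fx$pairs, fx$ann), "dropped")
  expect_false("cg7" %in% rownames(lfc2))
})

test_that("swapping primary and relapse labels negates the matrix", {
  fx <- cnv_fixture()
  sheet_sw <- sample_sheet(fx$sheet$sample_id, fx$sheet$patient_id,
                           ifelse(fx$sheet$status == "PRIMARY", "RELAPSE",
                                  "PRIMARY"),
                           ifelse(fx$sheet$status == "PRIMARY", 1, 0),
                           fx$sheet$subgroup)
  pairs_sw <- make_pairs(sheet_sw)
  a <- patient_logfc(fx$totals, fx$pairs, fx$ann, pseudocount = 0,
                     center = FALSE)
  b <- patient_logfc(fx$totals, pairs_sw, fx$ann, pseudocount = 0,
                     center = FALSE)
  expect_equal(unclass(a), -unclass(b), ignore_attr = TRUE)
})

test_that("top-k selection is deterministic, stable and criterion-driven", {
  fx <- cnv_fixture(n = 40)
  lfc <- patient_logfc(fx$totals, fx$pairs, fx$ann)
  # k = all loci returns the input in normalized order
  expect_warning(all_loci <- top_k_loci(lfc, k = 500), "exceeds")
  expect_equal(nrow(all_loci), nrow(lfc))
  expect_equal(rownames(all_loci), rownames(lfc))

  # one locus with planted variance far above the rest
  lfc2 <- lfc
  lfc2["cg3", ] <- c(-5, 5, -5, 5)
  top1 <- top_k_loci(lfc2, k = 1)
  expect_equal(rownames(top1), "cg3")
  expect_equal(rownames(top_k_loci(lfc2, k = 1, criterion = "max_abs")),
               "cg3")

  # exact ties resolve by genomic position, stably across runs
  tie <- matrix(rep(c(-1, 1, -1, 1), each = 6), 6, 4,
                dimnames = list(paste0("cg", 1:6), paste0("p", 1:4)))
  attr(tie, "loci") <- data.frame(
    probe_id = rownames(tie),
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    position = c(10, 20, 30, 1, 5, 10))
  class(tie) <- c("cnv_matrix", "matrix", "array")
  first <- top_k_loci(tie, k = 2)
  second <- top_k_loci(tie, k = 2)
  expect_identical(rownames(first), rownames(second))
  expect_equal(attr(first, "loci")$chromosome, c("chr1", "chr1"))
  expect_equal(attr(first, "loci")$position, c(10, 20))

  # selected set invariant under patient-column permutation
  perm <- c(3, 1, 4, 2)
  lfc_p <- lfc2[, perm]
  attr(lfc_p, "loci") <- attr(lfc2, "loci")
  class(lfc_p) <- class(lfc2)
  expect_equal(sort(rownames(top_k_loci(lfc_p, k = 5))),
               sort(rownames(top_k_loci(lfc2, k = 5))))
})

test_that("subgroup summaries and the heatmap handle small cohorts", {
  fx <- cnv_fixture()
  lfc <- patient_logfc(fx$totals, fx$pairs, fx$ann)
  summ <- cnv_report(lfc, fx$sheet)
  expect_equal(summ$n_patients, 4)
  expect_lt(summ$mean_abs_logfc, 0.25)  # null data: small ratios

  # single-patient cohort: one column, no crash, figure written
  one <- lfc[, 1, drop = FALSE]
  attr(one, "loci") <- attr(lfc, "loci")
  class(one) <- class(lfc)
  fig <- tempfile(fileext = ".png")
  summ1 <- cnv_report(one, fx$sheet, file = fig)
  expect_equal(summ1$n_patients, 1)
  expect_true(file.exists(fig))
})

test_that("a planted subgroup gain shows up in the subgroup summary", {
  cfg <- sim_config(n_probes = 2000, subgroups = c(A = 6, B = 6),
                    cna_events = list(list(subgroup = "A",
                                           chromosome = "chr1", start = 1,
                                           end = 1e8, factor = 1.5)),
                    seed = 91)
  ds <- simulate_dataset(cfg)
  pairs <- make_pairs(ds$sheet)
  lfc <- patient_logfc(total_intensity(ds$intensities), pairs,
                       ds$annotation)
  aff <- rownames(lfc)[attr(lfc, "loci")$chromosome == "chr1"]
  carriers <- pairs$patient_id[pairs$subgroup == "A"]
  expect_equal(mean(lfc[aff, carriers]), log2(1.5), tolerance = 0.05)
  others <- pairs$patient_id[pairs$subgroup == "B"]
  expect_lt(abs(mean(lfc[aff, others])), 0.05)
})
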