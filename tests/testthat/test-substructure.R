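test_that("partition is total, disjoint and counts every category", {
  ann <- probe_annotation(paste0("cg", 1:5), "chr1", 1:5,
                          c("ISLAND", "N_SHORE", "S_SHORE", "N_SHELF",
                            "S_SHELF"))
  part <- partition_probes(ann)
  expect_equal(unname(part$counts[MAPPED_SUBSTRUCTURES]), rep(1L, 5))
  expect_equal(part$n_undefined, 0L)
  expect_equal(sum(part$counts), part$n_total)

  # all-UNDEFINED annotation: downstream analysis refuses to run
  ann_u <- probe_annotation(paste0("cg", 1:4), "chr1", 1:4, "UNDEFINED")
  part_u <- partition_probes(ann_u)
  gm <- list(primary = rep(0.5, 4), relapse = rep(0.5, 4))
  expect_error(substructure_status(gm, part_u), "no mapped probes")
})

test_that("reference 450K counts partition to the printed totals", {
  counts <- hm450_substructure_counts()
  part <- partition_probes(annotation_from_counts(counts))
  expect_equal(part$n_total, 485577L)
  expect_equal(part$counts[names(counts)], counts)
  expect_equal(sum(part$counts[MAPPED_SUBSTRUCTURES]) + part$n_undefined,
               part$n_total)
})

test_that("identical group means give t = 0, p = 1 in every substructure", {
  set.seed(61)
  ann <- tiny_annotation()
  part <- partition_probes(probe_annotation(
    paste0("cg", 1:50), "chr1", 1:50,
    rep(MAPPED_SUBSTRUCTURES, each = 10)))
  means <- runif(50)
  names(means) <- paste0("cg", 1:50)
  gm <- list(primary = means, relapse = means)
  st <- substructure_status(gm, part)
  expect_equal(st$t_stat, rep(0, 5))
  expect_equal(st$p_value, rep(1, 5))
})

test_that("a planted island shift is recovered with the right magnitude", {
  set.seed(67)
  n_isl <- 2000; n_oth <- 1000
  ids <- paste0("cg", seq_len(n_isl + n_oth))
  part <- partition_probes(probe_annotation(
    ids, "chr1", seq_along(ids),
    c(rep("ISLAND", n_isl), rep("N_SHORE", n_oth))))
  base <- runif(n_isl + n_oth, 0.2, 0.8)
  prim <- base + rnorm(n_isl + n_oth, 0, 0.01)
  rel <- base + c(rep(0.05, n_isl), rep(0, n_oth)) +
    rnorm(n_isl + n_oth, 0, 0.01)
  gm <- list(primary = setNames(prim, ids), relapse = setNames(rel, ids))
  st <- substructure_status(gm, part)
  isl <- st[st$substructure == "ISLAND", ]
  expect_lt(abs((isl$mean_relapse - isl$mean_primary) - 0.05), 0.001)
  expect_lt(isl$p_value, 1e-6)
  other <- st[st$substructure == "N_SHORE", ]
  expect_gt(other$p_value, 1e-4)  # no planted effect there
})

test_that("single-probe substructures are flagged without a statistic", {
  part <- partition_probes(probe_annotation(
    c("cg1", "cg2", "cg3"), "chr1", 1:3,
    c("ISLAND", "ISLAND", "N_SHORE")))
  gm <- list(primary = c(cg1 = 0.2, cg2 = 0.3, cg3 = 0.4),
             relapse = c(cg1 = 0.25, cg2 = 0.35, cg3 = 0.5))
  st <- substructure_status(gm, part)
  shore <- st[st$substructure == "N_SHORE", ]
  expect_true(shore$flagged)
  expect_true(is.na(shore$t_stat))
})

test_that("paired substructure test equals the one-sample t on mean diffs", {
  set.seed(71)
  ids <- paste0("cg", 1:400)
  part <- partition_probes(probe_annotation(
    ids, "chr1", 1:400, rep(MAPPED_SUBSTRUCTURES, each = 80)))
  gm <- list(primary = setNames(runif(400), ids),
             relapse = setNames(runif(400), ids))
  st <- substructure_status(gm, part, test_mode = "paired_over_probes")
  for (ss in MAPPED_SUBSTRUCTURES) {
    idx <- ids[as.character(part$map) == ss]
    ref <- paired_t(gm$relapse[idx] - gm$primary[idx], variance_floor = 0)
    row <- st[st$substructure == ss, ]
    expect_equal(row$t_stat, ref$t_stat, tolerance = 1e-10)
    expect_equal(row$p_value, ref$p_raw, tolerance = 1e-10)
  }
})

test_that("probes classify by the sign of logFC with zero in neither class", {
  expect_equal(as.character(classify_probe(c(-0.5, 0.5, 0))),
               c("HYPO", "HYPER", "NONE"))
  expect_error(classify_probe(c(1, NA)), "finite")
  expect_error(classify_probe(Inf), "finite")
})

test_that("fraction analysis reproduces the hypo/hyper accounting identity", {
  part <- partition_probes(annotation_from_counts(
    c(ISLAND = 30000, N_SHORE = 12000, S_SHORE = 10000,
      N_SHELF = 5000, S_SHELF = 4500)))
  tab <- accounting_dmp(n_sig = 58505, n_hyper = 36759)
  f <- fraction_analysis(tab, part, alpha = 0.05)
  tot <- attr(f, "totals")
  expect_equal(tot$selected, 58505)
  expect_equal(tot$hyper, 36759)
  expect_equal(tot$hypo, 21746)
  expect_equal(tot$hypo + tot$hyper + tot$none, tot$selected)
})

test_that("fraction panels sum to 100% and respect edge cases", {
  # all selected probes in ISLAND
  part <- partition_probes(probe_annotation(
    sprintf("cg%08d", 1:10), "chr1", 1:10,
    c(rep("ISLAND", 6), rep("N_SHORE", 4))))
  tab <- accounting_dmp(n_sig = 4, n_hyper = 2, n_null = 6)
  f <- fraction_analysis(tab, part)
  expect_equal(f$pct_all[f$substructure == "ISLAND"], 100)
  expect_equal(sum(f$pct_all), 100)
  expect_equal(sum(f$pct_hypo), 100)
  expect_equal(sum(f$pct_hyper), 100)

  # selection spread evenly over the five substructures -> 20% each
  part5 <- partition_probes(annotation_from_counts(
    setNames(rep(20L, 5), MAPPED_SUBSTRUCTURES)))
  tab5 <- accounting_dmp(n_sig = 100, n_hyper = 50)
  f5 <- fraction_analysis(tab5, part5)
  expect_equal(f5$pct_all, rep(20, 5))

  # zero selected probes -> empty table with a warning
  tab0 <- accounting_dmp(n_sig = 0, n_hyper = 0, n_null = 10)
  expect_warning(f0 <- fraction_analysis(tab0, part), "no significant")
  expect_equal(sum(f0$n_selected), 0)
})

test_that("planted directions concentrate HYPER in islands, HYPO in shelves", {
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config(n_probes = 4000, subgroups = c(G = 12),
                      delta_island = 0.06, delta_shelf = -0.05, seed = seed)
    ds <- simulate_dataset(cfg)
    fit <- relapse_fit(ds, per_subgroup = FALSE, top_k = 50)
    f <- fit$fractions
    expect_equal(f$substructure[which.max(f$pct_hyper)], "ISLAND")
    shelf_hypo <- sum(f$pct_hypo[f$substructure %in% c("N_SHELF", "S_SHELF")])
    island_hypo <- f$pct_hypo[f$substructure == "ISLAND"]
    expect_gt(shelf_hypo, island_hypo)
  }
})
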