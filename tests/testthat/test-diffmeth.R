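test_that("pairing builds one primary/relapse pair per patient", {
  sheet <- sample_sheet(
    c("a_p", "a_r1", "b_p", "b_r1", "b_r2", "b_r3", "c_r1"),
    c("a", "a", "b", "b", "b", "b", "c"),
    c("PRIMARY", "RELAPSE", "PRIMARY", "RELAPSE", "RELAPSE", "RELAPSE",
      "RELAPSE"),
    c(0, 1, 0, 1, 2, 3, 1), "g")
  pr <- make_pairs(sheet, "first_relapse")
  expect_equal(nrow(pr), 2)               # patient c has no primary
  expect_equal(attr(pr, "n_dropped"), 1)
  expect_equal(pr$relapse[[which(pr$patient_id == "b")]], "b_r1")

  pr2 <- make_pairs(sheet, "all_relapses_averaged")
  expect_equal(pr2$relapse[[which(pr2$patient_id == "b")]],
               c("b_r1", "b_r2", "b_r3"))
  # averaging policy: relapse value is the multi-sample mean
  m <- matrix(c(0, 1, 0, 1, 2, 3, 9), 1, 7,
              dimnames = list("cg1", sheet$sample_id))
  d <- paired_differences(m, pr2)
  expect_equal(unname(d[1, "b"]), mean(c(1, 2, 3)) - 0)

  only_rel <- sample_sheet("x_r", "x", "RELAPSE", 1, "g")
  expect_error(make_pairs(only_rel), "no complete")
})

test_that("paired t matches its closed-form and limiting examples", {
  z <- paired_t(c(0, 0, 0))
  expect_equal(z$t_stat, 0)
  expect_equal(z$p_raw, 1)

  # d = (1,2,3): t = 2*sqrt(3), df = 2, p from the df-2 Student CDF
  # P(T <= t) = 1/2 + t / (2*sqrt(2 + t^2))
  r <- paired_t(c(1, 2, 3))
  expect_equal(r$logFC, 2)
  expect_equal(r$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  t0 <- 2 * sqrt(3)
  expect_equal(r$p_raw, 1 - t0 / sqrt(2 + t0^2), tolerance = 1e-12)
  expect_equal(r$p_raw, 0.0741799, tolerance = 1e-6)

  # sign antisymmetry
  r2 <- paired_t(c(-1, -2, -3))
  expect_equal(r2$t_stat, -r$t_stat)
  expect_equal(r2$p_raw, r$p_raw)
})

test_that("vectorized paired t agrees with stats::t.test row by row", {
  set.seed(21)
  d <- matrix(rnorm(50 * 8, sd = 2), 50, 8)
  d[1, 5:8] <- NA  # pairwise-complete path
  res <- paired_t(d)
  for (i in c(1, 7, 23, 50)) {
    ref <- t.test(d[i, !is.na(d[i, ])])
    expect_equal(res$t_stat[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_raw[i], ref$p.value, tolerance = 1e-12)
  }
  expect_equal(res$n_pairs[1], 4)
})

test_that("probes with fewer than 2 complete pairs are flagged out", {
  d <- rbind(c(1, NA, NA), c(1, 2, 3))
  expect_message(res <- paired_t(d), "1 probe")
  expect_true(is.na(res$p_raw[1]))
  expect_false(is.na(res$p_raw[2]))
})

test_that("t p-value tracks the exhaustive sign-flip permutation p", {
  # the permutation p is discrete; the Student p approximates it with
  # discretization error that shrinks ~ 2^(-n/2)
  set.seed(31)
  n_inst <- 120
  devs <- numeric(n_inst)
  for (k in seq_len(n_inst)) {
    n <- sample(4:10, 1)
    d <- rnorm(n, mean = sample(c(0, 0.5, 1), 1))
    r <- paired_t(d)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tperm <- apply(signs, 1, function(s) {
      x <- s * d
      mean(x) / (sd(x) / sqrt(n))
    })
    p_perm <- mean(abs(tperm) >= abs(r$t_stat) - 1e-12)
    devs[k] <- abs(p_perm - r$p_raw)
    expect_lt(devs[k], 1.4 * 2^(-(n - 2) / 2))
  }
  expect_lt(mean(devs), 0.06)
})

test_that("variance moderation shrinks toward the prior and recovers it", {
  # degenerate: no dispersion in the variances
  mod <- moderate_variances(rep(2, 50), df = 10)
  expect_equal(mod$s0_2, 2, tolerance = 1e-6)
  expect_equal(mod$s2_post, rep(2, 50), tolerance = 1e-6)

  # posterior lies between the observed variance and the prior, probe-wise
  set.seed(41)
  s2 <- 1 * rchisq(500, 4) / 4
  mod <- moderate_variances(s2, df = 4)
  lo <- pmin(s2, mod$s0_2); hi <- pmax(s2, mod$s0_2)
  expect_true(all(mod$s2_post >= lo - 1e-12 & mod$s2_post <= hi + 1e-12))

  # parameter recovery from the generating model:
  # sigma^2 ~ scaled-inv-chisq(d0 = 4, s0^2 = 1), s^2 | sigma^2 ~ sigma^2 chisq(df)/df
  set.seed(43)
  df <- 12
  sigma2 <- 1 * 4 / rchisq(5000, 4)
  s2 <- sigma2 * rchisq(5000, df) / df
  mod <- moderate_variances(s2, df = df)
  expect_lt(abs(mod$d0 - 4) / 4, 0.25)
  expect_lt(abs(mod$s0_2 - 1) / 1, 0.10)
})

test_that("moderation agrees with the independent limma implementation", {
  set.seed(47)
  s2 <- 1.5 * rchisq(2000, 5) / 5 * rchisq(2000, 8) / 8
  mine <- moderate_variances(s2, df = 8)
  ref <- limma::squeezeVar(s2, df = 8)
  expect_equal(mine$s2_post, ref$var.post, tolerance = 0.02)
  expect_equal(mine$d0, ref$df.prior, tolerance = 0.05 * ref$df.prior)
})

test_that("BH adjustment matches the step-up formula and its invariants", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0,1\\]")

  # direct-formula oracle + permutation invariance + monotonicity
  bh_direct <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(adj, 1)[order(o)]
  }
  set.seed(53)
  for (i in 1:25) {
    p <- runif(sample(5:200, 1))^2
    expect_equal(adjust_pvalues(p), bh_direct(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(adjust_pvalues(p)[perm], adjust_pvalues(p[perm]))
    # raising one raw p never lowers any adjusted p
    j <- sample(length(p), 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_true(all(adjust_pvalues(p2) >= adjust_pvalues(p) - 1e-12))
  }
})

test_that("cohort and subgroup DMP runs handle degenerate subgroup sizes", {
  cfg <- sim_config(n_probes = 300, subgroups = c(A = 5, B = 2), seed = 17)
  ds <- simulate_dataset(cfg)
  tabs <- run_dmp(ds, scope = "per_subgroup")
  # the n = 2 subgroup runs at df = 1 without crashing
  expect_equal(unique(tabs$B$df), 1)
  expect_true(all(tabs$B$p_raw >= 0 & tabs$B$p_raw <= 1, na.rm = TRUE))
  expect_equal(nrow(tabs$A), 300)
  # p_adj >= p_raw at the smallest p, and signs of t match logFC
  tab <- run_dmp(ds, scope = "cohort")
  i <- which.min(tab$p_raw)
  expect_gte(tab$p_adj[i], tab$p_raw[i])
  nz <- tab$t_stat != 0 & tab$logFC != 0
  expect_true(all(sign(tab$t_stat[nz]) == sign(tab$logFC[nz])))
})
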