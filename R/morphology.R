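#' Declared scales of the histomorphology variables
#'
#' Cell density is scored 1 (low) to 3 (high); necrosis and vessel
#' proliferation 0 (absent) to 3 (plenty); Ki67 as a percentage of
#' positively stained tumor nuclei.
#'
#' @return named list of `c(min, max)` ranges.
#' @export
morphology_scales <- function() {
  list(cell_density = c(1, 3), necrosis = c(0, 3),
       vessel_proliferation = c(0, 3), ki67 = c(0, 100))
}

#' Build a validated score set
#'
#' @param value numeric scores.
#' @param group `"PRIMARY"`/`"RELAPSE"` per score.
#' @param variable one of `names(morphology_scales())`.
#' @return `data.frame` of class `score_set`.
#' @export
score_set <- function(value, group, variable) {
  variable <- match.arg(variable, names(morphology_scales()))
  rng <- morphology_scales()[[variable]]
  if (any(value < rng[1] | value > rng[2], na.rm = TRUE))
    stop_validation("%s scores must lie in [%g, %g]", variable,
                    rng[1], rng[2])
  group <- toupper(as.character(group))
  if (!all(group %in% c("PRIMARY", "RELAPSE")))
    stop_validation("group must be PRIMARY or RELAPSE")
  out <- data.frame(value = value, group = group, variable = variable,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  out
}

#' Per-group mean, SEM and n of a score set
#'
#' @param scores a [score_set()].
#' @return `data.frame` with one row per group: `mean`, `sem`
#'   (`sd/sqrt(n)`, `NA` for singleton groups), `n`.
#' @export
summarize_scores <- function(scores) {
  groups <- split(scores$value, scores$group)
  if (length(groups) == 0 || any(vapply(groups, length, 1L) == 0))
    stop_validation("each group needs >= 1 value")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]][!is.na(groups[[g]])]
    n <- length(v)
    data.frame(group = g, mean = mean(v),
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  out
}

#' Unpaired two-sample t-test from summary statistics
#'
#' Reconstructs the group variances from the standard errors
#' (`s^2 = sem^2 * n`) and applies the classical pooled-variance Student t
#' or the Welch t. Useful for checking published mean +/- SEM summaries.
#'
#' @param mean1,sem1,n1 first group summary (`n1 >= 2`, `sem1 >= 0`).
#' @param mean2,sem2,n2 second group summary.
#' @param mode `"student_pooled"` (default) or `"welch"`.
#' @param variance_floor lower bound on the (pooled) variance.
#' @return list with `t`, `df`, `p` (two-sided), `mode`.
#' @export
t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2,
                           mode = c("student_pooled", "welch"),
                           variance_floor = 1e-8) {
  mode <- match.arg(mode)
  if (n1 < 2 || n2 < 2) stop_validation("both groups need n >= 2")
  if (sem1 < 0 || sem2 < 0) stop_validation("SEMs must be >= 0")
  s1_2 <- sem1^2 * n1
  s2_2 <- sem2^2 * n2
  if (mode == "student_pooled") {
    sp2 <- ((n1 - 1) * s1_2 + (n2 - 1) * s2_2) / (n1 + n2 - 2)
    sp2 <- max(sp2, variance_floor)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- max(s1_2, variance_floor) / n1
    v2 <- max(s2_2, variance_floor) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  if (mean1 == mean2) t <- 0
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mode = mode)
}

#' Unpaired two-sample t-test on raw scores
#'
#' Two-sided unpaired t between the PRIMARY and RELAPSE scores, in the
#' pooled-variance Student or Welch variant. The statistic is computed
#' from the group summaries via [t_from_summary()], so results from raw
#' data and from their own summaries agree exactly. Zero variance in both
#' groups with equal means yields t = 0, p = 1.
#'
#' @param scores a [score_set()].
#' @param mode `"student_pooled"` or `"welch"`.
#' @param variance_floor see [t_from_summary()].
#' @return list with `t`, `df`, `p`, `mode` (RELAPSE minus PRIMARY sign
#'   convention: positive t means higher relapse scores).
#' @export
unpaired_t <- function(scores, mode = c("student_pooled", "welch"),
                       variance_floor = 1e-8) {
  mode <- match.arg(mode)
  s <- summarize_scores(scores)
  if (any(s$n < 2)) stop_validation("both groups need n >= 2")
  rel <- s[s$group == "RELAPSE", ]
  pri <- s[s$group == "PRIMARY", ]
  t_from_summary(rel$mean, rel$sem, rel$n, pri$mean, pri$sem, pri$n,
                 mode = mode, variance_floor = variance_floor)
}

#' Rank-based alternative for ordinal scores
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between the PRIMARY and
#' RELAPSE scores; appropriate when treating the ordinal scales as
#' interval data is in doubt.
#'
#' @param scores a [score_set()].
#' @return list with `W` and `p`.
#' @export
rank_test <- function(scores) {
  rel <- scores$value[scores$group == "RELAPSE"]
  pri <- scores$value[scores$group == "PRIMARY"]
  ht <- suppressWarnings(stats::wilcox.test(rel, pri))
  list(W = unname(ht$statistic), p = ht$p.value)
}
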