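test_that("ROUT keeps homogeneous samples and flags gross outliers", {
  expect_length(rout_outliers(c(1, 2, 3, 4, 5))$flagged, 0L)
  r <- rout_outliers(c(1, 2, 3, 4, 100))
  expect_identical(r$flagged, 5L)
  expect_equal(r$kept, c(1, 2, 3, 4))
  expect_warning(rout_outliers(c(1, 2)), "n >= 3")
  # two-sided: a low outlier is caught as well
  expect_identical(rout_outliers(c(-100, 4, 5, 6, 7))$flagged, 1L)
})

test_that("ROUT false-flag rate on clean normal samples stays below 2%", {
  set.seed(41)
  flagged <- 0L; total <- 0L
  for (i in 1:1000) {
    r <- rout_outliers(rnorm(50), q = 0.01)
    flagged <- flagged + length(r$flagged)
    total <- total + 50L
  }
  expect_lte(flagged / total, 0.02)
})

test_that("Shapiro-Wilk wrapper calibrates on normal data and rejects exponential data", {
  set.seed(42)
  rej_norm <- mean(vapply(1:1000, function(i) normality(rnorm(500))$p < 0.05,
                          logical(1)))
  expect_gte(rej_norm, 0.03); expect_lte(rej_norm, 0.07)
  rej_exp <- mean(vapply(1:200, function(i) normality(rexp(500))$p < 0.05,
                         logical(1)))
  expect_gte(rej_exp, 0.99)
  set.seed(1)
  expect_lte(normality(rnorm(100))$W, 1)
  # constant samples are treated as non-normal, not an error
  const <- normality(rep(3, 10))
  expect_false(const$normal)
  expect_true(is.na(const$W))
})

test_that("the decision tree takes the published branches", {
  set.seed(7)
  # two identical samples: no effect detected on either branch
  x <- rnorm(30)
  r_t <- compare_groups(list(a = x, b = x), rout_q = NULL)
  expect_identical(r_t$test_used, "t")
  expect_gte(r_t$p, 0.99)
  y <- rexp(30)
  r_mw <- compare_groups(list(a = y, b = y), rout_q = NULL)
  expect_identical(r_mw$test_used, "mann_whitney")
  expect_gte(r_mw$p, 0.99)

  # >= 3 groups: ANOVA + Dunnett with a control, Tukey without
  g3 <- list(ctrl = rnorm(20), t1 = rnorm(20), t2 = rnorm(20))
  expect_identical(compare_groups(g3, control = "ctrl")$test_used, "anova_dunnett")
  expect_identical(compare_groups(g3)$test_used, "anova_tukey")

  # non-normal branch: Kruskal-Wallis + Dunn
  g3e <- list(ctrl = rexp(25), t1 = rexp(25), t2 = rexp(25))
  rk <- compare_groups(g3e)
  expect_identical(rk$test_used, "kruskal_dunn")
  expect_equal(nrow(rk$posthoc), 3L)

  expect_error(compare_groups(list(a = rnorm(5), b = rnorm(2)), rout_q = NULL),
               "n < 3")
})

test_that("rank-based branches are invariant under strictly monotone transforms", {
  # bimodal samples stay non-normal under the cube transform, so the
  # non-parametric branch is taken on both scales and must agree exactly
  set.seed(9)
  bimodal <- function(n, d) c(rnorm(n / 2, 0, 0.05), rnorm(n / 2, 1 + d, 0.05))
  a <- bimodal(24, 0); b <- bimodal(24, 0.4); c3 <- bimodal(24, -0.2)
  cube <- function(x) x^3
  direct <- compare_groups(list(a = a, b = b, c = c3), rout_q = NULL)
  trans <- compare_groups(list(a = cube(a), b = cube(b), c = cube(c3)),
                          rout_q = NULL)
  expect_identical(direct$test_used, "kruskal_dunn")
  expect_identical(trans$test_used, "kruskal_dunn")
  expect_equal(direct$statistic, trans$statistic, tolerance = 1e-12)
  expect_equal(direct$posthoc$p_adjusted, trans$posthoc$p_adjusted,
               tolerance = 1e-12)

  mw1 <- compare_groups(list(a = a, b = b), rout_q = NULL)
  mw2 <- compare_groups(list(a = cube(a), b = cube(b)), rout_q = NULL)
  expect_identical(mw1$test_used, "mann_whitney")
  expect_identical(mw2$test_used, "mann_whitney")
  expect_equal(mw1$p, mw2$p, tolerance = 1e-12)
})

test_that("post hoc adjusted p-values never fall below their unadjusted values", {
  set.seed(10)
  g <- list(ctrl = rnorm(15), t1 = rnorm(15, 0.5), t2 = rnorm(15, 1))
  d <- mitoquant:::dunnett_posthoc(unlist(g), rep(names(g), each = 15), "ctrl")
  expect_true(all(d$p_adjusted >= d$p_unadjusted - 1e-10))
  ge <- list(a = rexp(15), b = rexp(15, 0.5), c = rexp(15, 0.2))
  du <- mitoquant:::dunn_posthoc(unlist(ge), rep(names(ge), each = 15))
  expect_true(all(du$p_adjusted >= du$p_unadjusted - 1e-12))
})

test_that("Dunnett adjustment agrees with a Monte-Carlo max-|t| oracle", {
  set.seed(11)
  n <- 10; k <- 3
  x <- c(rnorm(n, 0), rnorm(n, 0.9), rnorm(n, 0.2))
  g <- rep(c("ctrl", "t1", "t2"), each = n)
  d <- mitoquant:::dunnett_posthoc(x, g, "ctrl")

  # oracle: distribution of max |t_i| over the two control comparisons under H0
  B <- 20000
  sim_max <- vapply(seq_len(B), function(b) {
    m <- matrix(rnorm(k * n), n, k)
    s2 <- sum((m - rep(colMeans(m), each = n))^2) / (k * n - k)
    tt <- (colMeans(m)[-1] - colMeans(m)[1]) / sqrt(2 * s2 / n)
    max(abs(tt))
  }, numeric(1))
  for (i in seq_len(nrow(d))) {
    expect_equal(d$p_adjusted[i], mean(sim_max >= abs(d$t[i])), tolerance = 0.02)
  }
})

test_that("omnibus type-I error is calibrated at alpha through the full tree", {
  set.seed(12)
  rej <- vapply(1:1000, function(i) {
    g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    compare_groups(g)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("a real location shift is detected with high power", {
  set.seed(13)
  rej <- vapply(1:200, function(i) {
    compare_groups(list(a = rnorm(50), b = rnorm(50, 1)))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})

test_that("per-replicate normalisation removes between-experiment scale", {
  values <- c(1, 2, 1.5, 2, 4, 3)               # replicate B is 2x replicate A
  repl <- c("A", "A", "A", "B", "B", "B")
  grp <- c("ctrl", "ko", "ko", "ctrl", "ko", "ko")
  out <- normalize_per_replicate(values, repl, grp, control = "ctrl")
  expect_equal(out[repl == "A"], out[repl == "B"])
  # control mean is 1 within each replicate
  expect_equal(mean(out[repl == "A" & grp == "ctrl"]), 1)
  expect_equal(mean(out[repl == "B" & grp == "ctrl"]), 1)
  # control means all 1: identity
  v2 <- c(1, 5, 1, 7)
  expect_equal(normalize_per_replicate(v2, c("A", "A", "B", "B"),
                                       c("ctrl", "ko", "ctrl", "ko"), "ctrl"), v2)
  expect_error(normalize_per_replicate(1:3, c("A", "A", "B"),
                                       c("ctrl", "ko", "ko"), "ctrl"),
               "replicate 'B'")
})

test_that("outlier removal feeds the downstream comparison", {
  set.seed(14)
  a <- c(rnorm(20), 50)                          # one gross outlier
  b <- rnorm(20)
  rep_with <- compare_groups(list(a = a, b = b), rout_q = 0.01)
  expect_identical(rep_with$outliers_removed$indices$a, 21L)
  expect_length(rep_with$groups$a, 20L)
})
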