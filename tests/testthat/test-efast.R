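# closed-form Sobol decomposition of the Ishigami function
# f = sin x1 + a sin^2 x2 + b x3^4 sin x1, x ~ U(-pi, pi)^3
ishigami <- function(u, a = 7, b = 0.1) {
  x <- 2 * pi * (u - 0.5)
  sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1])
}
ishigami_sobol <- function(a = 7, b = 0.1) {
  v1 <- (1 + b * pi^4 / 5)^2 / 2
  v2 <- a^2 / 8
  v13 <- 8 * b^2 * pi^8 / 225
  v <- v1 + v2 + v13
  list(s = c(v1, v2, 0) / v, st = c(v1 + v13, v2, v13) / v)
}

test_that("search-curve designs obey the frequency and range constraints", {
  d <- fast_design(paste0("x", 1:5), ns = 729, M = 4, seed = 1)
  expect_equal(d$omega_max, 91)   # floor((729 - 1) / (2 * 4))
  for (fc in d$factors) {
    pts <- d$curves[[fc]][[1]]$points
    expect_equal(dim(pts), c(729L, 5L))
    expect_true(all(pts >= 0 & pts <= 1))
    w <- d$curves[[fc]][[1]]$omega
    expect_equal(w[match(fc, d$factors)], 91)
    expect_true(all(w[-match(fc, d$factors)] <= floor(91 / 8)))
    # the driven coordinate sweeps its range nearly uniformly
    ks <- suppressWarnings(
      stats::ks.test(pts[, fc], "punif")$statistic)
    expect_lt(unname(ks), 0.05)
  }
  expect_error(fast_design("x", ns = 730), "odd")
})

test_that("a pure single-factor model gives s_i close to s_ti close to 1", {
  d <- fast_design(c("a", "b", "c"), ns = 729, seed = 2)
  f <- function(u) sin(2 * pi * u[["a"]]) + 0.3 * u[["a"]]^2
  res <- fast_analyze(f, d)
  ra <- res[res$factor == "a", ]
  expect_equal(ra$s_i, 1, tolerance = 0.03)
  expect_equal(ra$s_ti, 1, tolerance = 0.03)
  # a factor the model ignores carries no first-order power
  rb <- res[res$factor == "b", ]
  expect_equal(rb$s_i, 0, tolerance = 0.02)
})

test_that("Ishigami indices match the closed-form Sobol values", {
  d <- fast_design(c("x1", "x2", "x3"), ns = 729, seed = 3, resamples = 6)
  res <- fast_analyze(function(u) ishigami(u), d)
  ref <- ishigami_sobol()
  for (i in 1:3) {
    expect_lt(abs(res$s_i[i] - ref$s[i]), 0.05)
    expect_lt(abs(res$s_ti[i] - ref$st[i]), 0.05)
  }
  # universal index inequalities
  expect_true(all(res$s_i >= -1e-6))
  expect_true(all(res$s_ti >= res$s_i - 1e-6))
  expect_true(all(res$s_ti <= 1 + 1e-6))
})

test_that("additive models close the first-order budget without interactions", {
  d <- fast_design(c("u", "v", "w"), ns = 729, seed = 4, resamples = 4)
  res <- fast_analyze(function(x) x[["u"]] + 2 * x[["v"]]^2 +
                        sin(pi * x[["w"]]), d)
  expect_gte(sum(res$s_i), 0.95)
  expect_lte(sum(res$s_i), 1.02)
  expect_true(all(res$s_ti - res$s_i < 0.05))
})

test_that("interacting factors show total indices exceeding first-order", {
  d <- fast_design(c("u", "v", "w"), ns = 729, seed = 5)
  res <- fast_analyze(function(x) x[["u"]] * x[["v"]] + 0.1 * x[["w"]], d)
  expect_gt(res$s_ti[res$factor == "u"] - res$s_i[res$factor == "u"], 0.05)
  expect_gt(res$s_ti[res$factor == "v"] - res$s_i[res$factor == "v"], 0.05)
})

test_that("index estimates are stable under phase reseeding", {
  ests <- t(vapply(1:10, function(s) {
    d <- fast_design(c("x1", "x2", "x3"), ns = 729, seed = s, resamples = 6)
    res <- fast_analyze(function(u) ishigami(u), d)
    c(res$s_i, res$s_ti)
  }, numeric(6)))
  expect_true(all(apply(ests, 2, stats::sd) < 0.02))
})

test_that("constant output raises an undefined-index error", {
  d <- fast_design(c("a", "b"), ns = 65, seed = 6)
  expect_error(fast_indices(rep(1, 65), d, "a"), "constant")
})

test_that("failed curve points are repaired or the curve is dropped", {
  d <- fast_design(c("a", "b"), ns = 729, seed = 7)
  n_bad <- 0
  f <- function(u) {
    n_bad <<- n_bad + 1
    if (n_bad %% 400 == 0) NA_real_ else u[["a"]]^2
  }
  res <- fast_analyze(f, d)   # < 1% failures: interpolated
  expect_equal(nrow(res), 2L)
  f2 <- function(u) if (u[["a"]] > 0.5) NA_real_ else u[["a"]]
  w <- testthat::capture_warnings(res2 <- fast_analyze(f2, d))
  expect_true(any(grepl("dropped", w)))
})

test_that("influential-factor selection implements the coverage rule", {
  tab <- expand.grid(factor = c("A", "B", "C"), site = "S1",
                     n_treatment = "HN", year = 1:4,
                     stringsAsFactors = FALSE)
  tab$s_ti <- ifelse(tab$factor == "A", 1, 0)
  expect_equal(select_influential(tab), "A")
  # two factors each holding half the budget: 90% coverage needs both
  tab$s_ti <- ifelse(tab$factor == "C", 0, 0.5)
  expect_setequal(select_influential(tab), c("A", "B"))
  # a factor marked in under half the years is not selected
  tab$s_ti <- ifelse(tab$factor == "A", 1,
                     ifelse(tab$factor == "B" & tab$year == 1, 50, 0))
  expect_equal(select_influential(tab), "A")
})

test_that("the published screening selection counts are reproduced", {
  sel <- efast_parameter_table()
  expect_equal(nrow(sel), 41L)
  counts <- table(sel$submodel)
  expect_equal(as.integer(counts[c("Phenology", "Leaf layer expansion",
                                   "Light interception and use efficiency",
                                   "Grain", "DM allocation", "N allocation",
                                   "Root growth and N uptake",
                                   "Soil drought factors")]),
               c(9L, 6L, 5L, 3L, 1L, 9L, 3L, 5L))
})
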