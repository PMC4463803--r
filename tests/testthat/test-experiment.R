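test_that("grain protein deviation is the OLS residual of GPC on GY", {
  # perfectly linear: all residuals zero, r2 = 1
  gy <- c(0.3, 0.4, 0.5, 0.6)
  gpc <- 20 - 10 * gy
  g <- suppressWarnings(grain_protein_deviation(gpc, gy))
  expect_equal(g$residuals, rep(0, 4), tolerance = 1e-12)
  expect_equal(g$r2, 1)
  expect_equal(g$slope, -10)
  # hand-computed three-point least squares
  g3 <- grain_protein_deviation(c(10, 8, 9), c(1, 2, 3))
  expect_equal(g3$slope, -0.5)
  expect_equal(g3$residuals, c(0.5, -1, 0.5))
  # residuals of an OLS fit with intercept always sum to zero
  set.seed(5)
  g4 <- grain_protein_deviation(rnorm(30, 12), runif(30, 0.2, 0.7))
  expect_equal(sum(g4$residuals), 0, tolerance = 1e-9)
  # degenerate: no yield variance
  g5 <- grain_protein_deviation(c(10, 11, 12), c(0.5, 0.5, 0.5))
  expect_false(g5$slope_defined)
  expect_equal(g5$residuals, c(-1, 0, 1))
})

test_that("distribution summaries give monotone CDFs and exact quantiles", {
  s <- summarize_distributions(c(1, 2, 3))
  expect_equal(s$q50, 2)
  e <- attr(s, "ecdf")$all
  grid <- seq(0, 4, 0.1)
  expect_true(all(diff(e(grid)) >= 0))
  expect_equal(e(0), 0)
  expect_equal(e(4), 1)
  s2 <- summarize_distributions(rep(7, 5))
  expect_equal(unlist(s2[1, c("q10", "q90")]), c(q10 = 7, q90 = 7))
})

test_that("a small Morris experiment runs end to end and is resumable", {
  dir <- withr::local_tempdir()
  args <- list(factors = c("RUE", "P", "Dgf", "EarGR"),
               sites = "CF", n_treatments = "HN", years = 2, r = 4,
               seed = 9, store_dir = dir)
  t1 <- do.call(morris_experiment, args)
  expect_equal(length(list.files(dir, pattern = "^morris_")), 2L)
  expect_setequal(unique(t1$stats$factor), args$factors)
  expect_setequal(unique(t1$stats$output),
                  c("anthesis", "gai", "crop_dm", "crop_n", "grain_dm",
                    "grain_n", "post_n", "gpc", "gpd"))
  expect_true(all(t1$stats$mu_star >= abs(t1$stats$mu) - 1e-9))
  expect_true(all(t1$stats$sigma >= 0))
  # resumed run reloads the shards and reproduces the statistics
  t2 <- do.call(morris_experiment, args)
  expect_equal(t2$stats$mu_star, t1$stats$mu_star, tolerance = 1e-9)
  # RUE dominates grain yield in this subset
  gd <- t1$stats[t1$stats$output == "grain_dm", ]
  med <- tapply(gd$mu_star, gd$factor, median)
  expect_equal(names(which.max(med)), "RUE")
})

test_that("a scaled-down extended-FAST experiment produces valid indices", {
  ef <- efast_experiment(factors = c("RUE", "P", "Dgf"),
                         sites = "CF", n_treatments = "HN", years = 1,
                         ns = 65, seed = 10)
  idx <- ef$indices
  expect_true(all(idx$s_ti >= idx$s_i - 1e-6))
  expect_true(all(idx$s_ti <= 1 + 1e-6))
  gd <- idx[idx$output == "grain_dm", ]
  expect_equal(gd$factor[which.max(gd$s_ti)], "RUE")
})

test_that("heat-map tables aggregate, rescale and order by submodel", {
  st <- expand.grid(factor = c("RUE", "P", "Dse"), site = c("CF", "RR"),
                    n_treatment = "HN", year = 1:3,
                    output = c("grain_dm", "gpc"), stringsAsFactors = FALSE)
  st$mu_star <- seq_len(nrow(st)) / 10
  hm <- build_heatmaps(st, value = "mu_star", rescale = TRUE)
  expect_true(all(hm$value_scaled >= 0 & hm$value_scaled <= 1))
  for (out in unique(hm$output)) {
    expect_equal(max(hm$value_scaled[hm$output == out]), 1)
    expect_equal(min(hm$value_scaled[hm$output == out]), 0)
  }
  # rows follow the parameter-table submodel order: Dse (phenology) before
  # P (phenology, later row) before RUE (light interception block)
  first <- tapply(seq_len(nrow(hm)), hm$factor, min)
  expect_lt(first[["Dse"]], first[["P"]])
  expect_lt(first[["P"]], first[["RUE"]])
  # signs flip the rescaled values into [-1, 1]
  sg <- unique(st[c("factor", "site", "n_treatment", "output")])
  sg$sign <- -1
  hm2 <- build_heatmaps(st, signs = sg)
  expect_true(all(hm2$value_scaled <= 0))
})
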