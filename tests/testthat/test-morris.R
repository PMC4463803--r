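test_that("trajectory designs obey the grid-walk invariants", {
  d <- sample_trajectories(75, p = 8, r = 10, seed = 3)
  expect_equal(nrow(d$points), 760L)        # r * (k + 1)
  expect_equal(d$delta, 4 / 7)              # p / (2 (p - 1))
  expect_true(all(d$points >= 0 & d$points <= 1))
  # every coordinate sits on the 8-level grid
  lv <- round(d$points * 7, 9)
  expect_true(all(abs(lv - round(lv)) < 1e-9))
  # each consecutive within-trajectory pair differs in exactly one
  # coordinate, by +/- delta
  for (t in 1:10) {
    rows <- ((t - 1) * 76 + 1):(t * 76)
    for (j in 2:76) {
      dif <- d$points[rows[j], ] - d$points[rows[j - 1], ]
      moved <- which(dif != 0)
      expect_length(moved, 1L)
      expect_equal(abs(dif[moved]), 4 / 7, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
  expect_error(sample_trajectories(5, p = 7), "even")
  # deterministic under the seed
  expect_identical(sample_trajectories(10, seed = 7)$points,
                   sample_trajectories(10, seed = 7)$points)
})

test_that("elementary effects recover linear coefficients exactly", {
  d <- sample_trajectories(3, r = 6, seed = 4)
  a <- c(3, -1, 0.5)
  y <- as.numeric(d$points %*% a)
  ee <- elementary_effects(d, y)
  for (i in 1:3) {
    expect_equal(unname(ee[[i]]), rep(a[i], 6), tolerance = 1e-10)
  }
  st <- morris_stats(ee)
  expect_equal(st$mu_star, abs(a), tolerance = 1e-10)
  expect_true(all(st$sigma < 1e-10))
  # constant model: all zero effects
  ee0 <- elementary_effects(d, rep(2, nrow(d$points)))
  expect_true(all(unlist(ee0) == 0))
})

test_that("statistics match hand arithmetic", {
  st <- morris_stats(list(a = c(1, 1, 1), b = c(-1, 1)))
  expect_equal(st$mu_star, c(1, 1))
  expect_equal(st$sigma, c(0, sqrt(2)))
  expect_equal(st$mu, c(1, 0))
  expect_error(morris_stats(list(a = 1)), ">= 2")
})

test_that("sampled mu*/sigma converge to the brute-force grid values", {
  fns <- list(
    prod2 = list(f = function(x) x[1] * x[2], k = 2),
    mix3 = list(f = function(x) x[1]^2 + x[1] * x[2] + 0.5 * x[3], k = 3)
  )
  for (nm in names(fns)) {
    f <- fns[[nm]]$f; k <- fns[[nm]]$k
    # estimator average over four r=200 designs (the single-design sigma
    # estimate carries sampling noise of the same order as the 5% band)
    ests <- lapply(1:4, function(s) {
      d <- sample_trajectories(k, r = 200, seed = s)
      y <- apply(d$points, 1, f)
      morris_stats(elementary_effects(d, y))
    })
    st <- ests[[1]]
    st$mu_star <- rowMeans(vapply(ests, `[[`, numeric(k), "mu_star"))
    st$sigma <- rowMeans(vapply(ests, `[[`, numeric(k), "sigma"))
    for (i in seq_len(k)) {
      bf <- brute_force_ee(f, k, i)
      mu_ref <- mean(abs(bf))
      sd_ref <- sqrt(mean((bf - mean(bf))^2))  # population sd of the
      # enumerated elementary-effect distribution
      expect_lt(abs(st$mu_star[i] - mu_ref), 0.05 * max(mu_ref, 0.1))
      expect_lt(abs(st$sigma[i] - sd_ref), 0.05 * max(sd_ref, 0.1))
    }
    # interaction: the factor multiplying another has sigma > 0
    if (nm == "prod2") expect_gt(st$sigma[1], 0.1)
  }
})

test_that("mu* is scale-equivariant", {
  f <- function(x) x[1]^2 + x[2]
  d <- sample_trajectories(2, r = 50, seed = 6)
  y1 <- apply(d$points, 1, f)
  y3 <- apply(d$points, 1, function(x) 3 * x[1]^2 + x[2])
  s1 <- morris_stats(elementary_effects(d, y1))
  s3 <- morris_stats(elementary_effects(d, y3))
  expect_equal(s3$mu_star[1], 3 * s1$mu_star[1], tolerance = 1e-9)
})

test_that("incomplete trajectories are dropped with a warning", {
  d <- sample_trajectories(2, r = 4, seed = 8)
  y <- as.numeric(d$points %*% c(1, 2))
  y[4] <- NA
  expect_warning(ee <- elementary_effects(d, y), "dropped 1")
  expect_length(ee[[1]], 3L)
})

test_that("heat-map rescaling maps each column onto [0, 1]", {
  m <- cbind(a = c(2, 4, 10), b = c(-1, 0, 3))
  r <- rescale_heatmap(m)
  expect_equal(r[, "a"], c(0, 0.25, 1))
  expect_equal(range(r), c(0, 1))
  # affine invariance
  expect_equal(rescale_heatmap(5 * m + 2), r, ignore_attr = TRUE)
  expect_warning(rescale_heatmap(cbind(c(1, 1, 1))), "constant")
})

test_that("one-at-a-time regression recovers the sign of the effect", {
  base <- c(x = 2, y = 3)
  expect_equal(sign_by_oat(function(p) 2 * p[["x"]], base, "x"), 1)
  expect_equal(sign_by_oat(function(p) 5, base, "x"), 0)
  expect_equal(sign_by_oat(function(p) -p[["x"]]^3, base, "x"), -1)
  expect_warning(
    s <- sign_by_oat(function(p) NA_real_, base, "x"),
    "undetermined")
  expect_equal(s, 0)
})
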