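test_that("environment generation is seed-deterministic with additive future deltas", {
  g <- build_grid(-70, -60, 40, 50, 0.5)
  e1 <- gen_environment(g, seed = 5)
  e2 <- gen_environment(g, seed = 5)
  expect_identical(e1, e2)
  e3 <- gen_environment(g, seed = 6)
  expect_false(identical(e1$periods$present$SST, e3$periods$present$SST))

  # zero noise: future field exactly equals present + delta
  p0 <- env_params(noise_sd = 0)
  e4 <- gen_environment(g, p0, seed = 5)
  expect_equal(e4$periods$mid_future$SST,
               e4$periods$present$SST + p0$delta$mid_future[["SST"]])

  # with noise the mean shift still matches the configured delta
  p1 <- env_params(noise_sd = 0.1)
  e5 <- gen_environment(g, p1, seed = 5)
  expect_equal(mean(e5$periods$mid_future$SST) - mean(e5$periods$present$SST),
               2, tolerance = 0.05)
  expect_error(gen_environment(g, env_params(corr_range = 1000)), "larger")
})

test_that("true suitability is a logistic in standardized covariates", {
  env <- quick_env()
  # all-zero coefficients -> constant 0.5
  tp <- truth_params(species_coef = list(blue = c("(Intercept)" = 0, SST = 0)))
  s0 <- true_suitability(env, tp, "blue")
  expect_true(all(abs(surface_values(s0) - 0.5) < 1e-12))

  # large negative SST coefficient -> suitability decreases with SST
  tp2 <- truth_params(species_coef = list(blue = c("(Intercept)" = 0, SST = -5)))
  s1 <- true_suitability(env, tp2, "blue")
  sst <- env$periods$present$SST[env$grid$mask]
  expect_lt(cor(surface_values(s1), sst, method = "spearman"), -0.99)

  # invariance to affine rescaling of a covariate (standardization internal)
  env2 <- env
  env2$periods$present$SST <- 1.8 * env$periods$present$SST + 32
  expect_equal(true_suitability(env2, tp2, "blue")$values, s1$values)

  expect_error(true_suitability(env, tp, "narwhal"), "no suitability")
})

test_that("sighting sampling follows suitability-times-effort weights", {
  g <- build_grid(0, 5, 0, 5, 1)
  suit <- surface(g, rep(1, 25))
  eff <- surface(g, c(1, rep(0, 24)))
  pts <- sample_sightings(suit, eff, 50, seed = 2)
  expect_true(all(pts$cell == 1))
  expect_true(all(pts$lon >= 0 & pts$lon <= 1 & pts$lat >= 0 & pts$lat <= 1))

  # chi-square goodness of fit against the weights at n = 10,000
  set.seed(4)
  w <- runif(25, 0.2, 1)
  pts2 <- sample_sightings(surface(g, w), surface(g, rep(1, 25)), 10000, seed = 8)
  obs <- tabulate(pts2$cell, nbins = 25)
  expect_gt(chisq.test(obs, p = w / sum(w))$p.value, 0.01)

  expect_identical(sample_sightings(suit, eff, 20, seed = 3),
                   sample_sightings(suit, eff, 20, seed = 3))
  expect_error(sample_sightings(suit, surface(g, rep(0, 25)), 5), "zero")
})

test_that("vessel activity peaks at hotspots and honours the target total", {
  g <- build_grid(0, 10, 0, 10, 0.5)
  hs <- data.frame(lon = 3.1, lat = 7.2, intensity = 100, sd = 1)
  tp <- truth_params(hotspots = hs, vessel_noise_sdlog = 0)
  v <- gen_vessel_activity(g, tp, seed = 1)
  expect_equal(which.max(v$values), cell_index(g, 3.1, 7.2))

  tp2 <- truth_params(hotspots = hs, vessel_total = 82141732)
  v2 <- gen_vessel_activity(g, tp2, seed = 1)
  expect_equal(sum(surface_values(v2)), 82141732, tolerance = 1e-3)

  expect_identical(gen_vessel_activity(g, tp, seed = 9),
                   gen_vessel_activity(g, tp, seed = 9))
  expect_error(gen_vessel_activity(g, truth_params(hotspots = hs[0, ])),
               "hotspot")
})

test_that("incident counts follow the zero-inflated negative-binomial truth", {
  g <- build_grid(0, 100, 0, 100, 1)  # 10,000 cells
  set.seed(6)
  V <- surface(g, runif(g$ncell, 0, 2))
  HSV <- surface(g, runif(g$ncell))

  # pi = 1: everything structurally zero
  tp1 <- truth_params(incident = list(beta0 = 1, beta1 = 0.5, beta2 = 1,
                                      theta = 2, pi = 1))
  expect_true(all(gen_incidents(tp1, seed = 1, V = V, HSV = HSV)$values == 0))

  # theta large, pi = 0: Poisson limit, variance ~ mean cell-wise
  tp2 <- truth_params(incident = list(beta0 = 0.5, beta1 = 0, beta2 = 0,
                                      theta = 1e6, pi = 0))
  ni <- surface_values(gen_incidents(tp2, seed = 2, V = V, HSV = HSV))
  expect_equal(var(ni) / mean(ni), 1, tolerance = 0.05)

  # empirical mean matches the closed-form ZINB mean (1 - pi) * mu
  tp3 <- truth_params(incident = list(beta0 = 0.4, beta1 = 0.6, beta2 = 0.8,
                                      theta = 1.5, pi = 0.3))
  ni3 <- surface_values(gen_incidents(tp3, seed = 3, V = V, HSV = HSV))
  mu <- exp(0.4 + 0.6 * surface_values(V) + 0.8 * surface_values(HSV))
  expect_equal(mean(ni3), 0.7 * mean(mu), tolerance = 0.03)

  expect_error(gen_incidents(truth_params(incident = list(
    beta0 = 0, beta1 = 0, beta2 = 0, theta = -1, pi = 0)), V = V, HSV = HSV),
    "theta")
})

test_that("acoustic detections are Bernoulli in the local suitability", {
  g <- build_grid(0, 10, 0, 10, 1)
  rec <- data.frame(lon = c(2.5, 7.5), lat = c(2.5, 7.5))
  sure <- surface(g, rep(1, 100))
  d1 <- gen_acoustic_detections(sure, rec, 20, seed = 1)
  expect_true(all(d1$detection == 1))
  none <- surface(g, rep(0, 100))
  expect_true(all(gen_acoustic_detections(none, rec, 20, seed = 1)$detection == 0))

  # detection fraction within the binomial CI at n = 1,000
  p <- 0.37
  s <- surface(g, rep(p, 100))
  d <- gen_acoustic_detections(s, rec[1, , drop = FALSE], 1000, seed = 5)
  ci <- binom.test(sum(d$detection), 1000, p)$p.value
  expect_gt(ci, 0.001)

  expect_error(gen_acoustic_detections(sure, data.frame(lon = 50, lat = 5), 5),
               "outside")
  gmask <- g; gmask$mask[cell_index(g, 2.5, 2.5)] <- FALSE
  smask <- surface(gmask, rep(1, 100))
  expect_error(gen_acoustic_detections(smask, rec, 5), "masked")
})
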