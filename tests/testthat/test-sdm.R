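test_that("collinearity filter removes the right variables", {
  set.seed(1)
  a <- rnorm(200); b <- a + rnorm(200, sd = 1e-8); c <- rnorm(200)
  # two identical variables -> exactly one survives
  expect_equal(filter_collinear(cbind(A = a, B = b, C = c)), c("B", "C"))
  # nothing correlated -> everything retained
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_setequal(filter_collinear(X), c("A", "B", "C"))
  # r(A,B) = 0.9, others low: the minimal removal is one of {A, B}, matching
  # an exhaustive search over retained subsets
  b2 <- 0.9 * scale(a) + sqrt(1 - 0.81) * rnorm(200)
  X2 <- cbind(A = as.numeric(scale(a)), B = as.numeric(b2), C = c)
  got <- filter_collinear(X2, threshold = 0.7)
  subsets <- list(c("A", "C"), c("B", "C"))
  ok <- function(s) max(abs(cor(X2[, s]))[upper.tri(diag(2))]) <= 0.7
  expect_true(any(vapply(subsets, function(s) setequal(got, s) && ok(s),
                         logical(1))))
  expect_warning(filter_collinear(cbind(A = a, K = rep(1, 200))), "constant")
})

test_that("pseudo-absences are uniform over eligible cells and never presences", {
  g <- tiny_grid(5)  # 25 cells
  pres <- c(1, 2, 3)
  pa <- generate_pseudo_absences(g, pres, n = 10, seed = 1)
  expect_length(pa, 10)
  expect_length(intersect(pa, pres), 0)
  expect_warning(all_pa <- generate_pseudo_absences(g, pres, n = 100, seed = 1),
                 "eligible")
  expect_setequal(all_pa, setdiff(1:25, pres))

  # empirical selection frequency uniform across reseeds (chi-square)
  counts <- integer(25)
  for (s in 1:1000) {
    draw <- generate_pseudo_absences(g, pres, n = 5, seed = s)
    counts[draw] <- counts[draw] + 1L
  }
  expect_equal(sum(counts[pres]), 0L)
  expect_gt(chisq.test(counts[-pres])$p.value, 0.01)
})

test_that("TSS equals sensitivity + specificity - 1 and the optimizer maximizes it", {
  # TP=40, FN=10, TN=30, FP=20 -> sens 0.8, spec 0.6, TSS 0.4
  labels <- c(rep(1, 50), rep(0, 50))
  scores <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
  expect_equal(tss(labels, scores, 0.5), 0.4)
  # perfect separation
  expect_equal(tss(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 0.5), 1)
  # constant score carries no skill
  expect_equal(tss(c(1, 0, 1, 0), rep(0.3, 4), 0.5), 0)
  expect_error(tss(c(1, 1), c(0.5, 0.9), 0.5), "both classes")

  # optimizer equals brute force over unique score values
  set.seed(2)
  for (i in 1:20) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(40), 2)
    brute <- sapply(sort(unique(s)), function(t) tss(y, s, t))
    expect_equal(tss(y, s, optimize_threshold(y, s)), max(brute))
  }
})

test_that("cross-validation is deterministic, null on permuted labels, strong on real signal", {
  truth <- covariate_truth(40, c(x1 = 2.5, x2 = -2, x3 = 1.5), b0 = -1,
                           n_presence = 300, seed = 3)
  set.seed(4)
  ab <- sample(truth$absence_pool, 700)
  occ <- make_occurrence(truth$presence, ab, truth$X)

  cv1 <- cross_validate(occ, "glm", repeats = 3, seed = 5)
  cv2 <- cross_validate(occ, "glm", repeats = 3, seed = 5)
  expect_identical(cv1, cv2)
  expect_gt(cv1$mean_tss, 0.7)

  # label permutation destroys the skill (n = 2,000 rows)
  truth2 <- covariate_truth(50, c(x1 = 2.5, x2 = -2, x3 = 1.5), b0 = 0,
                            n_presence = 1000, seed = 6)
  pa2 <- generate_pseudo_absences(truth2$grid, truth2$presence, 1000, seed = 7)
  occ2 <- make_occurrence(truth2$presence, pa2, truth2$X)
  set.seed(8)
  occ2$y <- sample(occ2$y)
  null_cv <- cross_validate(occ2, "glm", repeats = 3, seed = 9)
  expect_lt(abs(null_cv$mean_tss), 0.1)
})

test_that("member models produce calibrated scores in [0, 1]", {
  # GLM on a linearly separable toy: score order matches labels
  occ_toy <- structure(list(
    y = c(1L, 1L, 0L, 0L),
    X = matrix(c(2, 1.5, -1.5, -2), ncol = 1, dimnames = list(NULL, "x1"))),
    class = "occurrence_data")
  m <- suppressWarnings(fit_member("glm", occ_toy))
  s <- predict(m, occ_toy$X)
  expect_true(all(s[1:2] > s[3:4]))
  expect_true(all(s >= 0 & s <= 1))

  # random forest on pure noise: no out-of-sample skill
  set.seed(10)
  occ_noise <- structure(list(
    y = rep(c(0L, 1L), each = 300),
    X = matrix(rnorm(1200), 600, 2, dimnames = list(NULL, c("x1", "x2")))),
    class = "occurrence_data")
  cv <- cross_validate(occ_noise, "rf", repeats = 3, seed = 11)
  expect_lt(abs(cv$mean_tss), 0.2)

  # maxent member at crushing regularization: near-constant score at the
  # presence prevalence (penalized-likelihood limit)
  truth <- covariate_truth(30, c(x1 = 2, x2 = -1.5), n_presence = 200, seed = 12)
  pa <- generate_pseudo_absences(truth$grid, truth$presence, 400, seed = 13)
  occ <- make_occurrence(truth$presence, pa, truth$X)
  mx <- fit_member("maxent", occ, seed = 14)
  shrunk <- as.numeric(predict(mx$fit$glmnet.fit,
                               newx = whalerisk:::expand_features(occ$X, products = TRUE),
                               s = 1e6, type = "response"))
  expect_equal(unname(shrunk), rep(mean(occ$y), length(occ$y)), tolerance = 1e-3)
})

test_that("ensemble weighting follows mean TSS with the stated cutoff", {
  truth <- covariate_truth(40, c(x1 = 2.5, x2 = -2, x3 = 1.5), b0 = -1,
                           n_presence = 400, seed = 15)
  set.seed(16)
  ab <- sample(truth$absence_pool, 800)
  occ <- make_occurrence(truth$presence, ab, truth$X)
  ens <- build_ensemble(occ, repeats = 2, seed = 17, num_trees = 150,
                        ensemble_cv = FALSE)
  # weights proportional to mean TSS of included members, summing to one
  inc <- names(ens$weights)
  expect_equal(unname(ens$weights),
               unname(ens$member_tss[inc] / sum(ens$member_tss[inc])))
  expect_equal(sum(ens$weights), 1)
  # ensemble score is the hand-computed weighted mean of member scores
  probe <- occ$X[1:7, , drop = FALSE]
  manual <- rowSums(sapply(inc, function(k)
    ens$weights[[k]] * predict(ens$members[[k]], probe)))
  expect_equal(unname(predict(ens, probe, standardized = TRUE)), unname(manual))
  # ensemble score bounded by the member score range per point
  per_member <- sapply(inc, function(k) predict(ens$members[[k]], probe))
  expect_true(all(predict(ens, probe, standardized = TRUE) >=
                    apply(per_member, 1, min) - 1e-12))
  expect_true(all(predict(ens, probe, standardized = TRUE) <=
                    apply(per_member, 1, max) + 1e-12))

  # an unreachable cutoff errors, naming the best member
  expect_error(build_ensemble(occ, kinds = "glm", cutoff = 1.01, repeats = 2,
                              seed = 18), "best is glm")
})

test_that("projection reproduces training scores and reports clamping", {
  env <- quick_env()
  tp <- truth_params()
  suit <- true_suitability(env, tp, "minke")
  eff <- effort_surface(env)
  sg <- sample_sightings(suit, eff, 300, seed = 19, species = "minke")
  pc <- which(presence_binarize(aggregate_points(sg, env$grid))$values == 1)
  # background = every other ocean cell, so training spans the domain range
  pa <- suppressWarnings(
    generate_pseudo_absences(env$grid, pc, n = env$grid$ncell, seed = 20))
  X <- env_covariates(env, "present")
  occ <- make_occurrence(pc, pa, X, species = "minke")
  ens <- build_ensemble(occ, kinds = "glm", cutoff = 0.3, repeats = 2,
                        seed = 21, ensemble_cv = FALSE)

  pr <- project_suitability(ens, env, "present")
  expect_true(all(surface_values(pr$hsv) >= 0 & surface_values(pr$hsv) <= 1))
  # projecting onto the training cells reproduces fitted scores
  fitted <- predict(ens, occ$X, standardized = TRUE)
  expect_equal(unname(pr$hsv$values[occ$cells]), unname(fitted))
  # clamping report empty when projecting the training period...
  expect_equal(nrow(pr$clamping), 0)
  # ...and flags a cell pushed beyond the training SST range
  env2 <- env
  hot <- which(env$grid$mask)[1]
  env2$periods$present$SST[hot] <- max(X[occ$cells, "SST"]) + 10
  pr2 <- project_suitability(ens, env2, "present")
  expect_true(hot %in% pr2$clamping$cell)
  expect_true("SST" %in% pr2$clamping$covariate)
})

test_that("permutation importance ranks informative covariates above a null one", {
  truth <- covariate_truth(40, c(x1 = 2.5, x2 = -2, x3 = 1.5, nullv = 0),
                           b0 = -1, n_presence = 400, seed = 22)
  set.seed(23)
  ab <- sample(truth$absence_pool, 800)
  occ <- make_occurrence(truth$presence, ab, truth$X)
  ens <- build_ensemble(occ, kinds = "glm", cutoff = 0.3, repeats = 2,
                        seed = 24, ensemble_cv = FALSE)
  vi1 <- variable_importance(ens, occ, seed = 25)
  vi2 <- variable_importance(ens, occ, seed = 25)
  expect_identical(vi1, vi2)
  expect_true(all(vi1$importance > -0.05))
  # the zero-coefficient covariate sits at the bottom
  expect_gt(vi1$rank[vi1$variable == "nullv"], 2)
})

test_that("acoustic evaluation summarizes suitability by detection class", {
  g <- build_grid(0, 4, 0, 4, 1)
  hsv <- surface(g, seq(0.05, 0.8, length.out = 16))
  top <- cell_centroids(g, which.max(hsv$values))
  det <- data.frame(lon = top$lon, lat = top$lat, detection = 1)
  ev <- evaluate_against_detections(hsv, det)
  expect_equal(ev$mean_hsv_detection, max(hsv$values))
  expect_true(is.na(ev$mean_hsv_non_detection))

  # labels random w.r.t. suitability: group means agree
  set.seed(26)
  cen <- cell_centroids(g)
  idx <- sample(16, 4000, replace = TRUE)
  det2 <- data.frame(lon = cen$lon[idx], lat = cen$lat[idx],
                     detection = rbinom(4000, 1, 0.5))
  ev2 <- evaluate_against_detections(hsv, det2)
  expect_equal(ev2$mean_hsv_detection, ev2$mean_hsv_non_detection,
               tolerance = 0.05)

  # detections generated from the true suitability separate the classes
  env <- quick_env()
  suit <- true_suitability(env, truth_params(), "fin")
  ocean <- which(env$grid$mask & suit$values > 0.05 & suit$values < 0.95)
  set.seed(27)
  rc <- cell_centroids(env$grid, sample(ocean, 15))
  det3 <- gen_acoustic_detections(suit, data.frame(lon = rc$lon, lat = rc$lat),
                                  60, seed = 28)
  ev3 <- evaluate_against_detections(suit, det3)
  expect_gt(ev3$mean_hsv_detection, ev3$mean_hsv_non_detection)
  expect_equal(nrow(ev3$receivers), 15)
})
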