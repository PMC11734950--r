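#' Presence-only ensemble species distribution modelling
#'
#' Covariate screening, pseudo-absence generation, three member models (GLM,
#' random forest, maximum entropy), repeated stratified cross-validation
#' scored by the True Skill Statistic, a TSS-weighted ensemble, permutation
#' variable importance, projection with clamping diagnostics, and independent
#' evaluation against acoustic detections.
#'
#' @name sdm
NULL

#' Greedy collinearity filter
#'
#' Removes variables until all pairwise |r| are at or below the threshold.
#' At each step the variable with the largest mean absolute correlation with
#' the others is dropped (ties broken alphabetically). Constant variables
#' (undefined correlation) are dropped first with a warning.
#'
#' @param covariates numeric matrix or data.frame with named columns.
#' @param threshold pairwise |r| cutoff (default 0.7).
#' @return character vector of retained variable names.
#' @export
filter_collinear <- function(covariates, threshold = 0.7) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("need at least two variables")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | !is.finite(sds))) {
    warning("dropping constant variable(s): ",
            paste(colnames(X)[sds == 0 | !is.finite(sds)], collapse = ", "))
    X <- X[, sds > 0 & is.finite(sds), drop = FALSE]
  }
  keep <- sort(colnames(X))
  repeat {
    if (length(keep) < 2) break
    r <- abs(stats::cor(X[, keep, drop = FALSE], use = "pairwise.complete.obs"))
    diag(r) <- 0
    if (max(r) <= threshold) break
    meanr <- rowMeans(r)
    drop <- names(which.max(meanr))  # which.max takes the first = alphabetical
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Random pseudo-absence cells
#'
#' Uniform sample without replacement from masked-in (ocean) cells excluding
#' presence cells. If fewer eligible cells than requested, all are returned
#' with a warning.
#'
#' @param grid a [build_grid()] grid.
#' @param presence_cells integer cell ids with presences.
#' @param n number of pseudo-absences (default 10000).
#' @param seed integer RNG seed.
#' @return integer vector of cell ids.
#' @export
generate_pseudo_absences <- function(grid, presence_cells, n = 10000, seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  eligible <- setdiff(which(grid$mask), presence_cells)
  if (length(eligible) == 0) stop("no eligible cells for pseudo-absences")
  set.seed(as.integer(seed))
  if (length(eligible) < n) {
    warning(sprintf("only %d eligible cells for %d requested pseudo-absences; using all",
                    length(eligible), n))
    return(sample(eligible))  # shuffled for downstream splits
  }
  sample(eligible, n)
}

#' True Skill Statistic
#'
#' `tss()` evaluates sensitivity + specificity - 1 classifying `scores >=
#' threshold` as presence; `optimize_threshold()` returns the threshold (among
#' the unique score values) maximizing TSS.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric scores, same length.
#' @param threshold classification cutoff.
#' @return `tss()`: a number in \[-1, 1\]. `optimize_threshold()`: a threshold.
#' @export
tss <- function(labels, scores, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to compute TSS")
  pred <- scores >= threshold
  sens <- sum(pred & labels == 1) / sum(labels == 1)
  spec <- sum(!pred & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

#' @rdname tss
#' @export
optimize_threshold <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to optimize a threshold")
  thr <- sort(unique(scores))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  # per unique threshold t: predicted presence = score >= t; sweep ascending,
  # peeling off counts of each unique value as it drops below the threshold
  m <- match(scores, thr)
  pos_at <- tabulate(m[labels == 1], nbins = length(thr))
  neg_at <- tabulate(m[labels == 0], nbins = length(thr))
  tp <- npos - c(0, cumsum(pos_at))[seq_along(thr)]  # labels 1 with score >= t
  fp <- nneg - c(0, cumsum(neg_at))[seq_along(thr)]
  tssv <- tp / npos + (nneg - fp) / nneg - 1
  thr[which.max(tssv)]
}

#' Assemble an occurrence data set
#'
#' Couples presence and pseudo-absence cells with their (z-standardized)
#' covariates. Standardization statistics are computed here, on these
#' training cells, and reused for all projections.
#'
#' @param presence_cells,absence_cells integer cell ids (must be disjoint).
#' @param covariates numeric matrix over all grid cells (rows = cell ids).
#' @param species optional species label.
#' @return an object of class `occurrence_data` with elements `cells`, `y`,
#'   `X` (standardized), `center`, `scale`, `range` (raw training min/max per
#'   covariate), `species`.
#' @export
make_occurrence <- function(presence_cells, absence_cells, covariates,
                            species = NULL) {
  if (length(intersect(presence_cells, absence_cells)))
    stop("presence and pseudo-absence cells overlap")
  cells <- c(presence_cells, absence_cells)
  y <- c(rep(1L, length(presence_cells)), rep(0L, length(absence_cells)))
  X <- as.matrix(covariates)[cells, , drop = FALSE]
  ok <- stats::complete.cases(X)
  if (!all(ok)) {
    cells <- cells[ok]; y <- y[ok]; X <- X[ok, , drop = FALSE]
  }
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("constant covariate(s): ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  rng <- apply(X, 2, range)
  structure(list(cells = cells, y = y,
                 X = scale(X, center = ctr, scale = scl),
                 center = ctr, scale = scl, range = rng, species = species),
            class = "occurrence_data")
}

# quadratic (and optionally pairwise-product) feature expansion of a
# standardized covariate matrix; used by the GLM and MaxEnt members
expand_features <- function(X, products = FALSE) {
  X <- as.matrix(X)
  out <- cbind(X, X^2)
  colnames(out) <- c(colnames(X), paste0(colnames(X), "_sq"))
  if (products && ncol(X) > 1) {
    cmb <- utils::combn(colnames(X), 2)
    prods <- apply(cmb, 2, function(p) X[, p[1]] * X[, p[2]])
    colnames(prods) <- apply(cmb, 2, paste, collapse = "_x_")
    out <- cbind(out, prods)
  }
  out
}

#' Fit one ensemble member
#'
#' * `glm`: binomial logistic regression with linear + quadratic terms.
#' * `rf`: probability random forest (class-1 vote fraction).
#' * `maxent`: L1-regularized logistic regression of presences against the
#'   pseudo-absence background with linear + quadratic + pairwise-product
#'   features, the standard MaxEnt-as-penalized-logistic formulation;
#'   regularization strength chosen by internal cross-validation.
#'
#' @param kind `"glm"`, `"rf"` or `"maxent"`.
#' @param occ an [make_occurrence()] data set (or a subset of one).
#' @param num_trees random-forest size.
#' @param seed RNG seed for the stochastic members.
#' @return an object of class `member_fit`; use [predict.member_fit()].
#' @export
fit_member <- function(kind = c("glm", "rf", "maxent"), occ,
                       num_trees = 300, seed = 1) {
  kind <- match.arg(kind)
  X <- occ$X; y <- occ$y
  fit <- switch(kind,
    glm = {
      df <- data.frame(y = y, expand_features(X))
      m <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial()))
      if (!m$converged) warning("GLM member did not converge")
      m
    },
    rf = ranger::ranger(
      y = factor(y, levels = c(0, 1)), x = as.data.frame(X),
      probability = TRUE, num.trees = num_trees, num.threads = 1,
      seed = as.integer(seed)),
    maxent = {
      Xf <- expand_features(X, products = TRUE)
      set.seed(as.integer(seed))
      cv <- glmnet::cv.glmnet(Xf, y, family = "binomial", alpha = 1,
                              nfolds = 5, nlambda = 30)
      cv
    })
  structure(list(kind = kind, fit = fit, vars = colnames(X)),
            class = "member_fit")
}

#' Predict member suitability scores
#'
#' @param object a [fit_member()] fit.
#' @param newdata standardized covariate matrix with the training columns.
#' @param ... unused.
#' @return scores in \[0, 1\].
#' @export
predict.member_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$vars, drop = FALSE]
  switch(object$kind,
    glm = as.numeric(stats::predict(object$fit,
      newdata = data.frame(expand_features(X)), type = "response")),
    rf = as.numeric(stats::predict(object$fit, data = as.data.frame(X),
      num.threads = 1)$predictions[, "1"]),
    maxent = as.numeric(stats::predict(object$fit,
      newx = expand_features(X, products = TRUE),
      s = "lambda.min", type = "response")))
}

# stratified train/test split indices (consumes the RNG stream)
stratified_split <- function(y, train_frac) {
  tr <- unlist(lapply(c(0, 1), function(cl) {
    i <- which(y == cl)
    sample(i, max(1, round(train_frac * length(i))))
  }))
  if (length(tr) >= length(y)) tr <- tr[-sample(length(tr), 2)]
  tr
}

#' Repeated stratified cross-validation of a member
#'
#' For each repeat: stratified 80/20 split, fit on the training part, optimize
#' the TSS threshold on the test part, score TSS on the test part.
#'
#' @param occ an [make_occurrence()] data set.
#' @param kind member kind (see [fit_member()]).
#' @param repeats number of repeats (default 5).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer RNG seed.
#' @param num_trees passed to [fit_member()].
#' @return list: `per_repeat` TSS vector, `mean_tss`, `thresholds`.
#' @export
cross_validate <- function(occ, kind, repeats = 5, train_frac = 0.8, seed = 1,
                           num_trees = 300) {
  stopifnot(inherits(occ, "occurrence_data"))
  set.seed(as.integer(seed))
  scores <- thr <- numeric(repeats)
  for (r in seq_len(repeats)) {
    tr <- stratified_split(occ$y, train_frac)
    te <- setdiff(seq_along(occ$y), tr)
    if (length(unique(occ$y[te])) < 2)
      stop("a class is absent from the test split")
    sub <- occ
    sub$X <- occ$X[tr, , drop = FALSE]; sub$y <- occ$y[tr]
    m <- fit_member(kind, sub, num_trees = num_trees,
                    seed = sample.int(.Machine$integer.max, 1))
    s <- predict(m, occ$X[te, , drop = FALSE])
    thr[r] <- optimize_threshold(occ$y[te], s)
    scores[r] <- tss(occ$y[te], s, thr[r])
  }
  list(per_repeat = scores, mean_tss = mean(scores), thresholds = thr)
}

#' TSS-weighted ensemble of member models
#'
#' Fits and cross-validates the requested members, keeps those with mean TSS
#' above the cutoff, and weights each by its mean TSS (weights normalized to
#' sum 1). The ensemble score of a cell is the weighted mean of member scores.
#'
#' @param occ an [make_occurrence()] data set.
#' @param kinds member kinds to include.
#' @param cutoff mean-TSS inclusion cutoff (default 0.7).
#' @param repeats,seed,num_trees cross-validation settings.
#' @param ensemble_cv also cross-validate the weighted ensemble score itself
#'   (default TRUE; disable to save the extra member refits when only member
#'   weights and projections are needed).
#' @return an object of class `sdm_ensemble`: members (fits on all data),
#'   `cv` per member, `weights`, `ensemble_tss` (same CV protocol applied to
#'   the weighted score), plus the standardization and training ranges from
#'   `occ`.
#' @export
build_ensemble <- function(occ, kinds = c("glm", "rf", "maxent"), cutoff = 0.7,
                           repeats = 5, seed = 1, num_trees = 300,
                           ensemble_cv = TRUE) {
  stopifnot(inherits(occ, "occurrence_data"))
  cv <- lapply(seq_along(kinds), function(i)
    cross_validate(occ, kinds[i], repeats = repeats, seed = seed + i,
                   num_trees = num_trees))
  names(cv) <- kinds
  mean_tss <- vapply(cv, `[[`, numeric(1), "mean_tss")
  included <- names(mean_tss)[mean_tss > cutoff]
  if (!length(included)) {
    best <- names(which.max(mean_tss))
    stop(sprintf("no member exceeds the TSS cutoff %.2f; best is %s at %.3f",
                 cutoff, best, mean_tss[best]))
  }
  w <- mean_tss[included] / sum(mean_tss[included])
  fits <- lapply(seq_along(included), function(i)
    fit_member(included[i], occ, num_trees = num_trees, seed = seed + 100 + i))
  names(fits) <- included
  ens <- structure(
    list(members = fits, cv = cv, weights = w, member_tss = mean_tss,
         cutoff = cutoff, center = occ$center, scale = occ$scale,
         range = occ$range, vars = colnames(occ$X), species = occ$species),
    class = "sdm_ensemble")
  ens$ensemble_tss <- if (ensemble_cv)
    ensemble_cv_tss(ens, occ, repeats = repeats, seed = seed,
                    num_trees = num_trees) else NA_real_
  ens
}

# cross-validated TSS of the weighted ensemble score (same 80/20 x repeats
# protocol as the members, refitting every member per repeat)
ensemble_cv_tss <- function(ens, occ, repeats = 5, seed = 1, num_trees = 300) {
  set.seed(as.integer(seed))
  out <- numeric(repeats)
  for (r in seq_len(repeats)) {
    tr <- stratified_split(occ$y, 0.8)
    te <- setdiff(seq_along(occ$y), tr)
    sub <- occ
    sub$X <- occ$X[tr, , drop = FALSE]; sub$y <- occ$y[tr]
    s <- rowSums(sapply(names(ens$members), function(k) {
      m <- fit_member(k, sub, num_trees = num_trees,
                      seed = sample.int(.Machine$integer.max, 1))
      ens$weights[[k]] * predict(m, occ$X[te, , drop = FALSE])
    }))
    out[r] <- tss(occ$y[te], s, optimize_threshold(occ$y[te], s))
  }
  mean(out)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat("sdm_ensemble", if (!is.null(x$species)) paste0("(", x$species, ")"), "\n")
  for (k in names(x$member_tss))
    cat(sprintf("  %-7s mean TSS %.3f %s\n", k, x$member_tss[k],
                if (k %in% names(x$weights))
                  sprintf("(weight %.3f)", x$weights[k]) else "(excluded)"))
  cat(sprintf("  ensemble CV TSS %.3f\n", x$ensemble_tss))
  invisible(x)
}

#' Ensemble suitability scores
#'
#' @param object an [build_ensemble()] ensemble.
#' @param newdata covariate matrix on the raw scale (training columns); it is
#'   standardized internally with the training statistics.
#' @param standardized set `TRUE` if `newdata` is already standardized.
#' @param ... unused.
#' @return scores in \[0, 1\].
#' @export
predict.sdm_ensemble <- function(object, newdata, standardized = FALSE, ...) {
  X <- as.matrix(newdata)[, object$vars, drop = FALSE]
  if (!standardized)
    X <- scale(X, center = object$center, scale = object$scale)
  s <- sapply(names(object$members), function(k)
    object$weights[[k]] * predict(object$members[[k]], X))
  if (is.null(dim(s))) sum(s) else rowSums(s)
}

#' Project an ensemble onto an environmental period
#'
#' Predicts habitat suitability (HSV) for every ocean cell of a period,
#' standardizing with the training statistics, and reports cells where any
#' covariate falls outside its training range (clamping: extrapolation beyond
#' the fitted niche, where projections are unreliable).
#'
#' @param ensemble an [build_ensemble()] ensemble.
#' @param env an [gen_environment()] scenario (or any object accepted by
#'   [env_covariates()]).
#' @param period period name.
#' @return list: `hsv` (a [surface()]), `clamping` (data.frame of flagged
#'   cells and offending covariates).
#' @export
project_suitability <- function(ensemble, env, period = "present") {
  X <- env_covariates(env, period, vars = ensemble$vars)
  g <- env$grid
  mask <- g$mask
  scores <- predict(ensemble, X[mask, , drop = FALSE])
  vals <- numeric(g$ncell)
  vals[mask] <- scores
  rng <- ensemble$range
  flags <- lapply(ensemble$vars, function(v) {
    bad <- mask & (X[, v] < rng[1, v] | X[, v] > rng[2, v])
    if (any(bad)) data.frame(cell = which(bad), covariate = v) else NULL
  })
  clamping <- do.call(rbind, flags)
  if (is.null(clamping))
    clamping <- data.frame(cell = integer(), covariate = character())
  list(hsv = surface(g, vals, period = period, species = ensemble$species,
                     units = "HSV"),
       clamping = clamping)
}

#' Permutation variable importance (mean decrease in TSS)
#'
#' Importance of a covariate is the mean decrease in ensemble TSS (on the
#' occurrence data, at the ensemble's optimized threshold) when that
#' covariate's values are permuted across rows, averaged over `n_shuffles`
#' permutations. Rank 1 is the most important variable; ties break by larger
#' raw decrease, then name.
#'
#' @param ensemble an [build_ensemble()] ensemble.
#' @param occ the [make_occurrence()] data it was built from.
#' @param n_shuffles permutations per covariate (default 10).
#' @param seed integer RNG seed.
#' @return data.frame: variable, importance (TSS decrease), rank.
#' @export
variable_importance <- function(ensemble, occ, n_shuffles = 10, seed = 1) {
  stopifnot(inherits(ensemble, "sdm_ensemble"), inherits(occ, "occurrence_data"))
  set.seed(as.integer(seed))
  base_scores <- predict(ensemble, occ$X, standardized = TRUE)
  thr <- optimize_threshold(occ$y, base_scores)
  base_tss <- tss(occ$y, base_scores, thr)
  n <- nrow(occ$X)
  imp <- vapply(ensemble$vars, function(v) {
    drops <- vapply(seq_len(n_shuffles), function(s) {
      Xp <- occ$X
      Xp[, v] <- Xp[sample.int(n), v]
      base_tss - tss(occ$y, predict(ensemble, Xp, standardized = TRUE), thr)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  ord <- order(-imp, ensemble$vars)
  out <- data.frame(variable = ensemble$vars[ord], importance = imp[ord])
  out$rank <- seq_len(nrow(out))
  out
}

#' Evaluate projected suitability against acoustic detections
#'
#' Mean habitat suitability at detection vs non-detection records, plus a
#' per-receiver table of detection counts and local HSV (the style of
#' comparison used for receivers reporting detection counts only).
#'
#' @param hsv a suitability [surface()].
#' @param detections data.frame with lon, lat, detection (0/1), optional
#'   receiver.
#' @return list: `mean_hsv_detection`, `mean_hsv_non_detection`, `receivers`
#'   (per-receiver table).
#' @export
evaluate_against_detections <- function(hsv, detections) {
  stopifnot(inherits(hsv, "surface"))
  cells <- cell_index(hsv$grid, detections$lon, detections$lat)
  if (any(is.na(cells))) stop("detection record outside the grid extent")
  h <- hsv$values[cells]
  det <- as.integer(detections$detection)
  rec <- if (!is.null(detections$receiver)) detections$receiver else cells
  tab <- do.call(rbind, lapply(split(seq_along(det), rec), function(i)
    data.frame(receiver = rec[i[1]], n = length(i), n_detections = sum(det[i]),
               hsv = mean(h[i]))))
  rownames(tab) <- NULL
  list(mean_hsv_detection = if (any(det == 1)) mean(h[det == 1]) else NA_real_,
       mean_hsv_non_detection = if (any(det == 0)) mean(h[det == 0]) else NA_real_,
       receivers = tab)
}
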