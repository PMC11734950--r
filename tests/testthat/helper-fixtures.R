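# Shared fixtures: small grids, environments and synthetic-truth data sets
# built in code at test time.

tiny_grid <- function(n = 4, res = 1) {
  build_grid(0, n * res, 0, n * res, res)
}

# covariate-field truth: named covariates as smooth random fields over an
# all-ocean grid, logistic suitability from `beta` (named, with intercept),
# per-cell occupancy labels y ~ Bernoulli(suitability), and presence cells
# sampled among the occupied ones (capped at their number)
covariate_truth <- function(nside, beta, b0 = 0, n_presence, seed = 1) {
  g <- build_grid(0, nside, 0, nside, 1)
  set.seed(seed)
  X <- sapply(names(beta), function(v)
    whalerisk:::gaussian_field(g, max(3, nside / 20)))
  colnames(X) <- names(beta)
  suit <- stats::plogis(b0 + as.numeric(scale(X) %*% beta))
  y <- stats::rbinom(g$ncell, 1, suit)
  occupied <- which(y == 1)
  pres <- sample(occupied, min(n_presence, length(occupied)))
  list(grid = g, X = X, suitability = suit, y = y, presence = pres,
       absence_pool = which(y == 0), beta = beta)
}

# quick environmental scenario shared across tests (generation is cheap but
# not free; memoise per session)
quick_env <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- gen_environment(build_grid(-70, -50, 40, 60, 0.5), seed = 11)
    cache
  }
})
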