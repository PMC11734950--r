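#' Synthetic study-system generators
#'
#' Everything the real study obtained externally (climate-model environmental
#' fields, bathymetry, opportunistic sightings, AIS vessel hours, incident
#' reports, acoustic detections) can be generated here with known ground
#' truth, so every downstream stage is testable offline. All generators are
#' pure functions of their parameters and seed.
#'
#' @name synthetic
NULL

# Gaussian random field on the grid via FFT-smoothed white noise.
# Periodic (torus) boundary; standardized to mean 0, sd 1 over all cells.
# `range_cells` is the Gaussian kernel sd in cell units and controls the
# spatial autocorrelation length. Consumes the current RNG stream.
gaussian_field <- function(grid, range_cells) {
  nr <- grid$nrow; nc <- grid$ncol
  if (range_cells <= 0) stop("correlation range must be positive")
  if (range_cells > min(nr, nc))
    stop("correlation range larger than the domain")
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells < .Machine$double.eps) return(as.vector(t(z)))
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * range_cells^2))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  # matrix is row = latitude row (south first); flatten row-major to cell ids
  as.vector(t(sm))
}

#' Default environment-generator parameters
#'
#' Defaults emulate a Northwest-Atlantic-like domain: a south-to-north SST
#' gradient over a shelf sloping away from a western coastline, with future
#' periods warmed and freshened relative to the present (the near- and
#' mid-future deltas approximate a doubling-CO2 trajectory: +1 and +2 deg C
#' SST, -0.2 and -0.4 ppt SSS, -5 and -10 g C m-2 yr-1 NPP).
#'
#' @param corr_range spatial correlation length of the random fields, in cells.
#' @param sst_south mean SST at the southern edge (deg C).
#' @param sst_gradient SST decrease per degree (or km-grid row) of latitude.
#' @param sst_amp,sss_amp,npp_amp field standard deviations (deg C, ppt, g C m-2 yr-1).
#' @param sss_mean,npp_mean field means.
#' @param delta named list of per-period additive deltas for SST/SSS/NPP.
#' @param noise_sd sd of the small-scale noise added to future fields (same
#'   units as each field; set 0 for exact present + delta).
#' @param land_fraction approximate fraction of cells turned into land along
#'   the western edge.
#' @return list of parameters for [gen_environment()].
#' @export
env_params <- function(corr_range = 4, sst_south = 18, sst_gradient = 0.6,
                       sst_amp = 1.5, sss_mean = 33, sss_amp = 1.2,
                       npp_mean = 150, npp_amp = 35,
                       delta = list(
                         near_future = c(SST = 1, SSS = -0.2, NPP = -5),
                         mid_future  = c(SST = 2, SSS = -0.4, NPP = -10)),
                       noise_sd = 0.1, land_fraction = 0.1) {
  list(corr_range = corr_range, sst_south = sst_south,
       sst_gradient = sst_gradient, sst_amp = sst_amp,
       sss_mean = sss_mean, sss_amp = sss_amp,
       npp_mean = npp_mean, npp_amp = npp_amp,
       delta = delta, noise_sd = noise_sd, land_fraction = land_fraction)
}

#' Generate a synthetic environmental scenario
#'
#' Produces smooth, spatially autocorrelated SST, SSS and NPP layers for three
#' periods (present, near_future, mid_future), plus static depth (m, negative
#' below sea level), slope and shelf layers, and a coastal land mask along the
#' western edge. Future layers are present + configured delta + small-scale
#' noise. Identical seeds give identical scenarios.
#'
#' @param grid a [build_grid()] grid (its mask is replaced by the generated
#'   ocean mask).
#' @param params see [env_params()].
#' @param seed integer RNG seed.
#' @return an object of class `env_scenario`: list with `grid` (ocean-masked),
#'   `static` (depth, slope, shelf), `periods` (per-period SST/SSS/NPP),
#'   `params`, `seed`.
#' @export
gen_environment <- function(grid, params = env_params(), seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  set.seed(as.integer(seed))
  p <- params
  nr <- grid$nrow; nc <- grid$ncol
  cen <- cell_centroids(grid)
  # fractional position across the extent
  fx <- (cen$lon - grid$lon_min) / (grid$lon_max - grid$lon_min)
  fy <- (cen$lat - grid$lat_min) / (grid$lat_max - grid$lat_min)

  # bathymetry: deepens away from the western coast, plus relief
  relief <- gaussian_field(grid, p$corr_range)
  depth <- -4200 * pmax(fx - p$land_fraction, 0)^0.7 + 400 * relief
  depth <- pmin(depth, 0 - 1e-6)
  land <- fx < p$land_fraction * (0.7 + 0.6 * stats::plogis(3 * relief))
  depth[land] <- abs(50 + 100 * relief[land])
  mask <- !land
  if (!any(mask)) stop("generated mask has no ocean cells")

  # slope: central-difference gradient magnitude of depth on the grid
  m <- matrix(depth, nr, nc, byrow = TRUE)
  gx <- (m[, pmin(seq_len(nc) + 1, nc)] - m[, pmax(seq_len(nc) - 1, 1)]) / 2
  gy <- (m[pmin(seq_len(nr) + 1, nr), ] - m[pmax(seq_len(nr) - 1, 1), ]) / 2
  slope <- as.vector(t(sqrt(gx^2 + gy^2)))
  shelf <- as.numeric(depth > -200 & mask)

  lat_span <- (grid$lat_max - grid$lat_min)
  sst0 <- p$sst_south - p$sst_gradient * lat_span * fy +
    p$sst_amp * gaussian_field(grid, p$corr_range)
  sss0 <- p$sss_mean + p$sss_amp * gaussian_field(grid, p$corr_range) +
    0.8 * p$sss_amp * fx  # fresher near the coast/estuaries
  npp0 <- p$npp_mean + p$npp_amp * gaussian_field(grid, p$corr_range) -
    0.5 * p$npp_amp * fx  # more productive over the shelf
  periods <- list(present = list(SST = sst0, SSS = sss0, NPP = npp0))
  for (per in names(p$delta)) {
    d <- p$delta[[per]]
    noise <- function() if (p$noise_sd > 0)
      p$noise_sd * gaussian_field(grid, max(p$corr_range / 2, 1)) else 0
    periods[[per]] <- list(SST = sst0 + d[["SST"]] + noise(),
                           SSS = sss0 + d[["SSS"]] + noise(),
                           NPP = npp0 + d[["NPP"]] + noise())
  }
  g <- grid; g$mask <- mask
  structure(list(grid = g,
                 static = list(depth = depth, slope = slope, shelf = shelf),
                 periods = periods, params = p, seed = seed),
            class = "env_scenario")
}

#' @export
print.env_scenario <- function(x, ...) {
  cat(sprintf("env_scenario: %d x %d grid, %d ocean cells, periods: %s\n",
              x$grid$nrow, x$grid$ncol, sum(x$grid$mask),
              paste(names(x$periods), collapse = ", ")))
  invisible(x)
}

#' Covariate matrix of an environmental scenario
#'
#' Assembles the per-cell covariate matrix (SST, SSS, NPP, depth, slope,
#' shelf) for one period, over all cells (rows in cell-id order).
#'
#' @param env an [gen_environment()] scenario.
#' @param period one of the scenario's period names.
#' @param vars covariates to include.
#' @return numeric matrix, `ncell` rows.
#' @export
env_covariates <- function(env, period = "present",
                           vars = c("SST", "SSS", "NPP", "depth", "slope", "shelf")) {
  stopifnot(inherits(env, "env_scenario"))
  if (!period %in% names(env$periods))
    stop("unknown period: ", period)
  pool <- c(env$periods[[period]], env$static)
  miss <- setdiff(vars, names(pool))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  m <- sapply(vars, function(v) as.numeric(pool[[v]]))
  colnames(m) <- vars
  m
}

#' Default ground-truth parameters
#'
#' Per-species logistic suitability coefficients on standardized covariates,
#' observation-effort decay, vessel hotspot geometry, and the incident-count
#' link. Coefficient signs follow the system being emulated: most species
#' prefer fresher, cooler, more productive shelf waters.
#'
#' @param species_coef named list (per species) of named coefficient vectors;
#'   `(Intercept)` plus any of SST, SSS, NPP, depth, slope, shelf.
#' @param effort_lambda e-folding distance (in cells) of the coastal
#'   observation-effort decay exp(-d/lambda).
#' @param hotspots data.frame of vessel hotspots: lon, lat, intensity (hours),
#'   sd (spread, extent units).
#' @param vessel_noise_sdlog lognormal sdlog of multiplicative vessel noise.
#' @param vessel_total target total vessel hours (NULL = no normalization).
#' @param incident named list: beta0, beta1 (vessel hours), beta2 (HSV),
#'   theta (NB dispersion), pi (zero-inflation probability), and a_risk/b_risk
#'   for the risk-form variant log mu = a + b * E.
#' @return list of class `truth_params`.
#' @export
truth_params <- function(
    species_coef = list(
      blue     = c("(Intercept)" = -5.0, SST = -3.6, SSS = -4.5, NPP = 2.4, depth = -1.8),
      fin      = c("(Intercept)" = -4.4, SST = -3.0, SSS = -3.6, NPP = 3.0, depth = -1.2),
      humpback = c("(Intercept)" = -3.5, SST = -4.2, SSS =  1.8, NPP = 2.7, shelf = 2.4),
      minke    = c("(Intercept)" = -4.4, SST = -3.3, SSS = -3.0, NPP = 2.1, shelf = 2.7),
      na_right = c("(Intercept)" = -5.6, SST = -4.8, SSS = -3.9, NPP = 3.3, shelf = 2.1),
      sei      = c("(Intercept)" = -6.2, SST = -2.7, SSS = -4.2, NPP = 2.7, depth = -0.9)),
    effort_lambda = 25,
    hotspots = NULL,
    vessel_noise_sdlog = 0.5,
    vessel_total = NULL,
    incident = list(beta0 = -1.0, beta1 = 0.3, beta2 = 2.0,
                    theta = 1.5, pi = 0.2, a_risk = -1.0, b_risk = 400)) {
  structure(list(species_coef = species_coef, effort_lambda = effort_lambda,
                 hotspots = hotspots, vessel_noise_sdlog = vessel_noise_sdlog,
                 vessel_total = vessel_total, incident = incident),
            class = "truth_params")
}

#' True habitat suitability from known coefficients
#'
#' logistic(beta . z(covariates)) per cell; covariates are z-standardized
#' internally over ocean cells, so suitability is invariant to affine
#' rescaling of any covariate.
#'
#' @param env an [gen_environment()] scenario.
#' @param params a [truth_params()] object.
#' @param species one of the six species names.
#' @param period scenario period.
#' @return a [surface()] with values in \[0, 1\].
#' @export
true_suitability <- function(env, params = truth_params(), species, period = "present") {
  stopifnot(inherits(env, "env_scenario"))
  coefs <- params$species_coef[[species]]
  if (is.null(coefs)) stop("no suitability coefficients for species: ", species)
  vars <- setdiff(names(coefs), "(Intercept)")
  X <- env_covariates(env, period, vars)
  mask <- env$grid$mask
  Z <- scale(X[mask, , drop = FALSE])
  eta <- as.numeric(Z %*% coefs[vars]) +
    if ("(Intercept)" %in% names(coefs)) coefs[["(Intercept)"]] else 0
  vals <- numeric(env$grid$ncell)
  vals[mask] <- stats::plogis(eta)
  surface(env$grid, vals, period = period, species = species, units = "suitability")
}

#' Coastal observation-effort surface
#'
#' Effort decays exponentially with distance to the nearest land cell,
#' `exp(-d / lambda)` with `d` in cell units, emulating the coastal bias of
#' opportunistic sightings. With no land cells, decay is from the western
#' boundary.
#'
#' @param env an [gen_environment()] scenario.
#' @param lambda e-folding distance in cells.
#' @return a [surface()] of relative effort (max 1).
#' @export
effort_surface <- function(env, lambda = truth_params()$effort_lambda) {
  g <- env$grid
  cen <- cell_centroids(g)
  land <- which(!g$mask)
  d <- if (length(land)) {
    lr <- (land - 1L) %/% g$ncol + 1L
    lc <- (land - 1L) %% g$ncol + 1L
    r <- (cen$cell - 1L) %/% g$ncol + 1L
    c <- (cen$cell - 1L) %% g$ncol + 1L
    sapply(seq_len(g$ncell), function(i)
      sqrt(min((r[i] - lr)^2 + (c[i] - lc)^2)))
  } else {
    (cen$lon - g$lon_min) / g$resolution
  }
  vals <- exp(-d / lambda)
  vals[!g$mask] <- 0
  surface(g, ifelse(g$mask, vals, 0), units = "effort")
}

#' Sample effort-biased sighting points
#'
#' Cells are drawn (with replacement) with probability proportional to
#' suitability x effort over ocean cells; each draw is jittered uniformly
#' within its cell.
#'
#' @param suitability a [surface()] (e.g. [true_suitability()]).
#' @param effort a [surface()] on the same grid (e.g. [effort_surface()]).
#' @param n number of sightings.
#' @param seed integer RNG seed.
#' @param species species label attached to the records.
#' @return data.frame of point records (lon, lat, species, date, cell).
#' @export
sample_sightings <- function(suitability, effort, n, seed = 1, species = "humpback") {
  stopifnot(inherits(suitability, "surface"), inherits(effort, "surface"), n > 0)
  g <- suitability$grid
  w <- suitability$values * effort$values
  w[!g$mask | is.na(w)] <- 0
  if (sum(w) <= 0) stop("all sampling weights are zero")
  set.seed(as.integer(seed))
  cells <- sample.int(g$ncell, n, replace = TRUE, prob = w)
  cen <- cell_centroids(g, cells)
  res <- g$resolution
  data.frame(
    lon = cen$lon + stats::runif(n, -res / 2, res / 2),
    lat = cen$lat + stats::runif(n, -res / 2, res / 2),
    species = species,
    date = sprintf("2015-%02d-%02d", sample(4:10, n, replace = TRUE),
                   sample(1:28, n, replace = TRUE)),
    cell = cells)
}

#' Generate a heavy-tailed vessel-activity surface
#'
#' Sum of Gaussian-kernel hotspots multiplied by lognormal noise (meanlog
#' -sdlog^2/2 so the noise has mean 1); zero on land. When
#' `params$vessel_total` is set the surface is rescaled to that total exactly.
#'
#' @param grid a [build_grid()] grid (typically `env$grid`).
#' @param params a [truth_params()]; if its `hotspots` is NULL, three default
#'   hotspots are placed along the coastal third of the domain.
#' @param seed integer RNG seed.
#' @return a [surface()] of vessel hours with attribute `"hotspots"`.
#' @export
gen_vessel_activity <- function(grid, params = truth_params(), seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  hs <- params$hotspots
  if (is.null(hs)) {
    lon_w <- grid$lon_max - grid$lon_min
    lat_w <- grid$lat_max - grid$lat_min
    hs <- data.frame(
      lon = grid$lon_min + c(0.20, 0.30, 0.45) * lon_w,
      lat = grid$lat_min + c(0.30, 0.65, 0.45) * lat_w,
      intensity = c(4000, 2500, 1500),
      sd = c(0.06, 0.08, 0.12) * lon_w)
  }
  if (nrow(hs) < 1) stop("at least one hotspot is required")
  if (any(hs$intensity < 0)) stop("hotspot intensity must be non-negative")
  set.seed(as.integer(seed))
  cen <- cell_centroids(grid)
  vals <- numeric(grid$ncell)
  for (i in seq_len(nrow(hs))) {
    d2 <- (cen$lon - hs$lon[i])^2 + (cen$lat - hs$lat[i])^2
    vals <- vals + hs$intensity[i] * exp(-d2 / (2 * hs$sd[i]^2))
  }
  sdl <- params$vessel_noise_sdlog
  if (sdl > 0)
    vals <- vals * stats::rlnorm(grid$ncell, meanlog = -sdl^2 / 2, sdlog = sdl)
  vals[!grid$mask] <- 0
  if (!is.null(params$vessel_total))
    vals <- vals * params$vessel_total / sum(vals)
  out <- surface(grid, ifelse(grid$mask, vals, 0), units = "hours")
  attr(out, "hotspots") <- hs
  out
}

#' Generate zero-inflated negative-binomial incident counts
#'
#' Per-cell counts from a zero-inflated NB whose log-mean is either the
#' covariate form `beta0 + beta1 * V + beta2 * HSV` or the risk form
#' `a_risk + b_risk * E`, matching the two regression stages downstream.
#' The realized truth is attached as the `"truth"` attribute.
#'
#' @param params a [truth_params()] (`incident` component).
#' @param seed integer RNG seed.
#' @param V,HSV surfaces for the covariate form.
#' @param E surface for the risk form (used when V/HSV are missing).
#' @return a [surface()] of integer counts.
#' @export
gen_incidents <- function(params = truth_params(), seed = 1,
                          V = NULL, HSV = NULL, E = NULL) {
  ip <- params$incident
  if (ip$theta <= 0) stop("NB dispersion theta must be positive")
  if (ip$pi < 0 || ip$pi > 1) stop("zero-inflation probability must be in [0, 1]")
  if (!is.null(V) && !is.null(HSV)) {
    g <- V$grid
    if (any(V$values < 0, na.rm = TRUE)) stop("vessel surface must be non-negative")
    mu <- exp(ip$beta0 + ip$beta1 * V$values + ip$beta2 * HSV$values)
    truth <- c(beta0 = ip$beta0, beta1 = ip$beta1, beta2 = ip$beta2,
               theta = ip$theta, pi = ip$pi)
  } else if (!is.null(E)) {
    g <- E$grid
    if (any(E$values < 0, na.rm = TRUE)) stop("risk surface must be non-negative")
    mu <- exp(ip$a_risk + ip$b_risk * E$values)
    truth <- c(a = ip$a_risk, b = ip$b_risk, theta = ip$theta, pi = ip$pi)
  } else stop("provide either V and HSV, or E")
  set.seed(as.integer(seed))
  n <- g$ncell
  mu[!g$mask | !is.finite(mu)] <- 0
  counts <- ifelse(mu > 0,
                   stats::rnbinom(n, size = ip$theta, mu = pmax(mu, 1e-12)), 0)
  zeroed <- stats::rbinom(n, 1, ip$pi) == 1
  counts[zeroed] <- 0
  out <- surface(g, ifelse(g$mask, as.numeric(counts), 0), units = "incidents")
  attr(out, "truth") <- truth
  out
}

#' Generate acoustic detection/non-detection records
#'
#' Per receiver, Bernoulli detections with success probability equal to the
#' suitability of the receiver's cell.
#'
#' @param suitability a [surface()] in \[0, 1\].
#' @param receivers data.frame with lon, lat (and optional receiver id).
#' @param n_per_receiver records per receiver.
#' @param seed integer RNG seed.
#' @return data.frame: receiver, lon, lat, detection (0/1).
#' @export
gen_acoustic_detections <- function(suitability, receivers, n_per_receiver = 40,
                                    seed = 1) {
  stopifnot(inherits(suitability, "surface"))
  g <- suitability$grid
  cells <- cell_index(g, receivers$lon, receivers$lat)
  if (any(is.na(cells))) stop("receiver outside the grid extent")
  if (any(!g$mask[cells])) stop("receiver on a masked (land) cell")
  p <- suitability$values[cells]
  set.seed(as.integer(seed))
  idx <- rep(seq_len(nrow(receivers)), each = n_per_receiver)
  data.frame(
    receiver = if (!is.null(receivers$receiver)) receivers$receiver[idx] else idx,
    lon = receivers$lon[idx], lat = receivers$lat[idx],
    detection = stats::rbinom(length(idx), 1, p[idx]))
}
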