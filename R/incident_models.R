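#' Incident-count regression models and diagnostics
#'
#' Links per-cell incident-report counts to vessel activity, habitat
#' suitability and relative encounter risk: a zero-inflated negative-binomial
#' GLM (the count data are over-dispersed with excess zeros), a plain NB
#' alternative, a Poisson regression of counts on risk restricted to cells
#' with at least one incident, Moran's I residual diagnostics, and a Welch
#' t-test for seasonal contrasts in vessel hours.
#'
#' @name incident_models
NULL

# shared checks + data assembly for the count regressions
incident_frame <- function(NI, covars) {
  g <- NI$grid
  df <- data.frame(NI = NI$values)
  for (nm in names(covars)) df[[nm]] <- covars[[nm]]$values
  df <- df[g$mask & stats::complete.cases(df), , drop = FALSE]
  if (any(df$NI < 0) || any(df$NI != round(df$NI)))
    stop("incident counts must be non-negative integers")
  for (nm in names(covars))
    if (stats::sd(df[[nm]]) == 0)
      stop(sprintf("covariate '%s' is constant and cannot be estimated", nm))
  df
}

#' Incident counts vs vessel activity and habitat suitability
#'
#' Fits `NI ~ V + HSV` with a log link on the count mean and a negative
#' binomial response; by default a zero-inflated fit with an intercept-only
#' logistic zero component (structural zeros without covariates), with a
#' plain NB fit available for comparison. Coefficients are reported on the
#' original covariate scale with Wald standard errors and p-values.
#'
#' @param NI incident-count [surface()] (1-degree).
#' @param V vessel-hours [surface()] aligned with `NI`.
#' @param HSV habitat-suitability [surface()] aligned with `NI`.
#' @param zero_inflated fit the zero-inflated model (default) or plain NB.
#' @param drop_outliers optionally drop cells with |Pearson residual| > 4 on
#'   a first pass and refit (off by default; logged via a message).
#' @return an object of class `regression_result`: `family`, `coefficients`
#'   (Estimate/Std.Error/p), `theta`, `zero_prob`, `loglik`, `n`, `converged`.
#' @export
fit_zinb <- function(NI, V, HSV, zero_inflated = TRUE, drop_outliers = FALSE) {
  stopifnot(inherits(NI, "surface"), inherits(V, "surface"),
            inherits(HSV, "surface"))
  df <- incident_frame(NI, list(V = V, HSV = HSV))
  if (all(df$NI == 0)) stop("all-zero incident response")
  fit_once <- function(d) {
    if (zero_inflated) {
      m <- glmmTMB::glmmTMB(NI ~ V + HSV, ziformula = ~1,
                            family = glmmTMB::nbinom2(), data = d)
      s <- summary(m)$coefficients$cond
      list(model = m,
           coefficients = data.frame(Estimate = s[, 1], Std.Error = s[, 2],
                                     p = s[, 4], row.names = rownames(s)),
           theta = glmmTMB::sigma(m),
           zero_prob = stats::plogis(glmmTMB::fixef(m)$zi[[1]]),
           loglik = as.numeric(stats::logLik(m)),
           converged = isTRUE(m$sdr$pdHess),
           fitted = stats::fitted(m))
    } else {
      m <- MASS::glm.nb(NI ~ V + HSV, data = d)
      s <- summary(m)$coefficients
      list(model = m,
           coefficients = data.frame(Estimate = s[, 1], Std.Error = s[, 2],
                                     p = s[, 4], row.names = rownames(s)),
           theta = m$theta, zero_prob = NA_real_,
           loglik = as.numeric(stats::logLik(m)),
           converged = m$converged,
           fitted = stats::fitted(m))
    }
  }
  f <- fit_once(df)
  if (drop_outliers) {
    pear <- (df$NI - f$fitted) /
      sqrt(f$fitted * (1 + f$fitted / max(f$theta, 1e-8)))
    keep <- abs(pear) <= 4
    if (any(!keep)) {
      message(sprintf("dropping %d outlier cell(s) with |Pearson residual| > 4",
                      sum(!keep)))
      df <- df[keep, , drop = FALSE]
      f <- fit_once(df)
    }
  }
  structure(list(family = if (zero_inflated) "zinb" else "nb",
                 coefficients = f$coefficients, theta = f$theta,
                 zero_prob = f$zero_prob, loglik = f$loglik,
                 n = nrow(df), converged = f$converged,
                 model = f$model, data = df),
            class = "regression_result")
}

#' Incident counts vs relative risk on occupied cells
#'
#' Poisson log-link regression `NI ~ E`, restricted to cells with at least
#' one incident (zero cells are unidentifiable against absent observer
#' effort). Explained variance is the deviance pseudo-R-squared
#' `1 - D_model / D_null`.
#'
#' @param NI incident-count [surface()].
#' @param E_norm normalized-risk [surface()] aligned with `NI`.
#' @param min_cells minimum number of occupied cells (default 10).
#' @return a `regression_result` with elements `coefficients`, `r_squared`,
#'   `n`, `converged`.
#' @export
fit_poisson_risk <- function(NI, E_norm, min_cells = 10) {
  stopifnot(inherits(NI, "surface"), inherits(E_norm, "surface"))
  df <- data.frame(NI = NI$values, E = E_norm$values)
  df <- df[NI$grid$mask & stats::complete.cases(df) & df$NI >= 1, , drop = FALSE]
  if (nrow(df) < min_cells)
    stop(sprintf("only %d cells with incidents; need at least %d",
                 nrow(df), min_cells))
  if (stats::sd(df$E) == 0)
    stop("risk covariate is constant across occupied cells")
  m <- stats::glm(NI ~ E, family = stats::poisson(), data = df)
  s <- summary(m)$coefficients
  structure(list(family = "poisson",
                 coefficients = data.frame(Estimate = s[, 1],
                                           Std.Error = s[, 2], p = s[, 4],
                                           row.names = rownames(s)),
                 r_squared = 1 - m$deviance / m$null.deviance,
                 loglik = as.numeric(stats::logLik(m)),
                 n = nrow(df), converged = m$converged, model = m),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s regression (n = %d cells%s)\n", toupper(x$family), x$n,
              if (!x$converged) ", NOT CONVERGED" else ""))
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  if (!is.null(x$theta)) cat(sprintf("theta = %.3f\n", x$theta))
  if (!is.null(x$zero_prob) && !is.na(x$zero_prob))
    cat(sprintf("zero-inflation probability = %.3f\n", x$zero_prob))
  if (!is.null(x$r_squared))
    cat(sprintf("deviance pseudo-R2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Moran's I for gridded residuals
#'
#' Moran's I with row-standardized queen-contiguity weights (all eight
#' neighbours) over masked-in cells with finite residuals, with a permutation
#' p-value: residuals are reshuffled across cells and the two-sided tail
#' probability of the observed |I - E(I)| is reported.
#'
#' @param residuals a [surface()] of residuals (or a numeric vector over all
#'   grid cells with `grid` supplied).
#' @param grid the grid, when `residuals` is a bare vector.
#' @param nperm number of permutations (default 999).
#' @param seed integer RNG seed.
#' @return list: `I`, `expected` (-1/(n-1)), `p`, `n`, `nperm`.
#' @export
morans_i <- function(residuals, grid = NULL, nperm = 999, seed = 1) {
  if (inherits(residuals, "surface")) {
    grid <- residuals$grid
    z <- residuals$values
  } else z <- residuals
  stopifnot(inherits(grid, "grid_spec"), length(z) == grid$ncell)
  use <- which(grid$mask & is.finite(z))
  n <- length(use)
  if (n < 9) stop("need at least 9 cells with residuals")
  # queen-contiguity neighbour list among used cells
  row <- (use - 1L) %/% grid$ncol + 1L
  col <- (use - 1L) %% grid$ncol + 1L
  id <- rep(NA_integer_, grid$ncell)
  id[use] <- seq_len(n)
  nb <- vector("list", n)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  for (k in seq_len(nrow(off))) {
    r2 <- row + off$dr[k]; c2 <- col + off$dc[k]
    ok <- r2 >= 1 & r2 <= grid$nrow & c2 >= 1 & c2 <= grid$ncol
    tgt <- rep(NA_integer_, n)
    tgt[ok] <- id[(r2[ok] - 1L) * grid$ncol + c2[ok]]
    for (i in which(!is.na(tgt))) nb[[i]] <- c(nb[[i]], tgt[i])
  }
  deg <- lengths(nb)
  if (any(deg == 0)) stop("some cells have no contiguity neighbours")
  x <- z[use]
  ii <- rep(seq_len(n), deg)
  jj <- unlist(nb)
  w <- 1 / deg[ii]  # row-standardized
  moran_stat <- function(v) {
    vc <- v - mean(v)
    # row-standardized weights: S0 = n, so I = sum(w_ij vc_i vc_j) / sum(vc^2)
    sum(w * vc[ii] * vc[jj]) / sum(vc^2)
  }
  I_obs <- moran_stat(x)
  E_I <- -1 / (n - 1)
  set.seed(as.integer(seed))
  I_perm <- vapply(seq_len(nperm), function(p) moran_stat(sample(x)),
                   numeric(1))
  p <- (1 + sum(abs(I_perm - E_I) >= abs(I_obs - E_I))) / (nperm + 1)
  list(I = I_obs, expected = E_I, p = p, n = n, nperm = nperm)
}

#' Welch t-test for seasonal vessel-activity differences
#'
#' Two-sample Welch t-test of per-cell (or per-period) vessel hours in summer
#' vs the other seasons. Two identical zero-variance groups report t = 0 and
#' p = 1 rather than failing.
#'
#' @param hours_summer,hours_other numeric vectors (>= 2 values each).
#' @return list: `t`, `p`, `df`, group means.
#' @export
seasonal_ttest <- function(hours_summer, hours_other) {
  if (length(hours_summer) < 2 || length(hours_other) < 2)
    stop("need at least two observations per group")
  if (stats::sd(hours_summer) == 0 && stats::sd(hours_other) == 0) {
    if (mean(hours_summer) == mean(hours_other))
      return(list(t = 0, p = 1, df = NA_real_,
                  mean_summer = mean(hours_summer),
                  mean_other = mean(hours_other)))
    stop("zero-variance groups with different means: t is undefined")
  }
  tt <- stats::t.test(hours_summer, hours_other)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_summer = mean(hours_summer), mean_other = mean(hours_other))
}
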