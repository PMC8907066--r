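# Great-circle distances and the inverse-variance-weighted decay-curve fit
# relating excess relatedness to geographic distance.

#' Great-circle distance with dummy offset
#'
#' Haversine distance on a sphere of radius 6,371 km, plus a dummy value of
#' 0.001 km added to each distance (so identical coordinates give exactly
#' 0.001 km and the hyperbolic decay curve stays finite at zero separation).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90))
    stop("latitude out of range [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 360))
    stop("longitude out of range")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  h <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(h))) + 0.001
}

#' Fit the excess-relatedness decay curve
#'
#' Fits `y = 1 / (m x + a) + b` to (distance, excess relatedness) points by
#' inverse-variance-weighted least squares. The surface has flat directions
#' (a joint rescaling of `m` and `a` trades off against `b`), so the
#' optimizer uses a deterministic multi-start: a log-spaced grid over `m`,
#' with `a` initialized from the short-distance amplitude and `b` from the
#' long-distance tail, each refined by `nlminb` on `(log m, log a, b)` to
#' keep `m x + a` positive.
#'
#' @param points data.frame with columns `x`, `y`, `var_y` (per-point
#'   variance; weights are `1/var_y`).
#' @param exclusions optional logical/integer vector of rows to drop.
#' @param drop_same_site drop points with `x` at the dummy offset (same
#'   coordinates).
#' @return object of class `decay_fit`: `m`, `a`, `b`, `cov`, `decay_scale`
#'   (km), `rss` (weighted), `n_points`.
#' @export
fit_decay_curve <- function(points, exclusions = NULL,
                            drop_same_site = FALSE) {
  stopifnot(all(c("x", "y", "var_y") %in% names(points)))
  if (!is.null(exclusions)) points <- points[-(seq_len(nrow(points))[exclusions]), ]
  if (drop_same_site) points <- points[points$x > 0.0015, ]
  if (any(points$var_y <= 0)) stop("var_y must be positive")
  if (nrow(points) < 4) stop("need at least 4 points, have ", nrow(points))
  x <- points$x; y <- points$y; w <- 1 / points$var_y
  obj <- function(par) {
    m <- exp(par[1]); a <- exp(par[2]); b <- par[3]
    sum(w * (y - 1 / (m * x + a) - b)^2)
  }
  # deterministic starts
  ord <- order(x)
  b0s <- stats::weighted.mean(y[ord][x[ord] >= stats::quantile(x, 2 / 3)],
                              w[ord][x[ord] >= stats::quantile(x, 2 / 3)])
  y0 <- y[ord][1]
  best <- NULL
  for (m0 in 10^seq(-4, 1, by = 1)) {
    for (b0 in unique(c(b0s, 0, min(y)))) {
      amp <- y0 - b0
      a0 <- if (is.finite(amp) && amp > 1e-12) 1 / amp else 1
      a0 <- max(a0, 1e-8)
      fit <- tryCatch(
        stats::nlminb(c(log(m0), log(a0), b0), obj,
                      control = list(iter.max = 500, abs.tol = 0,
                                     rel.tol = 1e-14, x.tol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$objective < best$objective - 1e-14))
        best <- fit
    }
  }
  if (is.null(best) || !is.finite(best$objective))
    stop("decay-curve fit failed to converge from all deterministic starts")
  m <- exp(best$par[1]); a <- exp(best$par[2]); b <- best$par[3]
  # covariance from local quadratic approximation in (m, a, b)
  gr <- cbind(x / (m * x + a)^2, 1 / (m * x + a)^2, -1)  # d resid / d par
  J <- crossprod(gr * sqrt(w))
  s2 <- best$objective / max(1, nrow(points) - 3)
  covp <- tryCatch(s2 * solve(J), error = function(e)
    matrix(NA_real_, 3, 3))
  dimnames(covp) <- list(c("m", "a", "b"), c("m", "a", "b"))
  structure(list(m = m, a = a, b = b, cov = covp,
                 decay_scale = decay_scale(m, a),
                 rss = best$objective, n_points = nrow(points)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit: y = 1/(%.4g x + %.4g) + %.4g  (n = %d, wRSS = %.4g)\n",
    x$m, x$a, x$b, x$n_points, x$rss))
  cat(sprintf("  decay scale = %.4g km\n", x$decay_scale))
  invisible(x)
}

#' Decay scale of the fitted curve
#'
#' The distance at which the curve's amplitude above its baseline `b` falls
#' to 1/e of its value at x = 0: `(e - 1) * a / m`. Invariant under joint
#' rescaling of `m` and `a`.
#'
#' @param m,a fitted constants, both positive.
#' @return distance in km.
#' @export
decay_scale <- function(m, a) {
  if (m <= 0) stop("decay scale undefined: curve is non-decaying (m <= 0)")
  if (a <= 0) stop("decay scale undefined: a must be positive")
  (exp(1) - 1) * a / m
}
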