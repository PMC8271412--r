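#' Wrap angles to the (-180, 180] degree interval
#'
#' All angles in this package live on the half-open interval (-180, 180]
#' degrees, with -180 mapped to +180 so the pure-right sleep position has a
#' single representation.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped into (-180, 180].
#' @examples
#' wrap_angle(c(190, -180, 540))
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' Circular mean, standard deviation and median of angles in degrees
#'
#' Sleep and stand angles are periodic: a set of right-lateral angles at
#' {179, -179} has mean 180, not 0. `circ_mean()` returns the direction of
#' the resultant vector; `circ_sd()` returns the circular standard deviation
#' `sqrt(-2 log R)` (in degrees), which approaches the arithmetic SD for
#' concentrated data; `circ_median()` minimises the mean circular distance
#' over the observed angles.
#'
#' @param x Numeric vector of angles in degrees. `NA`s are dropped.
#' @return A length-one numeric, in degrees, wrapped to (-180, 180]
#'   (`circ_sd()` is a non-negative dispersion, not wrapped). Empty input
#'   gives `NA`.
#' @examples
#' circ_mean(c(179, -179))
#' circ_sd(c(85, 95))
#' @export
circ_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  r <- x * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' @rdname circ_mean
#' @export
circ_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  r <- x * pi / 180
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(rbar, 1) # guard tiny numeric overshoot
  sqrt(-2 * log(rbar)) * 180 / pi
}

#' @rdname circ_mean
#' @export
circ_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (length(x) == 1L) return(wrap_angle(x))
  cost <- vapply(x, function(m) mean(abs(circ_dist(x, m))), numeric(1))
  wrap_angle(x[which.min(cost)])
}

#' Signed circular distance between angles
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Signed difference `a - b` wrapped into (-180, 180] degrees; use
#'   `abs()` for the usual circular distance in \[0, 180\].
#' @examples
#' circ_dist(179, -179)
#' @export
circ_dist <- function(a, b) {
  wrap_angle(a - b)
}

# von Mises sampler (Best & Fisher 1979); kappa = 0 falls back to uniform.
# Used by the night simulator for angular jitter around position centers.
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) {
    return(wrap_angle(stats::runif(n, -180, 180)))
  }
  if (kappa > 1e7) { # sub-0.02-degree jitter: numerically a point mass
    return(wrap_angle(rep(mu_deg, n)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(mu_deg + out * 180 / pi)
}
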