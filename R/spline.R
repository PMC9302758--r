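#' Periodic piecewise cubic spline through a closed 3D loop
#'
#' Fits three independent one-dimensional periodic cubic splines (one per
#' coordinate axis) through an ordered closed loop of 3D points. The
#' parameter is cumulative chord length; the unknown second derivatives at
#' the knots solve the cyclic tridiagonal continuity system
#' `l_(k-1) g''_(k-1) + 2 (l_(k-1) + l_k) g''_k + l_k g''_(k+1) = 6 (dg_k - dg_(k-1))`
#' with periodic closure (value, tangent and curvature match at the seam).
#' The production solver is O(n) (Thomas algorithm plus a Sherman-Morrison
#' correction for the cyclic corner entries).
#'
#' @param points numeric matrix (n x 3) of reference points in order around
#'   the loop; the closing segment from the last point back to the first is
#'   implicit. At least 4 distinct points, no repeated consecutive points.
#' @return object of class `periodic_spline`: list with `knots` (length
#'   n + 1, chord-length parameters of the n + 1 loop points with the first
#'   repeated at the end), `values` ((n + 1) x 3), `second_derivatives`
#'   ((n + 1) x 3), `section_lengths` (length n), and `period`.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' sp <- fit_periodic_spline(cbind(10 * cos(th), 10 * sin(th), 0))
#' evaluate_spline(sp, sp$knots[3])  # interpolates the 3rd point exactly
fit_periodic_spline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must be an n x 3 matrix")
  n <- nrow(points)
  if (n < 4) stop("need at least 4 reference points")
  closed <- rbind(points, points[1, ])
  chords <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                            closed[-(n + 1), , drop = FALSE])^2))
  if (any(chords <= 1e-6))
    stop("duplicate consecutive reference points (chord <= 1e-6 mm) at segment ",
         which(chords <= 1e-6)[1])
  knots <- c(0, cumsum(chords))
  g2 <- vapply(1:3, function(ax)
    solve_periodic_second_derivs(knots, closed[, ax]), numeric(n))
  g2 <- rbind(g2, g2[1, , drop = FALSE])  # periodic: g''(p_n) = g''(p_0)
  structure(list(knots = knots, values = closed, second_derivatives = g2,
                 section_lengths = chords, period = knots[n + 1]),
            class = "periodic_spline")
}

# Second derivatives g'' at the n distinct knots of a periodic cubic spline.
# knots: length n+1 (closed); y: length n+1 with y[n+1] == y[1].
# System row k (k = 1..n, indices mod n):
#   l[k-1] g2[k-1] + 2 (l[k-1] + l[k]) g2[k] + l[k] g2[k+1] = rhs[k]
solve_periodic_second_derivs <- function(knots, y) {
  n <- length(knots) - 1L
  l <- diff(knots)
  dd <- diff(y) / l                      # divided differences, length n
  prev <- c(n, seq_len(n - 1))           # k-1 cyclically
  rhs <- 6 * (dd - dd[prev])
  lower <- l[prev]                       # coefficient of g2[k-1]
  diagc <- 2 * (l[prev] + l)
  upper <- l                             # coefficient of g2[k+1]
  solve_cyclic_tridiag(lower, diagc, upper, rhs)
}

# O(n) cyclic tridiagonal solver: Thomas algorithm with a Sherman-Morrison
# rank-one correction for the (1,n) and (n,1) corner entries.
solve_cyclic_tridiag <- function(lower, diagc, upper, rhs) {
  n <- length(diagc)
  if (n < 3) stop("cyclic system needs at least 3 unknowns")
  alpha <- lower[1]   # A[1, n]
  beta <- upper[n]    # A[n, 1]
  gamma <- -diagc[1]
  d <- diagc
  d[1] <- d[1] - gamma
  d[n] <- d[n] - alpha * beta / gamma
  u <- numeric(n); u[1] <- gamma; u[n] <- beta
  v <- numeric(n); v[1] <- 1; v[n] <- alpha / gamma
  y1 <- solve_tridiag(lower, d, upper, rhs)
  y2 <- solve_tridiag(lower, d, upper, u)
  y1 - y2 * (sum(v * y1) / (1 + sum(v * y2)))
}

solve_tridiag <- function(lower, diagc, upper, rhs) {
  n <- length(diagc)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diagc[1]
  dp[1] <- rhs[1] / diagc[1]
  for (k in 2:n) {
    m <- diagc[k] - lower[k] * cp[k - 1]
    cp[k] <- upper[k] / m
    dp[k] <- (rhs[k] - lower[k] * dp[k - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (k in (n - 1):1) x[k] <- dp[k] - cp[k] * x[k + 1]
  x
}

#' Evaluate a periodic spline (position, tangent, curvature)
#'
#' Evaluates the cubic piece containing the (period-wrapped) parameter, or
#' its first or second derivative with respect to the chord-length parameter.
#'
#' @param spline a [fit_periodic_spline()] result.
#' @param p numeric vector of parameter values; wrapped into `[0, period)`.
#' @param deriv 0 (position), 1 (first derivative) or 2 (second derivative).
#' @return numeric matrix (`length(p)` x 3).
#' @export
evaluate_spline <- function(spline, p, deriv = 0L) {
  stopifnot(deriv %in% 0:2)
  knots <- spline$knots
  n <- length(knots) - 1L
  pw <- p %% spline$period
  k <- pmin(pmax(findInterval(pw, knots, rightmost.closed = TRUE), 1L), n)
  l <- spline$section_lengths[k]
  t0 <- pw - knots[k]
  t1 <- pw - knots[k + 1]
  out <- matrix(0, length(p), 3)
  for (ax in 1:3) {
    g2a <- spline$second_derivatives[k + 1, ax]
    g2b <- spline$second_derivatives[k, ax]
    ga <- spline$values[k + 1, ax]
    gb <- spline$values[k, ax]
    out[, ax] <- switch(as.character(deriv),
      "0" = g2a * (t0^3 / (6 * l) - l * t0 / 6) +
            g2b * (-t1^3 / (6 * l) + l * t1 / 6) +
            ga * t0 / l - gb * t1 / l,
      "1" = g2a * (t0^2 / (2 * l) - l / 6) +
            g2b * (-t1^2 / (2 * l) + l / 6) +
            (ga - gb) / l,
      "2" = g2a * t0 / l - g2b * t1 / l)
  }
  out
}
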