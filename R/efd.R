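#' Chain-code a closed contour
#'
#' Computes per-step displacements, Euclidean step lengths and cumulative
#' arc lengths for a closed contour, including the closing step from the
#' last point back to the first. For integer pixel chains every step is an
#' 8-neighbour move and the lengths are the Freeman values 1 (axis step) or
#' sqrt(2) (diagonal); for analytic contours the length is simply the
#' segment length (the contour is treated as piecewise linear between
#' samples).
#'
#' @param contour a `canopy_contour` (or 2-column matrix accepted by
#'   [as_contour()]).
#' @param pixel_chain if `TRUE`, verify that all steps are 8-neighbour
#'   moves (integer displacements in \{-1, 0, 1\}); if `NULL` (default)
#'   this check is applied when all coordinates are whole numbers.
#' @return object of class `chain_code`: list with `points` (s x 2, start
#'   point first), `dx`, `dy`, `dt` (per-step, step p goes from point p to
#'   point p+1, the last step closing the loop), `t` (cumulative arc length
#'   after each step), `T` (perimeter) and `s` (step count).
#' @export
chain_code <- function(contour, pixel_chain = NULL) {
  contour <- as_contour(unclass(contour))
  p <- unclass(contour)
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  dx <- nxt[, 1] - p[, 1]
  dy <- nxt[, 2] - p[, 2]
  if (is.null(pixel_chain))
    pixel_chain <- all(p == round(p)) && all(abs(dx) <= 1) && all(abs(dy) <= 1)
  if (pixel_chain &&
      (any(abs(dx) > 1) || any(abs(dy) > 1) || any(dx != round(dx)) ||
       any(dy != round(dy))))
    stop("consecutive contour points are not 8-neighbours")
  dt <- sqrt(dx^2 + dy^2)
  t <- cumsum(dt)
  structure(list(points = p, dx = dx, dy = dy, dt = dt,
                 t = t, T = t[length(t)], s = length(dt)),
            class = "chain_code")
}

#' Elliptic Fourier descriptors of a chain-coded contour
#'
#' Expands the closed piecewise-linear curve x(t), y(t) (t = arc length)
#' into a truncated Fourier series. For harmonic n,
#' \deqn{a_n = \frac{T}{2n^2\pi^2}\sum_p \frac{\Delta x_p}{\Delta t_p}
#'   \left(\cos\frac{2n\pi t_p}{T} - \cos\frac{2n\pi t_{p-1}}{T}\right)}
#' and analogously b (sin, x), c (cos, y), d (sin, y). The DC terms
#' `A0`, `C0` are the arc-length averages of x(t) and y(t) (the centroid of
#' the curve under uniform-speed traversal), so reconstructions live in the
#' same absolute coordinates as the input contour.
#'
#' @param chain a [chain_code()] (a bare contour is chain-coded first).
#' @param N number of harmonics (>= 1); 4N coefficients are returned.
#' @return object of class `efd`: list with `A0`, `C0`, `coef` (N x 4
#'   matrix, columns a, b, c, d), `N`, `T` and the start point.
#' @export
efourier <- function(chain, N) {
  if (inherits(chain, "canopy_contour") || is.matrix(chain))
    chain <- chain_code(chain)
  if (!inherits(chain, "chain_code")) stop("chain must be a chain_code")
  if (N < 1) stop("N must be >= 1")
  N <- as.integer(N)
  T <- chain$T
  if (T <= 0) stop("zero-perimeter contour")
  tp <- chain$t
  t0 <- c(0, tp[-length(tp)])
  n <- seq_len(N)
  ang1 <- outer(tp, n) * (2 * pi / T)   # s x N
  ang0 <- outer(t0, n) * (2 * pi / T)
  dcos <- cos(ang1) - cos(ang0)
  dsin <- sin(ang1) - sin(ang0)
  wx <- chain$dx / chain$dt
  wy <- chain$dy / chain$dt
  const <- T / (2 * n^2 * pi^2)
  coef <- cbind(a = const * colSums(wx * dcos),
                b = const * colSums(wx * dsin),
                c = const * colSums(wy * dcos),
                d = const * colSums(wy * dsin))
  # DC terms: trapezoid rule on the piecewise-linear x(t), y(t)
  x <- chain$points[, 1]; y <- chain$points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  A0 <- sum(chain$dt * (x + xn) / 2) / T
  C0 <- sum(chain$dt * (y + yn) / 2) / T
  structure(list(A0 = A0, C0 = C0, coef = coef, N = N, T = T,
                 start = chain$points[1, ]),
            class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat(sprintf("efd: %d harmonics, perimeter %.2f, centre (%.2f, %.2f)\n",
              x$N, x$T, x$A0, x$C0))
  invisible(x)
}

#' Reconstruct a contour from elliptic Fourier descriptors
#'
#' Evaluates the truncated series at the requested arc-length positions.
#'
#' @param efd an [efourier()] result (or `efd_std`; see Details).
#' @param N harmonics to use, `1 <= N <= efd$N`.
#' @param t arc-length positions in \[0, T]; default `n_points` equally
#'   spaced positions.
#' @param n_points used when `t` is missing.
#' @return `canopy_contour` of reconstructed points.
#' @details A standardized descriptor set can be reconstructed too; it is
#'   re-embedded with `A0 = C0 = 0` and unit perimeter scale, yielding the
#'   normalized shape.
#' @export
efd_reconstruct <- function(efd, N = efd$N, t = NULL, n_points = 300) {
  if (N < 1) stop("N must be >= 1")
  if (N > efd$N) stop("N exceeds the ", efd$N, " stored harmonics")
  N <- as.integer(N)
  T <- if (is.null(efd$T)) 1 else efd$T
  if (is.null(t)) t <- seq(0, T, length.out = n_points + 1)[-(n_points + 1)]
  if (any(t < 0 | t > T)) stop("t values must lie in [0, T]")
  xy <- efd_evaluate(efd, N, t)
  as_contour(xy)
}

# series evaluation shared by reconstruction and error computation;
# returns a plain matrix (possibly with duplicate rows)
efd_evaluate <- function(efd, N, t) {
  T <- if (is.null(efd$T)) 1 else efd$T
  n <- seq_len(N)
  ang <- outer(t, n) * (2 * pi / T)
  cosA <- cos(ang); sinA <- sin(ang)
  A0 <- if (is.null(efd$A0)) 0 else efd$A0
  C0 <- if (is.null(efd$C0)) 0 else efd$C0
  cf <- efd$coef
  cbind(x = A0 + cosA %*% cf[n, 1] + sinA %*% cf[n, 2],
        y = C0 + cosA %*% cf[n, 3] + sinA %*% cf[n, 4])
}

# semi-major axis length of the first-harmonic ellipse: rotate the start
# point to the major axis (phase theta) and measure the radius there
first_harmonic_frame <- function(efd) {
  a1 <- unname(efd$coef[1, 1]); b1 <- unname(efd$coef[1, 2])
  c1 <- unname(efd$coef[1, 3]); d1 <- unname(efd$coef[1, 4])
  denom <- a1^2 + c1^2 - b1^2 - d1^2
  num <- 2 * (a1 * b1 + c1 * d1)
  theta <- 0.5 * atan2(num, denom)
  # theta is defined modulo pi/2 by the extremum condition; pick the
  # candidate that lands on the major (not minor) axis
  cand <- c(theta, theta + pi / 2)
  r2 <- vapply(cand, function(th) {
    (a1 * cos(th) + b1 * sin(th))^2 + (c1 * cos(th) + d1 * sin(th))^2
  }, numeric(1))
  theta <- cand[which.max(r2)]
  theta <- theta %% (2 * pi)
  astar <- a1 * cos(theta) + b1 * sin(theta)
  cstar <- c1 * cos(theta) + d1 * sin(theta)
  L <- sqrt(astar^2 + cstar^2)
  psi <- atan2(cstar, astar)
  list(L = L, psi = psi, theta = theta)
}

#' Normalized reconstruction error of a truncated descriptor set
#'
#' The maximum Euclidean deviation between original contour points and the
#' series evaluated at the same arc-length positions, normalized by the
#' full major-axis length (2L, with L the semi-major axis of the
#' first-harmonic ellipse) and expressed in percent:
#' \deqn{E_N = \max_p \|(x_p, y_p) - (x_{Np}, y_{Np})\| / (2L) \times 100}
#'
#' @param chain the [chain_code()] the descriptors were computed from.
#' @param efd the [efourier()] descriptor set.
#' @param N harmonics to use (default all stored).
#' @return scalar percent error (class `numeric`).
#' @export
efd_error <- function(chain, efd, N = efd$N) {
  if (inherits(chain, "canopy_contour") || is.matrix(chain))
    chain <- chain_code(chain)
  L <- first_harmonic_frame(efd)$L
  if (L <= 0) stop("degenerate first harmonic (L = 0)")
  rec <- efd_evaluate(efd, N, chain$t)
  orig <- rbind(chain$points[-1, , drop = FALSE], chain$points[1, , drop = FALSE])
  # chain$t[p] is the arc length at point p+1 (t_s closes back to point 1)
  dev <- sqrt(rowSums((orig - rec)^2))
  max(dev) / (2 * L) * 100
}

#' Index of the most complex contour in a collection
#'
#' Ranks contours by the reconstruction error of a low-order probe
#' expansion (10 harmonics by default): shapes with high-frequency boundary
#' detail leave the largest residual. Ties break to the lowest index.
#'
#' @param contours list of contours.
#' @param probe_N number of probe harmonics.
#' @return integer index into `contours`.
#' @export
find_most_complex <- function(contours, probe_N = 10) {
  if (length(contours) == 0) stop("empty contour collection")
  errs <- vapply(contours, function(ct) {
    ch <- chain_code(ct)
    efd_error(ch, efourier(ch, probe_N))
  }, numeric(1))
  unname(which.max(errs))  # first maximum: ties break to the lowest index
}

#' Choose the number of harmonics by an error threshold
#'
#' Sweeps the harmonic count over an arithmetic sequence and returns the
#' smallest value whose normalized reconstruction error [efd_error()] drops
#' to the threshold. If no sweep value qualifies the sweep maximum is
#' returned with a warning and attribute `converged = FALSE`.
#'
#' @param contour the contour to analyse (typically the most complex one).
#' @param threshold_pct target error in percent.
#' @param sweep increasing integer sequence of candidate harmonic counts.
#' @return selected harmonic count with attributes `errors` (the full sweep
#'   error curve) and `converged`.
#' @export
select_n_harmonics <- function(contour, threshold_pct = 1,
                               sweep = seq(10, 1000, by = 10)) {
  if (length(sweep) == 0) stop("empty sweep")
  if (threshold_pct < 0) stop("threshold must be positive")
  sweep <- as.integer(sort(sweep))
  ch <- chain_code(contour)
  efd <- efourier(ch, max(sweep))
  L <- first_harmonic_frame(efd)$L
  if (L <= 0) stop("degenerate first harmonic (L = 0)")
  # evaluate all truncations in one pass: per-harmonic contributions at the
  # original arc-length positions, accumulated across the sweep
  T <- efd$T
  tp <- ch$t
  orig <- rbind(ch$points[-1, , drop = FALSE], ch$points[1, , drop = FALSE])
  x <- rep(efd$A0, length(tp))
  y <- rep(efd$C0, length(tp))
  errors <- numeric(length(sweep))
  prev <- 0L
  for (i in seq_along(sweep)) {
    n_new <- seq.int(prev + 1L, sweep[i])
    ang <- outer(tp, n_new) * (2 * pi / T)
    cosA <- cos(ang); sinA <- sin(ang)
    x <- x + cosA %*% efd$coef[n_new, 1] + sinA %*% efd$coef[n_new, 2]
    y <- y + cosA %*% efd$coef[n_new, 3] + sinA %*% efd$coef[n_new, 4]
    errors[i] <- max(sqrt((orig[, 1] - x)^2 + (orig[, 2] - y)^2)) / (2 * L) * 100
    prev <- sweep[i]
  }
  ok <- which(errors <= threshold_pct)
  if (length(ok)) {
    out <- sweep[ok[1]]
    converged <- TRUE
  } else {
    out <- sweep[length(sweep)]
    converged <- FALSE
    warning("error threshold ", threshold_pct,
            "% not reached within the sweep; returning the sweep maximum")
  }
  structure(out, errors = stats::setNames(errors, sweep), converged = converged)
}

#' Standardize elliptic Fourier descriptors
#'
#' Makes the coefficients invariant to size, rotation and starting point
#' (Kuhl-Giardina normalization). Each harmonic block is rotated on the
#' right by n times the start-point phase \eqn{\theta = 2\pi t_m/T}
#' (moving the effective start point to the tip of the first-harmonic
#' ellipse's major axis), rotated on the left by the major-axis orientation
#' \eqn{\psi}, and scaled by the semi-major axis length L:
#' \deqn{\begin{bmatrix} a_n^* & b_n^* \\ c_n^* & d_n^* \end{bmatrix} =
#'  \frac{1}{L} R(-\psi)
#'  \begin{bmatrix} a_n & b_n \\ c_n & d_n \end{bmatrix} R(n\theta)}
#' After standardization \eqn{a_1^* = 1}, \eqn{b_1^* = 0},
#' \eqn{c_1^* = 0}. The sign ambiguity (\eqn{\psi}, \eqn{\theta} are
#' defined modulo \eqn{\pi}) is resolved by requiring the first harmonic's
#' semi-major axis to align with +x (so \eqn{a_1^* > 0}); no reflection is
#' ever applied, so mirrored shapes standardize to different descriptors.
#'
#' @param efd an [efourier()] result.
#' @return object of class `efd_std`: list with `coef` (N x 4 standardized
#'   quadruples), `N`, and the normalization frame `L`, `psi`, `theta`,
#'   `A0`, `C0`, `T` and the modified start point `xm`, `ym`.
#' @export
efd_standardize <- function(efd) {
  if (!inherits(efd, "efd")) stop("efd must be an efourier() result")
  fr <- first_harmonic_frame(efd)
  if (fr$L <= 0 || !is.finite(fr$L))
    stop("degenerate first harmonic (L = 0); cannot standardize")
  N <- efd$N
  cpsi <- cos(fr$psi); spsi <- sin(fr$psi)
  Rpsi <- matrix(c(cpsi, -spsi, spsi, cpsi), 2, 2)  # rows: [cos, sin; -sin, cos]
  coef <- matrix(0, N, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(N)) {
    cn <- cos(n * fr$theta); sn <- sin(n * fr$theta)
    Rth <- matrix(c(cn, sn, -sn, cn), 2, 2)  # [cos -sin; sin cos]
    M <- matrix(efd$coef[n, ], 2, 2, byrow = TRUE)  # [a b; c d]
    coef[n, ] <- as.vector(t(Rpsi %*% M %*% Rth)) / fr$L
  }
  # modified start point: position of the curve at t_m = theta*T/(2*pi)
  xm <- efd$A0 + fr$L * cpsi
  ym <- efd$C0 + fr$L * spsi
  structure(list(coef = coef, N = N, L = fr$L, psi = fr$psi,
                 theta = fr$theta, A0 = efd$A0, C0 = efd$C0, T = efd$T,
                 xm = xm, ym = ym),
            class = "efd_std")
}

#' @export
print.efd_std <- function(x, ...) {
  cat(sprintf(
    "standardized efd: %d harmonics, L = %.3f, psi = %.4f rad, theta = %.4f rad\n",
    x$N, x$L, x$psi, x$theta))
  invisible(x)
}

#' Re-embed standardized coefficients as a descriptor set
#'
#' Useful to reconstruct or re-standardize the normalized shape: returns an
#' `efd` with `A0 = C0 = 0`, unit perimeter and the standardized quadruples.
#'
#' @param std an [efd_standardize()] result.
#' @export
efd_from_standardized <- function(std) {
  structure(list(A0 = 0, C0 = 0, coef = std$coef, N = std$N, T = 1,
                 start = c(0, 0)),
            class = "efd")
}

#' Serialize a descriptor record compactly
#'
#' Writes `A0`, `C0` and the 4N coefficients as little-endian doubles, the
#' storage format behind the two-orders-of-magnitude size reduction
#' relative to the source photograph.
#'
#' @param efd an [efourier()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_efd_bin <- function(efd, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(efd$N), con, size = 4, endian = "little")
  writeBin(c(efd$A0, efd$C0, as.vector(t(efd$coef))), con,
           size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_efd_bin
#' @export
read_efd_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  N <- readBin(con, "integer", 1, size = 4, endian = "little")
  v <- readBin(con, "double", 2 + 4 * N, size = 8, endian = "little")
  coef <- matrix(v[-(1:2)], N, 4, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  structure(list(A0 = v[1], C0 = v[2], coef = coef, N = N, T = NULL,
                 start = c(NA, NA)),
            class = "efd")
}
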