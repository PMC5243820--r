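# polygon scalar measures used throughout: signed area (shoelace),
# perimeter, centroid and second central moments. Contours traced
# counter-clockwise in the y-up frame have positive signed area.

polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(xy) {
  nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - xy)^2)))
}

# area-normalized central second moments (covariance of the uniform
# density over the polygon interior), via the standard closed forms
polygon_moments <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps) stop("degenerate polygon (zero area)")
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  # raw moments about the origin
  Ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12        # integral of y^2 dA
  Iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12        # integral of x^2 dA
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(area = A, cx = cx, cy = cy,
       var_x = Iyy / A - cx^2,
       var_y = Ixx / A - cy^2,
       cov_xy = Ixy / A - cx * cy)
}

#' Moment-equivalent ellipse of a contour
#'
#' The ellipse with the same area-normalized second central moments as the
#' polygon enclosed by the contour (the convention used by standard image
#' analysis tools for "best-fitted ellipse"). For an ellipse with
#' semi-axes (p, q) the variance along the major axis is p^2/4, so the
#' axes are 4 times the square roots of the covariance eigenvalues.
#'
#' @param contour closed non-collinear contour (at least 3 points).
#' @return list with `major`, `minor` (full axis lengths, major >= minor),
#'   `center` and `orientation` (radians, major axis vs +x, in (-pi/2,
#'   pi/2]).
#' @export
fit_ellipse <- function(contour) {
  xy <- unclass(as_contour(unclass(contour)))
  m <- polygon_moments(xy)
  if (m$area < 0) { xy <- xy[rev(seq_len(nrow(xy))), ]; m <- polygon_moments(xy) }
  S <- matrix(c(m$var_x, m$cov_xy, m$cov_xy, m$var_y), 2, 2)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] <= .Machine$double.eps * max(1, e$values[1]))
    stop("degenerate (collinear) contour: ellipse fit undefined")
  major <- 4 * sqrt(e$values[1])
  minor <- 4 * sqrt(e$values[2])
  v <- e$vectors[, 1]
  orientation <- atan2(v[2], v[1])
  if (orientation <= -pi / 2) orientation <- orientation + pi
  if (orientation > pi / 2) orientation <- orientation - pi
  list(major = major, minor = minor, center = c(m$cx, m$cy),
       orientation = orientation)
}

#' Traditional morphometric traits of a closed contour
#'
#' Computes, on the polygon traced by the contour:
#' \itemize{
#'  \item aspect ratio: major / minor axis of the moment ellipse
#'   ([fit_ellipse()]);
#'  \item roundness: \eqn{4 A / (\pi \cdot \mathrm{major}^2)}, area-based
#'   closeness to a circle;
#'  \item circularity: \eqn{4 \pi A / P^2}, the isoperimetric ratio;
#'  \item solidity: \eqn{A / A_{hull}}, area over convex-hull area.
#' }
#' Area is the absolute shoelace area, perimeter the summed segment
#' lengths, hull area the shoelace area of the convex hull
#' ([grDevices::chull()]). Digitized pixel chains carry a small upward
#' perimeter bias (no smoothing correction is applied), which biases
#' circularity slightly downward; this affects originals and
#' reconstructions alike.
#'
#' @param contour closed contour.
#' @param id optional identifier stored in the result.
#' @return one-row data.frame: `aspect_ratio`, `roundness`, `circularity`,
#'   `solidity`, `area`, `perimeter`, `convex_area` (+ `id` if given).
#' @export
shape_traits <- function(contour, id = NULL) {
  xy <- unclass(as_contour(unclass(contour)))
  A_signed <- polygon_signed_area(xy)
  if (abs(A_signed) < .Machine$double.eps)
    stop("zero or ambiguous polygon area (self-intersecting contour?)")
  A <- abs(A_signed)
  P <- polygon_perimeter(xy)
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  convA <- abs(polygon_signed_area(hull))
  ell <- fit_ellipse(xy)
  out <- data.frame(
    aspect_ratio = ell$major / ell$minor,
    roundness = 4 * A / (pi * ell$major^2),
    circularity = 4 * pi * A / P^2,
    solidity = A / convA,
    area = A, perimeter = P, convex_area = convA)
  if (!is.null(id)) out <- cbind(data.frame(id = id), out)
  out
}

#' Trait fidelity of truncated Fourier reconstructions
#'
#' For each contour, computes the four traits from the original polygon
#' and from its N-harmonic reconstruction (evaluated at the original
#' arc-length positions so original and reconstruction have the same
#' vertex count), then summarizes per-trait agreement.
#'
#' @param contours named or unnamed list of contours.
#' @param efds matching list of [efourier()] sets (computed from the same
#'   contours, same order/ids).
#' @param N harmonics for reconstruction (each set must store >= N).
#' @param ids optional ids; default names of `contours` or seq_along.
#' @return list with `traits` (long table, `source` in
#'   \{"original", "reconstructed"\}) and `summary` (per-trait Pearson
#'   correlation and maximum relative deviation).
#' @export
trait_fidelity <- function(contours, efds, N, ids = NULL) {
  if (length(contours) != length(efds))
    stop("contours and efds differ in length: id mismatch")
  if (is.null(ids)) ids <- names(contours)
  if (is.null(ids)) ids <- as.character(seq_along(contours))
  if (!is.null(names(efds)) && !identical(as.character(names(efds)), as.character(ids)))
    stop("efd ids do not match contour ids")
  rows <- vector("list", 2 * length(contours))
  for (i in seq_along(contours)) {
    ch <- chain_code(contours[[i]])
    orig <- shape_traits(contours[[i]], id = ids[i])
    rec_xy <- efd_reconstruct(efds[[i]], N = N, t = c(0, ch$t[-ch$s]))
    rec <- shape_traits(rec_xy, id = ids[i])
    orig$source <- "original"; rec$source <- "reconstructed"
    rows[[2 * i - 1]] <- orig; rows[[2 * i]] <- rec
  }
  traits <- do.call(rbind, rows)
  tn <- c("aspect_ratio", "roundness", "circularity", "solidity")
  o <- traits[traits$source == "original", ]
  r <- traits[traits$source == "reconstructed", ]
  r <- r[match(o$id, r$id), ]
  summary <- data.frame(
    trait = tn,
    correlation = vapply(tn, function(v) {
      if (nrow(o) < 2) return(NA_real_)  # undefined for a single canopy
      so <- stats::sd(o[[v]]); sr <- stats::sd(r[[v]])
      if (so == 0 && sr == 0) 1                     # both constant: agree
      else if (so == 0 || sr == 0) NA_real_         # correlation undefined
      else stats::cor(o[[v]], r[[v]])
    }, numeric(1)),
    max_rel_dev = vapply(tn, function(v)
      max(abs(r[[v]] - o[[v]]) / abs(o[[v]])), numeric(1)),
    row.names = NULL)
  list(traits = traits, summary = summary)
}

#' Write / read a trait table as CSV
#'
#' Schema: `id`, `aspect_ratio`, `roundness`, `circularity`, `solidity`,
#' `area`, `perimeter`, `convex_area`, `source`; numeric columns are
#' written at full double precision.
#' @param traits trait table (as produced by [shape_traits()] /
#'   [trait_fidelity()]).
#' @param path CSV path.
#' @export
write_trait_csv <- function(traits, path) {
  need <- c("id", "aspect_ratio", "roundness", "circularity", "solidity",
            "area", "perimeter", "convex_area")
  if (!"source" %in% names(traits)) traits$source <- "original"
  check_schema(traits, c(need, "source"), "trait table")
  write_table_lossless(traits[, c(need, "source")], path)
}

#' @rdname write_trait_csv
#' @export
read_trait_csv <- function(path) {
  df <- utils::read.csv(path)
  check_schema(df, c("id", "aspect_ratio", "roundness", "circularity",
                     "solidity", "area", "perimeter", "convex_area",
                     "source"), "trait table")
  df
}
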