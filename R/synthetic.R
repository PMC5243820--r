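#' Parameters for a synthetic canopy image
#'
#' Describes a star-convex, lobed silhouette rendered as green foliage on
#' a brown soil background. The boundary is the radial curve
#' \deqn{r(\phi) = R(\phi)\,(1 + A\cos(m\phi) + \eta(\phi))}
#' where \eqn{R(\phi)} is the radius of the base ellipse with the given
#' semi-axes, m = `lobe_count`, A = `lobe_amplitude` and \eqn{\eta} is a
#' smooth random perturbation with pointwise standard deviation
#' `boundary_noise_sd` (a low-order random cosine series, so the outline
#' stays smooth and simple). Lobes emulate the leaflet-driven boundary
#' complexity of real canopies. The constraint
#' `lobe_amplitude + 3 * boundary_noise_sd < 1` keeps the radius positive
#' and the polygon simple.
#'
#' Debris specks are small foreground-coloured disks away from the canopy
#' (removed by [clean_mask()]); holes are interior background-coloured
#' disks (removed by [fill_holes()]).
#'
#' @param semi_axes base ellipse semi-axes in pixels (length 2).
#' @param lobe_count integer >= 0.
#' @param lobe_amplitude fraction of the base radius.
#' @param boundary_noise_sd fraction of the base radius.
#' @param rotation radians.
#' @param debris_count,hole_count integers >= 0.
#' @param size image size in pixels, `c(height, width)`.
#' @param n_vertices polygon resolution of the analytic boundary.
#' @param seed integer seed driving every random draw for this image.
#' @return object of class `canopy_params`.
#' @export
canopy_params <- function(semi_axes = c(80, 60), lobe_count = 6,
                          lobe_amplitude = 0.15, boundary_noise_sd = 0.02,
                          rotation = 0, debris_count = 0, hole_count = 0,
                          size = c(256, 256), n_vertices = 720,
                          seed = 1) {
  stopifnot(length(semi_axes) == 2, all(semi_axes > 0),
            lobe_count >= 0, lobe_amplitude >= 0, boundary_noise_sd >= 0,
            debris_count >= 0, hole_count >= 0, length(size) == 2)
  if (lobe_amplitude + 3 * boundary_noise_sd >= 1)
    stop("lobe_amplitude + 3*boundary_noise_sd must be < 1 ",
         "(shape would not stay simple)")
  structure(list(semi_axes = as.numeric(semi_axes),
                 lobe_count = as.integer(lobe_count),
                 lobe_amplitude = lobe_amplitude,
                 boundary_noise_sd = boundary_noise_sd,
                 rotation = rotation,
                 debris_count = as.integer(debris_count),
                 hole_count = as.integer(hole_count),
                 size = as.integer(size),
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "canopy_params")
}

# analytic boundary polygon in y-up coordinates centred on `center`
canopy_polygon <- function(params, center, noise_coefs = NULL) {
  phi <- seq(0, 2 * pi, length.out = params$n_vertices + 1)[-(params$n_vertices + 1)]
  a <- params$semi_axes[1]; b <- params$semi_axes[2]
  R <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  mod <- 1 + params$lobe_amplitude * cos(params$lobe_count * phi)
  if (!is.null(noise_coefs)) {
    eta <- rowSums(vapply(seq_along(noise_coefs$amp), function(j)
      noise_coefs$amp[j] * cos(j * phi + noise_coefs$phase[j]),
      numeric(length(phi))))
    mod <- mod + eta
  }
  r <- R * mod
  th <- phi + params$rotation
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# scanline (even-odd) rasterization of a simple polygon given in y-up
# coordinates; returns a logical h x w matrix (row 1 = top of image).
# A pixel at (row, col) has centre x = col, y = h - row + 1.
rasterize_polygon <- function(xy, h, w) {
  mask <- matrix(FALSE, h, w)
  px <- xy[, 1]; py <- xy[, 2]
  nxt <- c(seq_len(nrow(xy))[-1], 1L)
  for (row in seq_len(h)) {
    yc <- h - row + 1
    y1 <- py; y2 <- py[nxt]
    crosses <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(crosses)) next
    i <- which(crosses)
    xs <- px[i] + (yc - y1[i]) / (y2[i] - y1[i]) * (px[nxt][i] - px[i])
    xs <- sort(xs)
    for (j in seq(1, length(xs) - 1, by = 2)) {
      lo <- ceiling(xs[j]); hi <- floor(xs[j + 1])
      if (hi >= lo) {
        lo <- max(1L, lo); hi <- min(w, hi)
        if (hi >= lo) mask[row, lo:hi] <- TRUE
      }
    }
  }
  mask
}

# disk raster helper (y-up centre)
rasterize_disk <- function(center, radius, h, w) {
  rows <- seq_len(h); cols <- seq_len(w)
  yc <- h - rows + 1
  outer(yc, cols, function(y, x) (x - center[1])^2 + (y - center[2])^2 <= radius^2)
}

# random HSV field -> RGB array values for the given logical selector
hsv_field <- function(n, h_range, s_range, v_range) {
  h <- stats::runif(n, h_range[1], h_range[2])
  s <- stats::runif(n, s_range[1], s_range[2])
  v <- stats::runif(n, v_range[1], v_range[2])
  grDevices::col2rgb(grDevices::hsv(h, s, v)) / 255
}

#' Render a synthetic canopy image with ground truth
#'
#' Draws the lobed silhouette of [canopy_params()] as green-hued foliage
#' pixels on a brown-hued soil background, optionally adding debris specks
#' and interior holes, and returns the image together with its ground
#' truth: the filled truth mask (holes do not pierce it - they are "empty
#' space inside the canopy" that segmentation is expected to fill back),
#' the analytic noiseless boundary polygon, and the traits of that
#' noiseless polygon. Foreground hues fall inside the default
#' [seg_config()] acceptance band and background hues outside it, so the
#' default segmentation succeeds by construction. The same seed always
#' yields a bit-identical image.
#'
#' @param params a [canopy_params()].
#' @return list: `image` (h x w x 3 array in \[0,1]), `mask` (truth),
#'   `contour` (noisy truth boundary polygon, y-up), `clean_contour`
#'   (noiseless analytic polygon), `traits` (traits of the noiseless
#'   polygon), `n_components` (1 + debris count actually placed), `params`.
#' @export
simulate_canopy <- function(params = canopy_params()) {
  stopifnot(inherits(params, "canopy_params"))
  set.seed(params$seed)
  h <- params$size[1]; w <- params$size[2]
  center <- c(w / 2, h / 2)
  # smooth boundary noise: 5 random low-order cosine modes
  noise_coefs <- NULL
  if (params$boundary_noise_sd > 0) {
    n_modes <- 5
    noise_coefs <- list(
      amp = stats::rnorm(n_modes, 0, params$boundary_noise_sd * sqrt(2 / n_modes)),
      phase = stats::runif(n_modes, 0, 2 * pi))
  }
  poly <- canopy_polygon(params, center, noise_coefs)
  clean_poly <- canopy_polygon(params, center, NULL)
  mask <- rasterize_polygon(poly, h, w)
  if (!any(mask)) stop("degenerate parameters: empty rasterized shape")
  # holes: interior disks, radius ~ 4-8 px, placed well inside the shape
  holes <- matrix(FALSE, h, w)
  if (params$hole_count > 0) {
    rmin <- min(params$semi_axes) * (1 - params$lobe_amplitude -
                                       3 * params$boundary_noise_sd)
    for (i in seq_len(params$hole_count)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, max(0, rmin * 0.5))
      hr <- stats::runif(1, 4, 8)
      holes <- holes | rasterize_disk(center + rad * c(cos(ang), sin(ang)),
                                      hr, h, w)
    }
    holes <- holes & mask
  }
  # debris: small foreground-coloured specks away from the canopy
  debris <- matrix(FALSE, h, w)
  n_debris_placed <- 0L
  if (params$debris_count > 0) {
    rmax <- max(params$semi_axes) * (1 + params$lobe_amplitude +
                                       3 * params$boundary_noise_sd)
    for (i in seq_len(params$debris_count)) {
      for (try in 1:50) {
        pos <- c(stats::runif(1, 5, w - 5), stats::runif(1, 5, h - 5))
        if (sqrt(sum((pos - center)^2)) > rmax + 12) break
      }
      dr <- stats::runif(1, 1.5, 3.5)
      disk <- rasterize_disk(pos, dr, h, w)
      if (any(disk) && !any(disk & mask)) {
        debris <- debris | disk
        n_debris_placed <- n_debris_placed + 1L
      }
    }
  }
  fg <- (mask & !holes) | debris
  img <- array(0, c(h, w, 3))
  n_bg <- sum(!fg); n_fg <- sum(fg)
  bg_rgb <- hsv_field(n_bg, c(0.05, 0.11), c(0.35, 0.6), c(0.3, 0.65))
  fg_rgb <- hsv_field(n_fg, c(0.22, 0.38), c(0.5, 0.9), c(0.35, 0.8))
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[!fg] <- bg_rgb[ch, ]
    plane[fg] <- fg_rgb[ch, ]
    img[, , ch] <- plane
  }
  list(image = img, mask = mask, contour = as_contour(poly),
       clean_contour = as_contour(clean_poly),
       traits = shape_traits(clean_poly),
       n_components = 1L + n_debris_placed, params = params)
}

#' Generate a fixture suite spanning a complexity gradient
#'
#' Writes `n` synthetic canopy images (plus truth masks and truth contour
#' CSVs) whose lobe count and amplitude ramp from a plain ellipse (index
#' 1: a near-circular shape) up to a designated high-lobe "most complex"
#' shape (last index), together with a manifest CSV recording parameters
#' and truth traits.
#'
#' @param out_dir output directory (created if needed).
#' @param n number of shapes (>= 2).
#' @param seed master seed; image i uses seed `seed * 1000 + i`.
#' @param size image size `c(h, w)`.
#' @param noise_sd boundary noise (0 for noiseless fixtures).
#' @param debris_count,hole_count passed to every shape.
#' @return the manifest data.frame (invisibly written to
#'   `file.path(out_dir, "manifest.csv")`), with columns `id`, `file`,
#'   `mask_file`, `contour_file`, shape parameters, `most_complex`
#'   and the truth traits.
#' @export
simulate_fixture_suite <- function(out_dir, n = 20, seed = 7,
                                   size = c(256, 256), noise_sd = 0,
                                   debris_count = 0, hole_count = 0) {
  if (n < 2) stop("need at least 2 shapes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory is not writable")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    frac <- (i - 1) / (n - 1)
    lobes <- if (i == n) 12L else as.integer(round(frac * 8))
    amp <- if (i == n) 0.3 else 0.22 * frac
    if (lobes == 0) amp <- 0
    ecc <- 1 + 0.5 * ((i - 1) %% 4) / 3          # aspect variation 1..1.5
    base <- min(size) * 0.27
    p <- canopy_params(semi_axes = c(base * ecc, base) / sqrt(ecc),
                       lobe_count = lobes, lobe_amplitude = amp,
                       boundary_noise_sd = noise_sd,
                       rotation = (i - 1) * pi / n,
                       debris_count = debris_count,
                       hole_count = hole_count,
                       size = size, seed = seed * 1000L + i)
    sim <- simulate_canopy(p)
    id <- sprintf("canopy_%03d", i)
    img_file <- file.path(out_dir, paste0(id, ".png"))
    mask_file <- file.path(out_dir, paste0(id, "_mask.png"))
    contour_file <- file.path(out_dir, paste0(id, "_contour.csv"))
    png::writePNG(sim$image, img_file)
    write_mask_png(sim$mask, mask_file)
    write_contour_csv(sim$contour, contour_file)
    rows[[i]] <- cbind(
      data.frame(id = id, file = basename(img_file),
                 mask_file = basename(mask_file),
                 contour_file = basename(contour_file),
                 lobe_count = lobes, lobe_amplitude = amp,
                 semi_major = p$semi_axes[1], semi_minor = p$semi_axes[2],
                 rotation = p$rotation, seed = p$seed,
                 most_complex = i == n),
      sim$traits)
  }
  manifest <- do.call(rbind, rows)
  write_table_lossless(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Simulate a balanced RCBD trait table with known variance components
#'
#' Draws y_ik = mu + g_i + b_k + e_ik with g ~ N(0, sigma2_g),
#' b ~ N(0, sigma2_b), e ~ N(0, sigma2_e), one observation per genotype x
#' block cell.
#'
#' @param n_genotypes,k design size (k = blocks/replications).
#' @param mu grand mean.
#' @param sigma2_g,sigma2_b,sigma2_e variance components (>= 0).
#' @param trait trait name stored in the table.
#' @param seed integer seed.
#' @return data.frame: `genotype`, `block`, `trait`, `value`.
#' @export
simulate_rcbd <- function(n_genotypes = 300, k = 3, mu = 1,
                          sigma2_g = 2, sigma2_b = 0.5, sigma2_e = 1,
                          trait = "trait", seed = 1) {
  stopifnot(n_genotypes >= 2, k >= 1,
            sigma2_g >= 0, sigma2_b >= 0, sigma2_e >= 0)
  set.seed(seed)
  g <- stats::rnorm(n_genotypes, 0, sqrt(sigma2_g))
  b <- stats::rnorm(k, 0, sqrt(sigma2_b))
  e <- stats::rnorm(n_genotypes * k, 0, sqrt(sigma2_e))
  idx <- expand.grid(genotype = seq_len(n_genotypes), block = seq_len(k))
  data.frame(genotype = sprintf("G%04d", idx$genotype),
             block = sprintf("B%d", idx$block),
             trait = trait,
             value = mu + g[idx$genotype] + b[idx$block] + e)
}
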