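#' Segmentation configuration
#'
#' Thresholds used to separate the green canopy from the soil background in
#' hue-saturation-value (HSV) space. A pixel is kept as foreground when its
#' saturation is at least `saturation_min` and its hue falls inside the
#' (possibly wrap-around) band `[hue_min, hue_max]`.
#'
#' Hues are on the \[0, 1) colour-wheel scale used by
#' [grDevices::rgb2hsv()]; values given in degrees (> 1) are divided by 360.
#' The band may wrap around the origin (`hue_min > hue_max`), e.g. a
#' red-centred band `c(0.95, 0.05)`.
#'
#' The defaults are placeholders that accept green through yellow-green
#' vegetation hues; they are configuration values, not claims about any
#' particular camera or field protocol, and should be tuned per campaign.
#'
#' @param hue_min,hue_max hue band endpoints in \[0, 1) (or degrees).
#' @param saturation_min minimum saturation in \[0, 1].
#' @param min_component_fraction floor on connected-component size relative
#'   to the largest component; components smaller than this fraction are
#'   always removed by [clean_mask()]. The default 1 keeps only the largest.
#' @return object of class `seg_config`.
#' @export
seg_config <- function(hue_min = 0.15, hue_max = 0.5,
                       saturation_min = 0.25,
                       min_component_fraction = 1) {
  to_unit_hue <- function(h) if (h > 1) h / 360 else h
  hue_min <- to_unit_hue(hue_min)
  hue_max <- to_unit_hue(hue_max)
  if (hue_min < 0 || hue_min >= 1 || hue_max < 0 || hue_max >= 1)
    stop("hue band endpoints must lie in [0, 1) (or be given in degrees)")
  if (saturation_min < 0 || saturation_min > 1)
    stop("saturation_min must lie in [0, 1]")
  if (min_component_fraction < 0 || min_component_fraction > 1)
    stop("min_component_fraction must lie in [0, 1]")
  structure(list(hue_min = hue_min, hue_max = hue_max,
                 saturation_min = saturation_min,
                 min_component_fraction = min_component_fraction),
            class = "seg_config")
}

#' Read a segmentation config from a JSON file
#'
#' Expects a JSON object with fields `hue_min`, `hue_max`, `saturation_min`
#' and optionally `min_component_fraction`.
#'
#' @param path path to a JSON file.
#' @return a [seg_config()] object.
#' @export
read_seg_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(seg_config, x[intersect(names(x),
    c("hue_min", "hue_max", "saturation_min", "min_component_fraction"))])
}

hue_in_band <- function(h, hue_min, hue_max) {
  if (hue_min <= hue_max) h >= hue_min & h <= hue_max
  else h >= hue_min | h <= hue_max   # band wraps around the hue origin
}

#' Threshold an RGB image into a foreground mask
#'
#' Converts the image to HSV and keeps pixels whose saturation is at least
#' `config$saturation_min` and whose hue lies inside the configured band.
#' No morphological cleaning is applied; see [clean_mask()] and
#' [fill_holes()].
#'
#' @param image numeric array `h x w x 3` with values in \[0, 1]
#'   (as returned by [read_rgb()]).
#' @param config a [seg_config()].
#' @return logical matrix `h x w`, `TRUE` for foreground.
#' @export
segment_canopy <- function(image, config = seg_config()) {
  if (!inherits(config, "seg_config")) stop("config must be a seg_config")
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("image must be an h x w x 3 RGB array")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h == 0 || w == 0) stop("empty image")
  rgb <- rbind(as.vector(image[, , 1]),
               as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  keep <- hsv["s", ] >= config$saturation_min &
    hue_in_band(hsv["h", ], config$hue_min, config$hue_max)
  matrix(keep, nrow = h, ncol = w)
}

# Run-length connected-component labelling. Foreground uses `connectivity`
# (8 by default); the complementary background labelling for hole filling
# uses 4. Runs of consecutive TRUE pixels within each row are merged across
# adjacent rows with a union-find over run indices; labels are then
# renumbered 1..n_components in order of each component's first run
# (row-major), which fixes the tie-break used by clean_mask().
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  runs_start <- vector("list", h); runs_end <- vector("list", h)
  n_runs <- 0L
  for (r in seq_len(h)) {
    row <- mask[r, ]
    if (!any(row)) { runs_start[[r]] <- integer(0); runs_end[[r]] <- integer(0); next }
    d <- diff(c(FALSE, row, FALSE))
    s <- which(d == 1L); e <- which(d == -1L) - 1L
    runs_start[[r]] <- s; runs_end[[r]] <- e
    n_runs <- n_runs + length(s)
  }
  if (n_runs == 0L) return(matrix(0L, h, w))
  parent <- seq_len(n_runs)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  # run ids, assigned row-major
  run_id <- vector("list", h)
  nxt <- 1L
  for (r in seq_len(h)) {
    k <- length(runs_start[[r]])
    run_id[[r]] <- if (k) seq.int(nxt, nxt + k - 1L) else integer(0)
    nxt <- nxt + k
  }
  slack <- if (connectivity == 8) 1L else 0L
  for (r in seq_len(h)[-1]) {
    sa <- runs_start[[r - 1]]; ea <- runs_end[[r - 1]]
    sb <- runs_start[[r]];     eb <- runs_end[[r]]
    if (!length(sa) || !length(sb)) next
    for (i in seq_along(sb)) {
      touching <- which(sa <= eb[i] + slack & ea >= sb[i] - slack)
      for (j in touching) union(run_id[[r]][i], run_id[[r - 1]][j])
    }
  }
  roots <- vapply(seq_len(n_runs), find, integer(1))
  labels <- match(roots, unique(roots))  # renumber by first appearance
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    s <- runs_start[[r]]
    if (!length(s)) next
    e <- runs_end[[r]]; ids <- labels[run_id[[r]]]
    for (i in seq_along(s)) out[r, s[i]:e[i]] <- ids[i]
  }
  out
}

#' Keep the largest connected foreground component
#'
#' Labels the mask with 8-connectivity and removes every component smaller
#' than the largest, emulating the standard plot-image cleanup that drops
#' soil debris and stray vegetation specks. When two components tie for the
#' largest size, the one whose first pixel appears earliest in row-major
#' order is kept (deterministic tie-break).
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param min_component_fraction components at least this fraction of the
#'   largest are also kept (default 1: largest only).
#' @return logical matrix of the same dimensions.
#' @export
clean_mask <- function(mask, min_component_fraction = 1) {
  if (!any(mask)) stop("mask has no foreground pixels")
  lab <- label_components(mask, connectivity = 8)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- max(sizes)
  if (min_component_fraction >= 1) {
    # largest only; ties resolve to the smallest label, i.e. the component
    # whose first pixel appears earliest in row-major order
    keep <- min(which(sizes == biggest))
  } else {
    keep <- which(sizes >= biggest * min_component_fraction)
  }
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Fill interior holes of a mask
#'
#' Background regions (4-connected) that do not touch the image border are
#' interior holes; they are converted to foreground. Concavities open to
#' the border are untouched.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  if (!any(mask)) stop("mask has no foreground pixels")
  bg <- label_components(!mask, connectivity = 4)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  mask | !(bg %in% c(0L, border_labels))
}

# offsets for Moore neighbourhood, clockwise in (row, col) image coordinates
# starting from west: W, NW, N, NE, E, SE, S, SW
.moore <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))

#' Trace the outer outline of a mask
#'
#' Moore-neighbour boundary tracing of the (single) foreground component.
#' The trace starts at the boundary pixel first encountered in row-major
#' scan and follows the outer boundary; in the returned y-up coordinate
#' frame the loop runs counter-clockwise. Consecutive points are
#' 8-neighbours and the last point connects back to the first.
#'
#' Coordinates: a pixel at image row `r`, column `c` is reported as
#' `x = c`, `y = nrow(mask) - r + 1`, i.e. the image is flipped so y grows
#' upward and standard planar geometry (positive shoelace area for
#' counter-clockwise loops) applies.
#'
#' @param mask logical matrix; should be cleaned and hole-filled.
#' @return a `canopy_contour`: numeric matrix with columns `x`, `y`.
#' @export
trace_outline <- function(mask) {
  if (!any(mask)) stop("mask has no foreground pixels")
  if (sum(mask) < 3) stop("degenerate blob: fewer than 3 foreground pixels")
  h <- nrow(mask); w <- ncol(mask)
  # pad so neighbour lookups never leave the matrix
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[2:(h + 1L), 2:(w + 1L)] <- mask
  # first foreground pixel in row-major scan of the original mask
  hit <- which(t(mask), arr.ind = TRUE)  # t(): row-major order
  r0 <- hit[1, 2] + 1L; c0 <- hit[1, 1] + 1L
  pts <- matrix(0L, nrow = 4L * sum(mask) + 8L, ncol = 2L)
  n <- 1L
  pts[1L, ] <- c(r0, c0)
  # entered the start pixel coming from the west (scan direction); begin
  # searching the Moore neighbourhood clockwise from the backtrack cell
  back <- 1L  # index into .moore: W
  r <- r0; c <- c0
  second <- NULL
  repeat {
    found <- FALSE
    for (k in seq_len(8L)) {
      idx <- ((back - 1L + k - 1L) %% 8L) + 1L
      nr <- r + .moore[idx, 1L]; nc <- c + .moore[idx, 2L]
      if (m[nr, nc]) {
        # new backtrack: the ring cell examined just before the hit
        # (consecutive Moore-ring cells are 8-adjacent, so it neighbours
        # the new pixel too); express it relative to the new pixel
        prev <- ((idx - 2L) %% 8L) + 1L
        pr <- (r + .moore[prev, 1L]) - nr
        pc <- (c + .moore[prev, 2L]) - nc
        back <- which(.moore[, 1L] == pr & .moore[, 2L] == pc)
        r <- nr; c <- nc
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (cannot happen: >=3 px, 8-connected)
    if (is.null(second)) second <- c(r, c)
    else if (r == r0 && c == c0) {
      # Jacob's stopping criterion: back at start about to rewalk the loop
      break
    }
    n <- n + 1L
    if (n > nrow(pts)) pts <- rbind(pts, pts)  # defensive growth
    pts[n, ] <- c(r, c)
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  # drop the duplicated start if the trace closed on it
  if (n > 1L && all(pts[n, ] == pts[1L, ])) pts <- pts[-n, , drop = FALSE]
  if (nrow(pts) < 3L) stop("degenerate blob: boundary has fewer than 3 pixels")
  # the Moore walk above runs clockwise once the rows are flipped to y-up;
  # reverse the loop (keeping the start point first) so the contour is CCW
  pts <- pts[c(1L, rev(seq_len(nrow(pts))[-1L])), , drop = FALSE]
  xy <- cbind(x = pts[, 2L] - 1L, y = h - (pts[, 1L] - 1L) + 1L)
  as_contour(xy)
}

#' Construct a contour object
#'
#' A contour is an ordered closed sequence of at least 3 planar points;
#' closure is implicit (the last point connects to the first). Immediate
#' duplicate points are rejected.
#'
#' @param xy two-column numeric matrix (x, y) or data.frame.
#' @return matrix of class `canopy_contour`.
#' @export
as_contour <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stop("contour must have two columns (x, y)")
  storage.mode(xy) <- "double"
  if (nrow(xy) >= 2 && all(xy[nrow(xy), ] == xy[1, ]))
    xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 3) stop("contour needs at least 3 points")
  closing <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  if (any(rowSums(abs(closing - xy)) == 0))
    stop("contour contains immediately repeated points")
  colnames(xy) <- c("x", "y")
  class(xy) <- c("canopy_contour", class(xy))
  xy
}

#' @export
print.canopy_contour <- function(x, ...) {
  cat(sprintf("canopy_contour: %d points, perimeter %.1f\n",
              nrow(x), sum(sqrt(rowSums((rbind(x[-1, , drop = FALSE],
                x[1, , drop = FALSE]) - x)^2)))))
  invisible(x)
}

#' Read an RGB raster image
#'
#' Supports 8/16-bit PNG and JPEG (values rescaled to \[0, 1]). Grayscale
#' images are replicated to 3 channels; an alpha channel is dropped.
#'
#' @param path image path; format chosen by file extension.
#' @return numeric array `h x w x 3` in \[0, 1].
#' @export
read_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: '", ext, "' (PNG and JPEG are supported)"))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a binary mask as a PNG (0/255)
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 PNG mask back as a logical matrix
#' @param path PNG path.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write / read a contour as CSV
#'
#' Columns `point_index`, `x`, `y`; full double precision is preserved.
#' @param contour a `canopy_contour`.
#' @param path CSV path.
#' @export
write_contour_csv <- function(contour, path) {
  df <- data.frame(point_index = seq_len(nrow(contour)),
                   x = sprintf("%.17g", contour[, 1]),
                   y = sprintf("%.17g", contour[, 2]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric", "numeric"))
  as_contour(as.matrix(df[, c("x", "y")]))
}
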