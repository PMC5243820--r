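# analytic shape builders (y-up planar coordinates) and independent oracles

circle_pts <- function(R = 30, n = 256, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + R * cos(th), center[2] + R * sin(th))
}

ellipse_pts <- function(a = 40, b = 20, n = 256, center = c(0, 0), rot = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(center[1] + x * cos(rot) - y * sin(rot),
        center[2] + x * sin(rot) + y * cos(rot))
}

star_pts <- function(R = 40, lobes = 7, amp = 0.25, n = 256,
                     center = c(0, 0), ecc = 1.3) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- R * (1 + amp * cos(lobes * th))
  cbind(center[1] + ecc * r * cos(th), center[2] + r * sin(th))
}

# axis-aligned filled square mask, side s, top-left corner (r0, c0)
square_mask <- function(dim = c(20, 20), side = 10, r0 = 6, c0 = 6) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- TRUE
  m
}

disk_mask <- function(dim = c(80, 80), radius = 30,
                      center = c(40, 40)) {
  outer(seq_len(dim[1]), seq_len(dim[2]),
        function(r, c) (r - center[1])^2 + (c - center[2])^2 <= radius^2)
}

# independent brute-force oracle for the harmonic sums: plain double loop,
# no shared code with efourier()
efd_bruteforce <- function(xy, N) {
  s <- nrow(xy)
  dx <- dy <- dt <- numeric(s)
  for (p in 1:s) {
    q <- if (p == s) 1 else p + 1
    dx[p] <- xy[q, 1] - xy[p, 1]
    dy[p] <- xy[q, 2] - xy[p, 2]
    dt[p] <- sqrt(dx[p]^2 + dy[p]^2)
  }
  t <- cumsum(dt); T <- t[s]
  coef <- matrix(0, N, 4)
  for (n in 1:N) {
    an <- bn <- cn <- dn <- 0
    for (p in 1:s) {
      t1 <- t[p]; t0 <- if (p == 1) 0 else t[p - 1]
      an <- an + dx[p] / dt[p] * (cos(2 * n * pi * t1 / T) - cos(2 * n * pi * t0 / T))
      bn <- bn + dx[p] / dt[p] * (sin(2 * n * pi * t1 / T) - sin(2 * n * pi * t0 / T))
      cn <- cn + dy[p] / dt[p] * (cos(2 * n * pi * t1 / T) - cos(2 * n * pi * t0 / T))
      dn <- dn + dy[p] / dt[p] * (sin(2 * n * pi * t1 / T) - sin(2 * n * pi * t0 / T))
    }
    coef[n, ] <- T / (2 * n^2 * pi^2) * c(an, bn, cn, dn)
  }
  coef
}

# shoelace area oracle written independently (summed triangle cross terms)
area_bruteforce <- function(xy) {
  s <- nrow(xy); acc <- 0
  for (p in 1:s) {
    q <- if (p == s) 1 else p + 1
    acc <- acc + xy[p, 1] * xy[q, 2] - xy[q, 1] * xy[p, 2]
  }
  abs(acc) / 2
}

# 20-shape complexity-gradient suite run through the actual image pipeline
# (segmentation -> clean -> fill -> trace); built once and memoized
acceptance_contours <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      d <- file.path(tempdir(), "acceptance_suite")
      if (!file.exists(file.path(d, "manifest.csv")))
        simulate_fixture_suite(d, n = 20, seed = 7)
      manifest <- utils::read.csv(file.path(d, "manifest.csv"))
      cts <- lapply(file.path(d, manifest$file), function(f)
        trace_outline(fill_holes(clean_mask(segment_canopy(read_rgb(f))))))
      names(cts) <- manifest$id
      memo <<- list(dir = d, manifest = manifest, contours = cts)
    }
    memo
  }
})

# suite of fixture contours reused by several test files (built once)
fixture_suite_dir <- local({
  dir <- NULL
  function(n = 12, seed = 7) {
    if (is.null(dir)) {
      d <- file.path(tempdir(), sprintf("suite_%d_%d", n, seed))
      if (!file.exists(file.path(d, "manifest.csv")))
        simulate_fixture_suite(d, n = n, seed = seed)
      dir <<- d
    }
    dir
  }
})
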