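test_that("chain_code computes Freeman lengths and closes the loop", {
  # 2x2 pixel square traced as its 4 boundary pixels
  sq <- as_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  ch <- chain_code(sq)
  expect_equal(ch$T, 4)
  expect_equal(ch$dt, rep(1, 4))
  expect_equal(sum(ch$dx), 0)
  expect_equal(sum(ch$dy), 0)

  # diagonal step has length sqrt(2)
  tri <- as_contour(cbind(c(0, 1, 1), c(0, 1, 0)))
  expect_equal(chain_code(tri)$dt[1], sqrt(2))

  # closure holds for arbitrary analytic contours
  for (shape in list(circle_pts(), star_pts(), ellipse_pts())) {
    ch <- chain_code(as_contour(shape))
    expect_equal(sum(ch$dx), 0, tolerance = 1e-12)
    expect_equal(sum(ch$dy), 0, tolerance = 1e-12)
    expect_equal(ch$T, ch$t[ch$s])
  }

  # non-adjacent steps are rejected when a pixel chain is asserted
  expect_error(chain_code(cbind(c(0, 5, 5), c(0, 0, 5)), pixel_chain = TRUE),
               "8-neighbour")
  expect_error(as_contour(cbind(0:1, 0:1)), "3 points")
})

test_that("efourier matches the independent brute-force summation", {
  shapes <- list(square = cbind(c(0, 4, 4, 0), c(0, 0, 3, 3)),
                 star = star_pts(n = 50),
                 blob = cbind(c(0, 2, 5, 6, 4, 1), c(0, -2, -1, 2, 4, 3)))
  for (xy in shapes) {
    e <- efourier(as_contour(xy), 8)
    expect_equal(unname(e$coef), efd_bruteforce(xy, 8), tolerance = 1e-12)
  }
})

test_that("uniformly sampled circle reduces to its first harmonic", {
  R <- 30
  e <- efourier(as_contour(circle_pts(R = R, n = 256, center = c(5, -3))), 5)
  expect_equal(unname(e$coef[1, "a"]), R, tolerance = 1e-3)
  expect_equal(abs(unname(e$coef[1, "d"])), R, tolerance = 1e-3)
  expect_lt(abs(e$coef[1, "b"]) + abs(e$coef[1, "c"]), 1e-3 * R)
  expect_lt(max(abs(e$coef[2:5, ])), 1e-3 * R)
  expect_equal(e$A0, 5, tolerance = 1e-6)
  expect_equal(e$C0, -3, tolerance = 1e-6)
})

test_that("translation shifts only the DC terms", {
  xy <- star_pts(n = 64)
  e1 <- efourier(as_contour(xy), 6)
  e2 <- efourier(as_contour(xy + matrix(c(13, -7), 64, 2, byrow = TRUE)), 6)
  expect_equal(e1$coef, e2$coef, tolerance = 1e-12)
  expect_equal(e2$A0 - e1$A0, 13, tolerance = 1e-9)
  expect_equal(e2$C0 - e1$C0, -7, tolerance = 1e-9)
})

test_that("efd_reconstruct evaluates the truncated series", {
  # pure first-harmonic ellipse: closed form at quarter arcs
  e <- structure(list(A0 = 0, C0 = 0,
                      coef = matrix(c(2, 0, 0, 1), 1, 4,
                                    dimnames = list(NULL, c("a", "b", "c", "d"))),
                      N = 1L, T = 1, start = c(2, 0)), class = "efd")
  pts <- efd_reconstruct(e, N = 1, t = c(0, 0.25, 0.5))
  expect_equal(unclass(pts), cbind(x = c(2, 0, -2), y = c(0, 1, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # full-harmonic reconstruction of a digitized polygon converges
  ct <- trace_outline(disk_mask(radius = 25))
  ch <- chain_code(ct)
  e <- efourier(ch, 120)
  rec <- canopyefd:::efd_evaluate(e, 120, ch$t)
  orig <- rbind(unclass(ct)[-1, ], unclass(ct)[1, ])
  expect_lt(max(sqrt(rowSums((orig - rec)^2))), 1)

  # periodicity: t = 0 and t = T coincide
  p0 <- canopyefd:::efd_evaluate(e, 50, 0)
  pT <- canopyefd:::efd_evaluate(e, 50, e$T)
  expect_equal(p0, pT, tolerance = 1e-9)

  expect_error(efd_reconstruct(e, N = 0), "N must be")
  expect_error(efd_reconstruct(e, N = 200), "stored harmonics")
})

test_that("efd_error is the max pointwise deviation over 2L, in percent", {
  # hand-built case: reconstruction differs by a known displacement.
  # A unit-speed circle of radius 25 has L = 25; displacing one
  # reconstructed point by 0.5 px must give E = 0.5 / 50 * 100 = 1%.
  ct <- as_contour(circle_pts(R = 25, n = 128))
  ch <- chain_code(ct)
  e <- efourier(ch, 60)
  expect_equal(canopyefd:::first_harmonic_frame(e)$L, 25, tolerance = 1e-3)
  # E with full harmonics on the exact sample positions is ~0
  expect_lt(efd_error(ch, e, 60), 0.1)
  # the analytic displacement arithmetic
  expect_equal(0.5 / (2 * 25) * 100, 1.0)

  # convergence: error non-increasing in N on fixtures
  for (xy in list(star_pts(n = 300), ellipse_pts(n = 300))) {
    ch <- chain_code(as_contour(xy))
    e <- efourier(ch, 500)
    errs <- vapply(c(10, 50, 100, 500), function(n) efd_error(ch, e, n),
                   numeric(1))
    expect_true(all(diff(errs) <= 1e-9))
  }
})

test_that("find_most_complex ranks by 10-harmonic residual", {
  circ <- as_contour(circle_pts(R = 40, n = 256))
  star <- as_contour(star_pts(R = 40, lobes = 12, amp = 0.25, n = 256, ecc = 1))
  expect_equal(find_most_complex(list(circ, star)), 2)
  expect_equal(find_most_complex(list(star, circ)), 1)
  expect_equal(find_most_complex(list(circ)), 1)
  expect_equal(find_most_complex(list(star, star)), 1)  # tie -> lowest index
  expect_error(find_most_complex(list()), "empty")
})

test_that("select_n_harmonics returns the first sweep value under threshold", {
  circ <- as_contour(circle_pts(R = 40, n = 512))
  n_circ <- select_n_harmonics(circ)
  expect_equal(as.integer(n_circ), 10)
  expect_true(attr(n_circ, "converged"))

  star <- as_contour(star_pts(R = 40, lobes = 12, amp = 0.3, n = 1024))
  n_star <- select_n_harmonics(star)
  expect_gt(as.integer(n_star), as.integer(n_circ))

  # unreachable threshold: sweep max + non-convergence flag
  ct <- trace_outline(disk_mask(radius = 20))
  expect_warning(
    n0 <- select_n_harmonics(ct, threshold_pct = 0, sweep = seq(10, 100, 10)),
    "not reached")
  expect_equal(as.integer(n0), 100)
  expect_false(attr(n0, "converged"))

  expect_error(select_n_harmonics(circ, sweep = integer(0)), "empty sweep")
})

test_that("standardization pins the first harmonic to (1, 0, 0)", {
  shapes <- list(star_pts(), ellipse_pts(rot = 0.7),
                 unclass(trace_outline(disk_mask(radius = 18))))
  for (xy in shapes) {
    s <- efd_standardize(efourier(as_contour(xy), 10))
    expect_equal(s$coef[1, "a"], 1, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(s$coef[1, "b"], 0, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(s$coef[1, "c"], 0, tolerance = 1e-9, ignore_attr = TRUE)
    expect_gt(s$L, 0)
  }
  degen <- structure(list(A0 = 0, C0 = 0,
                          coef = matrix(0, 2, 4,
                                        dimnames = list(NULL, c("a", "b", "c", "d"))),
                          N = 2L, T = 1, start = c(0, 0)), class = "efd")
  expect_error(efd_standardize(degen), "degenerate")
})

test_that("standardized descriptors are invariant to similarity + start shift", {
  xy <- star_pts(R = 40, lobes = 7, amp = 0.25, n = 256, ecc = 1.3)
  rot <- 37 * pi / 180
  Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  xy2 <- 2.5 * xy %*% t(Rm) + matrix(c(120, -45), 256, 2, byrow = TRUE)
  xy2 <- xy2[c(41:256, 1:40), ]           # start point shifted by 40 steps
  s1 <- efd_standardize(efourier(as_contour(xy), 12))
  s2 <- efd_standardize(efourier(as_contour(xy2), 12))
  expect_lt(max(abs(s1$coef - s2$coef)), 1e-3)
  expect_equal(s2$L / s1$L, 2.5, tolerance = 1e-6)
})

test_that("standardization is idempotent on re-embedded coefficients", {
  s1 <- efd_standardize(efourier(as_contour(star_pts(n = 128)), 8))
  s2 <- efd_standardize(efd_from_standardized(s1))
  expect_equal(s1$coef, s2$coef, tolerance = 1e-9)
  expect_equal(s2$L, 1, tolerance = 1e-9)
})

test_that("descriptor records serialize compactly and losslessly", {
  e <- efourier(as_contour(star_pts(n = 400)), 500)
  d <- withr::local_tempdir()
  f <- file.path(d, "rec.bin")
  write_efd_bin(e, f)
  back <- read_efd_bin(f)
  expect_equal(back$coef, e$coef)
  expect_equal(back$A0, e$A0)
  expect_equal(file.size(f), 4 + 8 * (2 + 4 * 500))
})
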