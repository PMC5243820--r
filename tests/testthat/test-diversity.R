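test_that("efd_pca drops constant columns and decomposes exactly", {
  set.seed(1)
  # rank-1 family: one base shape morphed along a single direction
  base <- efd_standardize(efourier(as_contour(star_pts(n = 128)), 6))
  mats <- lapply(seq(-1, 1, length.out = 15), function(s) {
    st <- base
    st$coef[3, "a"] <- st$coef[3, "a"] + s * 0.1
    st
  })
  names(mats) <- paste0("c", 1:15)
  m <- std_coef_matrix(mats)
  p <- efd_pca(m)
  expect_true(all(c("a_1", "b_1", "c_1") %in% p$dropped_columns))
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_gt(p$variance_fraction[1], 0.99)

  # full-rank projection reconstructs the centred matrix
  set.seed(2)
  x <- matrix(rnorm(60), 10, 6)
  p2 <- efd_pca(x)
  centred <- sweep(x, 2, p2$center)
  expect_equal(p2$scores %*% t(p2$loadings), centred,
               tolerance = 1e-8, ignore_attr = TRUE)
  # orthonormal loadings
  expect_equal(t(p2$loadings) %*% p2$loadings, diag(ncol(x)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # row order only permutes scores (up to identical components)
  ord <- sample(nrow(x))
  p3 <- efd_pca(x[ord, ])
  expect_equal(abs(p3$scores), abs(p2$scores[ord, ]), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(efd_pca(x[1, , drop = FALSE]), "at least 2")
  x[1, 1] <- NA
  expect_error(efd_pca(x), "non-finite")
})

test_that("hull_spread measures per-group convex hull areas", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  scores <- rbind(sq, cbind(seq(0, 1, length.out = 3), 0.5), c(5, 5))
  labels <- c(rep("square", 4), rep("line", 3), "single")
  out <- hull_spread(scores, labels)
  expect_equal(out$hull_area[out$group == "square"], 1)
  expect_false(out$degenerate[out$group == "square"])
  expect_equal(out$hull_area[out$group == "line"], 0)
  expect_true(out$degenerate[out$group == "line"])
  expect_true(out$degenerate[out$group == "single"])

  # hull monotonicity: subgroup area <= supergroup area
  set.seed(3)
  pts <- matrix(rnorm(60), 30, 2)
  sub <- pts[1:12, ]
  a_all <- hull_spread(pts, rep("all", 30))$hull_area
  a_sub <- hull_spread(sub, rep("sub", 12))$hull_area
  expect_lte(a_sub, a_all)

  expect_error(hull_spread(matrix(0, 0, 2), character(0)), "empty")
})

test_that("group_cv computes sd/mean per group and flags undefined cells", {
  tab <- data.frame(id = 1:7, aspect_ratio = c(1, 2, 3, 4, 4, 4, 9))
  labels <- c("A", "A", "A", "B", "B", "B", "C")
  out <- group_cv(tab, labels, trait_cols = "aspect_ratio")
  expect_equal(out$cv[out$group == "A"], 0.5)   # mean 2, sd 1
  expect_equal(out$cv[out$group == "B"], 0)     # constant group
  expect_true(out$undefined[out$group == "C"])  # n = 1
  # zero-mean cell flagged, not thrown
  tab0 <- data.frame(id = 1:2, aspect_ratio = c(-1, 1))
  out0 <- group_cv(tab0, c("Z", "Z"), trait_cols = "aspect_ratio")
  expect_true(out0$undefined)
  expect_error(group_cv(tab, labels, trait_cols = "nope"), "not found")
})

test_that("flag_outliers applies Tukey fences per group", {
  set.seed(9)
  x <- rnorm(200)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  spike <- median(x) + 10 * (q[2] - q[1])
  tab <- data.frame(id = paste0("p", 1:201), trait1 = c(x, spike))
  out <- flag_outliers(tab, rep("G", 201), trait_cols = "trait1")
  expect_true(out$flagged[out$id == "p201"])
  # the spike is the only value beyond its own fence by construction check:
  fences <- quantile(c(x, spike), c(0.25, 0.75), names = FALSE)
  iqr <- fences[2] - fences[1]
  expected <- c(x, spike) < fences[1] - 1.5 * iqr | c(x, spike) > fences[2] + 1.5 * iqr
  expect_equal(out$flagged, expected)

  # all-equal group yields no flags; small groups yield no flags
  tab2 <- data.frame(id = 1:6, trait1 = c(rep(5, 4), 1, 100))
  out2 <- flag_outliers(tab2, c(rep("E", 4), "S", "S"), trait_cols = "trait1")
  expect_false(any(out2$flagged))

  # replicate-consistency counting per genotype
  tab3 <- data.frame(id = 1:8, trait1 = c(0.1, 0, 0.05, 50, -0.1, 0.02, 0.07, -0.02))
  out3 <- flag_outliers(tab3, rep("G", 8),
                        genotypes = c("g1", "g1", "g1", "g1",
                                      "g2", "g2", "g2", "g2"),
                        trait_cols = "trait1")
  g1 <- out3[out3$genotype == "g1", ]
  expect_equal(unique(g1$consistency_count), 1)
  expect_equal(unique(g1$n_replicates), 4)
  expect_equal(sum(out3$flagged), 1)
})

test_that("rcbd_anova reproduces the hand-worked 2x2 decomposition", {
  toy <- data.frame(genotype = c("g1", "g1", "g2", "g2"),
                    block = c("b1", "b2", "b1", "b2"),
                    value = c(10, 12, 14, 16))
  a <- rcbd_anova(toy)
  expect_equal(a$ss_genotype, 16)
  expect_equal(a$ss_block, 4)
  expect_equal(a$ss_error, 0, tolerance = 1e-10)
  expect_equal(a$k, 2)

  # ANOVA identity on simulated data + agreement with stats::aov
  sim <- simulate_rcbd(n_genotypes = 25, k = 4, seed = 11)
  a2 <- rcbd_anova(sim[c("genotype", "block", "value")])
  expect_equal(a2$ss_total, a2$ss_genotype + a2$ss_block + a2$ss_error,
               tolerance = 1e-8)
  fit <- stats::aov(value ~ genotype + block, data = sim)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  expect_equal(a2$ms_genotype, ms[1], tolerance = 1e-10)
  expect_equal(a2$ms_block, ms[2], tolerance = 1e-10)
  expect_equal(a2$ms_error, ms[3], tolerance = 1e-10)

  # MSG < MSE: genotypic variance truncates to zero
  flat <- data.frame(genotype = rep(c("g1", "g2"), each = 2),
                     block = rep(c("b1", "b2"), 2),
                     value = c(1, 2, 2, 1))
  expect_equal(rcbd_anova(flat)$sigma2_g, 0)

  expect_error(rcbd_anova(toy[toy$genotype == "g1", ]), "at least 2")
  expect_error(rcbd_anova(rbind(toy, toy[1, ])), "duplicated")
})

test_that("unbalanced tables restrict to the modal replication count", {
  sim <- simulate_rcbd(n_genotypes = 30, k = 3, seed = 5)
  unb <- sim[!(sim$genotype %in% c("G0001", "G0002") & sim$block == "B3"), ]
  expect_message(a <- rcbd_anova(unb[c("genotype", "block", "value")]),
                 "dropped for balance")
  expect_equal(a$n_genotypes, 28)
  expect_equal(a$k, 3)
  expect_setequal(a$dropped_genotypes, c("G0001", "G0002"))
})

test_that("heritability follows the entry-mean formula and is monotone", {
  expect_equal(heritability(1, 1, k = 4), 0.8)
  expect_equal(heritability(0, 1, k = 4), 0)
  expect_warning(h <- heritability(0, 0, k = 3), "undefined")
  expect_true(is.na(h))
  # monotone in k and in sigma2_g
  ks <- vapply(1:6, function(k) heritability(1, 1, k), numeric(1))
  expect_true(all(diff(ks) > 0))
  gs <- vapply(seq(0.1, 3, 0.5), function(g) heritability(g, 1, 2), numeric(1))
  expect_true(all(diff(gs) > 0))
})

test_that("herit_report recovers simulated variance components across a grid", {
  # median bias of H2-hat over a small grid (reduced Monte Carlo for speed)
  grid <- expand.grid(ratio = c(0.25, 1, 4), k = c(2, 4))
  for (i in seq_len(nrow(grid))) {
    sg <- grid$ratio[i]; k <- grid$k[i]
    h_true <- sg / (sg + 1 / k)
    h_hat <- vapply(1:30, function(r) {
      sim <- simulate_rcbd(n_genotypes = 300, k = k, sigma2_g = sg,
                           sigma2_e = 1, seed = 1000 * i + r)
      suppressWarnings(heritability(rcbd_anova(sim[c("genotype", "block", "value")])))
    }, numeric(1))
    expect_lt(abs(median(h_hat) - h_true), 0.05)
  }
  # report layout
  sim <- simulate_rcbd(n_genotypes = 50, k = 3, trait = "roundness", seed = 2)
  rep <- herit_report(sim)
  expect_equal(rep$trait, "roundness")
  expect_true(rep$H2 >= 0 && rep$H2 <= 1)
  expect_true(rep$significance %in% c("", "*", "***"))
})
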