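#' PCA of standardized descriptor coefficients
#'
#' Mean-centred principal component analysis (no unit-variance scaling:
#' after standardization all coefficients share a common dimensionless
#' scale) of a canopies-by-coefficients matrix. Columns that are constant
#' across canopies - in particular the standardized a1*, b1*, c1* - carry
#' no information and are dropped before the decomposition.
#'
#' @param std_matrix numeric matrix, one row per canopy, columns the
#'   standardized coefficients (e.g. from [std_coef_matrix()]).
#' @param var_tol columns with variance below this are treated as constant.
#' @return list with `scores`, `loadings`, `variance_fraction`,
#'   `cumulative_fraction`, `center`, `dropped_columns`.
#' @export
efd_pca <- function(std_matrix, var_tol = 1e-12) {
  std_matrix <- as.matrix(std_matrix)
  if (nrow(std_matrix) < 2) stop("need at least 2 canopies for PCA")
  if (any(!is.finite(std_matrix))) stop("non-finite entries in coefficient matrix")
  v <- apply(std_matrix, 2, stats::var)
  dropped <- which(v <= var_tol)
  x <- if (length(dropped)) std_matrix[, -dropped, drop = FALSE] else std_matrix
  if (ncol(x) == 0) stop("all coefficient columns are constant")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation,
       variance_fraction = vf, cumulative_fraction = cumsum(vf),
       center = p$center, dropped_columns = colnames(std_matrix)[dropped])
}

#' Stack standardized descriptor sets into a matrix
#'
#' @param stds list of [efd_standardize()] results sharing the same N.
#' @param ids row names (default names of the list).
#' @return matrix, one row per canopy, columns `a_1, b_1, c_1, d_1, a_2, ...`.
#' @export
std_coef_matrix <- function(stds, ids = names(stds)) {
  Ns <- vapply(stds, function(s) s$N, integer(1))
  if (length(unique(Ns)) != 1) stop("all descriptor sets must share N")
  m <- do.call(rbind, lapply(stds, function(s) as.vector(t(s$coef))))
  colnames(m) <- as.vector(t(outer(seq_len(Ns[1]), c("a", "b", "c", "d"),
                                   function(n, l) paste0(l, "_", n))))
  rownames(m) <- ids
  m
}

#' Convex-hull area of each group in a score plane
#'
#' Measures how much of the (PC1, PC2) plane each diversity group covers.
#' Groups with fewer than 3 points, or collinear groups, get area 0 and a
#' degenerate flag.
#'
#' @param scores two-column matrix of coordinates (e.g. PC1/PC2 scores).
#' @param labels group label per row.
#' @return data.frame: `group`, `n`, `hull_area`, `degenerate`.
#' @export
hull_spread <- function(scores, labels) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  if (nrow(scores) == 0) stop("empty score set")
  if (length(labels) != nrow(scores)) stop("labels do not match scores")
  groups <- unique(as.character(labels))
  out <- lapply(groups, function(g) {
    pts <- scores[labels == g, , drop = FALSE]
    area <- 0; degen <- TRUE
    if (nrow(pts) >= 3) {
      hull <- pts[grDevices::chull(pts), , drop = FALSE]
      if (nrow(hull) >= 3) {
        area <- abs(polygon_signed_area(hull))
        degen <- area == 0
      }
    }
    data.frame(group = g, n = nrow(pts), hull_area = area, degenerate = degen)
  })
  do.call(rbind, out)
}

#' Per-group, per-trait coefficient of variation
#'
#' CV = sample standard deviation / mean within each group x trait cell.
#' Groups of size 1 (CV undefined) and zero-mean cells are flagged rather
#' than raising an error.
#'
#' @param traits data.frame with an `id` column and one column per trait.
#' @param labels group label per row of `traits`.
#' @param trait_cols trait columns to summarize.
#' @return data.frame: `group`, `trait`, `n`, `mean`, `sd`, `cv`,
#'   `undefined`.
#' @export
group_cv <- function(traits, labels,
                     trait_cols = c("aspect_ratio", "roundness",
                                    "circularity", "solidity")) {
  if (length(labels) != nrow(traits)) stop("labels do not match trait rows")
  missing_cols <- setdiff(trait_cols, names(traits))
  if (length(missing_cols))
    stop("trait columns not found: ", paste(missing_cols, collapse = ", "))
  groups <- unique(as.character(labels))
  rows <- list()
  for (g in groups) for (v in trait_cols) {
    x <- traits[[v]][labels == g]
    n <- length(x); m <- mean(x)
    s <- if (n >= 2) stats::sd(x) else NA_real_
    undef <- n < 2 || m == 0
    rows[[length(rows) + 1]] <- data.frame(
      group = g, trait = v, n = n, mean = m, sd = s,
      cv = if (undef) NA_real_ else s / m, undefined = undef)
  }
  do.call(rbind, rows)
}

#' Flag per-group trait outliers by Tukey fences
#'
#' A canopy is flagged for a trait when its value falls outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of its group (the whisker convention of
#' standard boxplots). When a genotype map is supplied, a per-genotype
#' replicate-consistency count is attached: in how many of its replicates
#' the same genotype was flagged for the same trait.
#'
#' @param traits data.frame with `id` and trait columns.
#' @param labels group label per row.
#' @param genotypes optional genotype label per row (for consistency
#'   counts).
#' @param trait_cols trait columns to scan.
#' @param k fence multiplier (1.5 = standard whiskers).
#' @param min_group minimum group size for meaningful fences; smaller
#'   groups produce no flags.
#' @return data.frame: `id`, `trait`, `group`, `value`, `flagged`, and
#'   (with genotypes) `genotype`, `n_replicates`, `consistency_count`.
#' @export
flag_outliers <- function(traits, labels, genotypes = NULL,
                          trait_cols = c("aspect_ratio", "roundness",
                                         "circularity", "solidity"),
                          k = 1.5, min_group = 4) {
  if (length(labels) != nrow(traits)) stop("labels do not match trait rows")
  rows <- list()
  for (g in unique(as.character(labels))) {
    sel <- which(labels == g)
    for (v in trait_cols) {
      x <- traits[[v]][sel]
      flagged <- rep(FALSE, length(x))
      if (length(x) >= min_group) {
        q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
        iqr <- q[2] - q[1]
        flagged <- x < q[1] - k * iqr | x > q[2] + k * iqr
      }
      rows[[length(rows) + 1]] <- data.frame(
        id = traits$id[sel], trait = v, group = g, value = x,
        flagged = flagged)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(genotypes)) {
    if (length(genotypes) != nrow(traits)) stop("genotypes do not match rows")
    gmap <- data.frame(id = traits$id, genotype = genotypes)
    out <- merge(out, gmap, by = "id", sort = FALSE)
    key <- paste(out$genotype, out$trait)
    out$n_replicates <- stats::ave(out$flagged, key, FUN = length)
    out$consistency_count <- stats::ave(out$flagged, key, FUN = sum)
  }
  rownames(out) <- NULL
  out
}

#' Two-way random-effects ANOVA for a randomized complete block design
#'
#' Fits y_ik = mu + g_i + b_k + e_ik by the classical balanced two-way
#' decomposition and derives variance components by the method of moments
#' on the expected mean squares: sigma2_e = MSE, sigma2_g = max(0,
#' (MSG - MSE) / k). Genotypes not observed in the modal number of blocks
#' are dropped (with a message) so the analysed table is balanced; `k` is
#' that modal replication count.
#'
#' @param records data.frame with columns `genotype`, `block`, `value`
#'   (one trait), or `genotype`, `block`, `trait`, `value` for several
#'   traits (then a list of results is returned, one per trait).
#' @return object of class `rcbd_anova`: list with `ms_genotype`,
#'   `ms_block`, `ms_error`, `F_G`, `p_value`, `sigma2_g`, `sigma2_e`,
#'   `k`, `df_genotype`, `df_error`, `n_genotypes`, sums of squares, and
#'   `dropped_genotypes`.
#' @export
rcbd_anova <- function(records) {
  need <- c("genotype", "block", "value")
  if ("trait" %in% names(records) && length(unique(records$trait)) > 1) {
    return(lapply(split(records, records$trait),
                  function(d) rcbd_anova(d[setdiff(names(d), "trait")])))
  }
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(records[c("genotype", "block")]))
    stop("duplicated (genotype, block) observations")
  reps <- table(as.character(records$genotype))
  k_modal <- as.integer(names(sort(table(reps), decreasing = TRUE))[1])
  keep_g <- names(reps)[reps == k_modal]
  dropped <- setdiff(names(reps), keep_g)
  if (length(dropped))
    message(length(dropped), " genotype(s) without the modal replication (",
            k_modal, ") dropped for balance")
  d <- records[as.character(records$genotype) %in% keep_g, ]
  # all retained genotypes must share the same block set for a clean RCBD
  blocks <- sort(unique(as.character(d$block)))
  bad <- vapply(split(as.character(d$block), as.character(d$genotype)),
                function(b) !identical(sort(b), blocks), logical(1))
  if (any(bad))
    stop("retained genotypes are not observed in a common block set")
  g <- length(keep_g); k <- length(blocks)
  if (g < 2 || k < 2) stop("need at least 2 genotypes and 2 blocks")
  y <- d$value
  grand <- mean(y)
  gm <- tapply(y, as.character(d$genotype), mean)
  bm <- tapply(y, as.character(d$block), mean)
  ss_g <- k * sum((gm - grand)^2)
  ss_b <- g * sum((bm - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_e <- ss_tot - ss_g - ss_b
  df_g <- g - 1; df_b <- k - 1; df_e <- (g - 1) * (k - 1)
  msg <- ss_g / df_g; msb <- ss_b / df_b; mse <- ss_e / df_e
  F_G <- msg / mse
  structure(list(
    ms_genotype = msg, ms_block = msb, ms_error = mse,
    ss_genotype = ss_g, ss_block = ss_b, ss_error = ss_e, ss_total = ss_tot,
    F_G = F_G, p_value = stats::pf(F_G, df_g, df_e, lower.tail = FALSE),
    sigma2_g = max(0, (msg - mse) / k), sigma2_e = mse,
    k = k, df_genotype = df_g, df_block = df_b, df_error = df_e,
    n_genotypes = g, dropped_genotypes = dropped),
    class = "rcbd_anova")
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat(sprintf(
    "RCBD ANOVA: %d genotypes x %d blocks\n  F_G = %.3f (p = %.3g)\n  sigma2_g = %.4f, sigma2_e = %.4f, H2 = %.3f\n",
    x$n_genotypes, x$k, x$F_G, x$p_value, x$sigma2_g, x$sigma2_e,
    heritability(x)))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e / k)} with k the
#' number of replications. Returns `NA` with a warning when both variance
#' components are zero (H2 undefined).
#'
#' @param anova an [rcbd_anova()] result, or a numeric `sigma2_g`.
#' @param sigma2_e,k used when `anova` is numeric.
#' @return scalar in \[0, 1] (or `NA`).
#' @export
heritability <- function(anova, sigma2_e = NULL, k = NULL) {
  if (inherits(anova, "rcbd_anova")) {
    sg <- anova$sigma2_g; se <- anova$sigma2_e; k <- anova$k
  } else {
    sg <- anova; se <- sigma2_e
    if (is.null(se) || is.null(k)) stop("supply sigma2_e and k")
  }
  if (k < 1) stop("k must be >= 1")
  if (!is.finite(sg) || !is.finite(se)) stop("non-finite variance components")
  if (sg == 0 && se == 0) {
    warning("both variance components are zero: H2 undefined")
    return(NA_real_)
  }
  sg / (sg + se / k)
}

#' Heritability report over several traits
#'
#' Runs [rcbd_anova()] per trait and tabulates F, significance stars
#' (`*` p < 0.05, `***` p < 0.001, F test with (g-1, (g-1)(k-1)) df),
#' variance components and H2.
#'
#' @param records long data.frame: `genotype`, `block`, `trait`, `value`.
#' @return data.frame: `trait`, `F_G`, `significance`, `sigma2_g`,
#'   `sigma2_e`, `k`, `H2`.
#' @export
herit_report <- function(records) {
  stopifnot(all(c("genotype", "block", "trait", "value") %in% names(records)))
  traits <- unique(as.character(records$trait))
  rows <- lapply(traits, function(v) {
    a <- rcbd_anova(records[records$trait == v,
                            c("genotype", "block", "value")])
    data.frame(trait = v, F_G = a$F_G,
               significance = if (a$p_value < 0.001) "***"
                              else if (a$p_value < 0.05) "*" else "",
               sigma2_g = a$sigma2_g, sigma2_e = a$sigma2_e, k = a$k,
               H2 = suppressWarnings(heritability(a)))
  })
  do.call(rbind, rows)
}
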