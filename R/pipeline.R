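# ---- table IO helpers ------------------------------------------------------

# CSV writer that preserves doubles exactly: numerics go through %.17g,
# which round-trips IEEE doubles; everything else is written as-is.
write_table_lossless <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

efd_colnames <- function(N) {
  if (N < 1) return(character(0))
  as.vector(t(outer(seq_len(N), c("a", "b", "c", "d"),
                    function(n, l) paste0(l, "_", n))))
}

#' Write / read an EFD table
#'
#' One row per canopy: `id`, `A0`, `C0`, `T`, then
#' `a_1, b_1, c_1, d_1, ..., a_N, ..., d_N`. Standardized tables use the
#' same coefficient layout plus the normalization frame columns `L`,
#' `psi`, `theta`. Doubles round-trip losslessly.
#'
#' @param efds named list of [efourier()] sets (shared N).
#' @param path CSV path.
#' @export
write_efd_csv <- function(efds, path) {
  if (length(efds) == 0) {
    return(write_table_lossless(
      data.frame(id = character(), A0 = double(), C0 = double(), T = double()),
      path))
  }
  Ns <- vapply(efds, function(e) e$N, integer(1))
  if (length(unique(Ns)) != 1) stop("all descriptor sets must share N")
  ids <- names(efds)
  if (is.null(ids)) ids <- as.character(seq_along(efds))
  m <- do.call(rbind, lapply(efds, function(e)
    c(e$A0, e$C0, if (is.null(e$T)) NA_real_ else e$T, as.vector(t(e$coef)))))
  df <- data.frame(id = ids, m, check.names = FALSE)
  names(df) <- c("id", "A0", "C0", "T", efd_colnames(Ns[1]))
  write_table_lossless(df, path)
}

#' @rdname write_efd_csv
#' @export
read_efd_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_schema(df, c("id", "A0", "C0", "T"), "EFD table")
  if (nrow(df) == 0) return(stats::setNames(list(), character(0)))
  N <- (ncol(df) - 4L) %/% 4L
  check_schema(df, efd_colnames(N), "EFD table")
  out <- lapply(seq_len(nrow(df)), function(i) {
    coef <- matrix(as.numeric(df[i, efd_colnames(N)]), N, 4, byrow = TRUE,
                   dimnames = list(NULL, c("a", "b", "c", "d")))
    structure(list(A0 = df$A0[i], C0 = df$C0[i], coef = coef, N = N,
                   T = df$T[i], start = c(NA, NA)), class = "efd")
  })
  names(out) <- df$id
  out
}

#' @rdname write_efd_csv
#' @param stds named list of [efd_standardize()] results.
#' @export
write_std_csv <- function(stds, path) {
  Ns <- vapply(stds, function(e) e$N, integer(1))
  if (length(unique(Ns)) != 1) stop("all descriptor sets must share N")
  ids <- names(stds)
  if (is.null(ids)) ids <- as.character(seq_along(stds))
  m <- do.call(rbind, lapply(stds, function(s)
    c(s$L, s$psi, s$theta, s$A0, s$C0, as.vector(t(s$coef)))))
  df <- data.frame(id = ids, m, check.names = FALSE)
  names(df) <- c("id", "L", "psi", "theta", "A0", "C0", efd_colnames(Ns[1]))
  write_table_lossless(df, path)
}

#' @rdname write_efd_csv
#' @export
read_std_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_schema(df, c("id", "L", "psi", "theta", "A0", "C0"), "standardized table")
  N <- (ncol(df) - 6L) %/% 4L
  check_schema(df, efd_colnames(N), "standardized table")
  out <- lapply(seq_len(nrow(df)), function(i) {
    coef <- matrix(as.numeric(df[i, efd_colnames(N)]), N, 4, byrow = TRUE,
                   dimnames = list(NULL, c("a", "b", "c", "d")))
    structure(list(coef = coef, N = N, L = df$L[i], psi = df$psi[i],
                   theta = df$theta[i], A0 = df$A0[i], C0 = df$C0[i],
                   T = NA_real_, xm = NA_real_, ym = NA_real_),
              class = "efd_std")
  })
  names(out) <- df$id
  out
}

# ---- pipeline --------------------------------------------------------------

#' Pipeline configuration
#'
#' @param seg a [seg_config()].
#' @param n_harmonics fixed harmonic count, or `NULL` to auto-select.
#' @param threshold_pct error threshold for auto-selection (percent).
#' @param sweep harmonic sweep for auto-selection.
#' @param probe_N harmonics used to rank outline complexity.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seg = seg_config(), n_harmonics = NULL,
                            threshold_pct = 1,
                            sweep = seq(10, 1000, by = 10),
                            probe_N = 10) {
  if (!is.null(n_harmonics) && n_harmonics < 1) stop("n_harmonics must be >= 1")
  structure(list(seg = seg, n_harmonics = n_harmonics,
                 threshold_pct = threshold_pct, sweep = sweep,
                 probe_N = probe_N),
            class = "pipeline_config")
}

# segmentation + outline for one image file; errors propagate to caller
image_to_contour <- function(path, seg) {
  img <- read_rgb(path)
  raw <- segment_canopy(img, seg)
  if (!any(raw)) stop("segmentation produced an empty mask")
  cleaned <- clean_mask(raw, seg$min_component_fraction)
  filled <- fill_holes(cleaned)
  list(contour = trace_outline(filled),
       n_components_removed = max(label_components(raw)) - 1L,
       holes_filled = sum(filled) - sum(cleaned))
}

#' Run the full outline-to-descriptor pipeline on an image directory
#'
#' Implements the batch workflow: every image is segmented, cleaned,
#' filled and traced; all outlines are probed with a low-order expansion
#' (`probe_N`); the most complex outline (largest probe error) is used to
#' select the harmonic count by the error-threshold sweep (unless a fixed
#' `n_harmonics` is configured); every outline is then re-expressed with
#' that count, standardized, and traits are computed from both the
#' original polygon and the reconstruction. Images that fail to read or
#' segment are skipped with a reason in the manifest; the batch never
#' aborts on a single image.
#'
#' @param image_dir directory of PNG/JPEG images.
#' @param metadata_path optional CSV with an `id` column (image file name
#'   without extension) merged into the trait table.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the EFD, standardized
#'   and trait tables plus a JSON run manifest are written there.
#' @return list: `efds`, `stds` (named lists), `traits` (long table),
#'   `N_used`, `most_complex_id`, `manifest` (per-image status
#'   data.frame), `probe_errors`.
#' @export
run_pipeline <- function(image_dir, metadata_path = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  files <- list.files(image_dir, pattern = "(?i)\\.(png|jpe?g)$",
                      full.names = TRUE)
  files <- files[!grepl("_mask\\.png$", files)]
  if (length(files) == 0) stop("no readable images in ", image_dir)
  ids <- tools::file_path_sans_ext(basename(files))
  status <- stats::setNames(rep("ok", length(files)), ids)
  contours <- list()
  qc <- list()
  for (i in seq_along(files)) {
    res <- tryCatch(image_to_contour(files[i], config$seg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- paste0("error:", conditionMessage(res))
    } else {
      contours[[ids[i]]] <- res$contour
      qc[[ids[i]]] <- res
    }
  }
  if (length(contours) == 0) stop("no image could be processed")
  # rank complexity with the probe expansion
  probe_err <- vapply(contours, function(ct) {
    ch <- chain_code(ct)
    efd_error(ch, efourier(ch, config$probe_N))
  }, numeric(1))
  complex_id <- names(contours)[which.max(probe_err)]
  if (is.null(config$n_harmonics)) {
    N_used <- as.integer(select_n_harmonics(contours[[complex_id]],
                                            threshold_pct = config$threshold_pct,
                                            sweep = config$sweep))
  } else {
    N_used <- as.integer(config$n_harmonics)
  }
  efds <- lapply(contours, efourier, N = N_used)
  stds <- lapply(efds, efd_standardize)
  fid <- trait_fidelity(contours, efds, N = N_used, ids = names(contours))
  traits <- fid$traits
  if (!is.null(metadata_path)) {
    meta <- utils::read.csv(metadata_path)
    check_schema(meta, "id", "metadata table")
    traits <- merge(traits, meta, by = "id", all.x = TRUE, sort = FALSE)
  }
  manifest <- data.frame(id = ids, file = basename(files), status = status,
                         row.names = NULL)
  ok <- manifest$status == "ok"
  manifest$E_N <- NA_real_
  manifest$E_N[ok] <- vapply(manifest$id[ok], function(id)
    efd_error(chain_code(contours[[id]]), efds[[id]]), numeric(1))
  manifest$n_components_removed <- NA_integer_
  manifest$n_components_removed[ok] <-
    vapply(manifest$id[ok], function(id) qc[[id]]$n_components_removed, integer(1))
  manifest$holes_filled <- NA_integer_
  manifest$holes_filled[ok] <-
    vapply(manifest$id[ok], function(id) qc[[id]]$holes_filled, integer(1))
  out <- list(efds = efds, stds = stds, traits = traits, N_used = N_used,
              most_complex_id = complex_id, manifest = manifest,
              probe_errors = probe_err)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_efd_csv(efds, file.path(out_dir, "efd.csv"))
    write_std_csv(stds, file.path(out_dir, "efd_standardized.csv"))
    write_trait_csv(traits, file.path(out_dir, "traits.csv"))
    jsonlite::write_json(
      list(n_images = length(files),
           n_ok = sum(ok), n_error = sum(!ok),
           N_used = N_used, most_complex_id = complex_id,
           per_image = manifest,
           version = as.character(utils::packageVersion("canopyefd"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
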