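# Focal-plane-array hyperspectral pipeline: working-range trimming,
# scaled-MAD outlier flagging and neighbour-mean repair, PCA + k-means
# foreground segmentation, EMSC-based descattering of foreground spectra,
# and band / ratio map extraction.

FPA_SEGMENT_BANDS <- c(3010, 2955, 2925, 2855, 1742, 1708, 1650)

#' Trim a cube to the informative working range
#'
#' Bands above 3200 cm^-1 (water-dominated, no lipid signatures) and
#' below 1000 cm^-1 (acquisition noise) are removed.
#'
#' @param cube a [hyper_cube()].
#' @param lo,hi working range bounds in cm^-1 (defaults 1000 and 3200).
#' @return The trimmed `hyper_cube`.
#' @export
trim_cube <- function(cube, lo = 1000, hi = 3200) {
  stopifnot(inherits(cube, "hyper_cube"))
  keep <- cube$wavenumber >= lo & cube$wavenumber <= hi
  if (!any(keep)) stop("no bands remain in the working range [", lo, ", ", hi, "]")
  hyper_cube(cube$values[, , keep, drop = FALSE], cube$wavenumber[keep],
             cube$pixel_size)
}

#' Flag outlier pixels by the scaled-MAD rule
#'
#' Per band (spectral map), a pixel is flagged when its value lies more
#' than `k` scaled median absolute deviations (MAD x 1.4826, the
#' consistency constant for a normal distribution) from the map median.
#' Pixels flagged in more than `global_fraction` of all bands are
#' additionally marked as global outliers (dead/hot detector pixels).
#'
#' @param cube a [hyper_cube()] with at least 9 pixels per band.
#' @param k threshold in scaled MADs (default 3).
#' @param global_fraction fraction of bands above which a pixel counts as
#'   a global outlier (default 0.5).
#' @return Object of class `outlier_mask`: logical array `mask`
#'   (same shape as the cube), logical matrix `global` (per pixel), and
#'   the per-band flag counts.
#' @export
flag_outliers <- function(cube, k = 3, global_fraction = 0.5) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  if (d[1L] * d[2L] < 9L) stop("need at least 9 pixels per band")
  mask <- array(FALSE, d)
  for (b in seq_len(d[3L])) {
    img <- cube$values[, , b]
    med <- stats::median(img)
    s <- stats::mad(img)  # scaled by 1.4826 by default
    if (s == 0) {
      warning("zero MAD in band ", b, "; falling back to standard deviation")
      s <- stats::sd(img)
      if (s == 0) next
    }
    mask[, , b] <- abs(img - med) > k * s
  }
  frac <- apply(mask, c(1L, 2L), mean)
  glob <- frac > global_fraction
  # a global outlier is treated as flagged in every band
  if (any(glob)) {
    gi <- which(glob)
    for (b in seq_len(d[3L])) {
      band <- mask[, , b]
      band[gi] <- TRUE
      mask[, , b] <- band
    }
  }
  structure(list(mask = mask, global = glob,
                 band_counts = apply(mask, 3L, sum)),
            class = "outlier_mask")
}

#' @export
print.outlier_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat("<outlier_mask> ", sum(x$mask), " flags over ", d[1L] * d[2L],
      " px x ", d[3L], " bands (", sum(x$global), " global)\n", sep = "")
  invisible(x)
}

# mean of unflagged 8-neighbours for a set of flagged positions in one map
neighbour_mean <- function(img, flagged) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, sum(flagged))
  pos <- which(flagged, arr.ind = TRUE)
  for (q in seq_len(nrow(pos))) {
    i <- pos[q, 1L]; j <- pos[q, 2L]
    ri <- max(1L, i - 1L):min(nr, i + 1L)
    rj <- max(1L, j - 1L):min(nc, j + 1L)
    vals <- img[ri, rj]
    ok <- !flagged[ri, rj]
    ok[match(i, ri), match(j, rj)] <- FALSE
    if (any(ok)) out[q] <- mean(vals[ok])
  }
  out
}

#' Repair flagged outlier pixels by neighbour means
#'
#' Band-wise, each flagged pixel is replaced by the mean of its
#' non-flagged 8-neighbours; where a flagged pixel has no clean
#' neighbour, the replacement iterates (repaired pixels count as clean in
#' the next pass) up to `max_iter` passes.
#'
#' @param cube a [hyper_cube()].
#' @param mask a [flag_outliers()] result.
#' @param max_iter iteration cap (default 10).
#' @return The repaired `hyper_cube`.
#' @export
repair_outliers <- function(cube, mask, max_iter = 10L) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "outlier_mask"))
  vals <- cube$values
  for (b in seq_len(dim(vals)[3L])) {
    img <- vals[, , b]
    flagged <- mask$mask[, , b]
    it <- 0L
    while (any(flagged) && it < max_iter) {
      repl <- neighbour_mean(img, flagged)
      done <- !is.na(repl)
      idx <- which(flagged)
      img[idx[done]] <- repl[done]
      flagged[idx[done]] <- FALSE
      it <- it + 1L
      if (!any(done)) break
    }
    if (any(flagged)) {
      pos <- which(flagged, arr.ind = TRUE)
      stop("unrecoverable outlier pixels in band ", b, ": ",
           paste(sprintf("(%d,%d)", pos[, 1L], pos[, 2L]), collapse = " "))
    }
    vals[, , b] <- img
  }
  hyper_cube(vals, cube$wavenumber, cube$pixel_size)
}

# k-means++ seeding (deterministic given the RNG state), then Lloyd
# iterations through stats::kmeans; best of `restarts` by total
# within-cluster sum of squares.
kmeanspp <- function(X, k, restarts = 10L, seed = 0L) {
  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, ncol(X))
    centers[1L, ] <- X[sample.int(nrow(X), 1L), ]
    d2 <- rowSums((X - matrix(centers[1L, ], nrow(X), ncol(X), byrow = TRUE))^2)
    if (k > 1L) for (c in 1L:(k - 1L)) {
      nxt <- if (sum(d2) > 0) sample.int(nrow(X), 1L, prob = d2 / sum(d2))
             else sample.int(nrow(X), 1L)
      centers[c + 1L, ] <- X[nxt, ]
      d2 <- pmin(d2, rowSums((X - matrix(X[nxt, ], nrow(X), ncol(X),
                                         byrow = TRUE))^2))
    }
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100L)),
      error = function(e)
        suppressWarnings(stats::kmeans(X, centers = k, iter.max = 100L)))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Segment a cube into foreground (cells) and background
#'
#' Per-pixel features are the absorbances at the named marker bands
#' (nearest axis band within `band_tol`), standardised per band, reduced
#' by PCA to the components reaching at least `variance_keep` cumulative
#' variance, and clustered by k-means (k = 2, k-means++ seeding, 10
#' restarts, best inertia kept). The foreground is the cluster with the
#' higher mean amide-I (1650 cm^-1) absorbance.
#'
#' @param cube a [hyper_cube()].
#' @param bands marker bands in cm^-1; default the seven lipid/protein
#'   bands 3010, 2955, 2925, 2855, 1742, 1708, 1650.
#' @param variance_keep cumulative-variance threshold (default 0.99).
#' @param seed RNG seed for the clustering (default 0).
#' @param band_tol band lookup tolerance in cm^-1 (default 4, the FPA
#'   resolution).
#' @return Object of class `segmentation_mask`: logical `foreground`
#'   matrix, `cluster_means` per band, `n_components` kept.
#' @export
segment_cube <- function(cube, bands = FPA_SEGMENT_BANDS,
                         variance_keep = 0.99, seed = 0L, band_tol = 4) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  idx <- vapply(bands, function(b) {
    j <- which.min(abs(cube$wavenumber - b))
    if (abs(cube$wavenumber[j] - b) > band_tol)
      stop("band ", b, " cm^-1 not on the cube axis (within +/-", band_tol, ")")
    j
  }, integer(1L))
  feat <- sapply(idx, function(j) as.vector(cube$values[, , j]))
  colnames(feat) <- as.character(bands)
  sds <- apply(feat, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant band(s): ",
            paste(bands[sds == 0], collapse = ", "))
    feat <- feat[, sds > 0, drop = FALSE]
    bands <- bands[sds > 0]
  }
  Z <- scale(feat)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(cum >= variance_keep)[1L]
  km <- kmeanspp(pc$x[, seq_len(ncomp), drop = FALSE], k = 2L, seed = seed)
  # foreground = cluster with higher mean amide-I absorbance
  amide <- which.min(abs(cube$wavenumber - 1650))
  amide_vals <- as.vector(cube$values[, , amide])
  m1 <- mean(amide_vals[km$cluster == 1L])
  m2 <- mean(amide_vals[km$cluster == 2L])
  fg_cluster <- if (m1 >= m2) 1L else 2L
  fg <- matrix(km$cluster == fg_cluster, d[1L], d[2L])
  cluster_means <- rbind(foreground = colMeans(feat[km$cluster == fg_cluster, ,
                                                    drop = FALSE]),
                         background = colMeans(feat[km$cluster != fg_cluster, ,
                                                    drop = FALSE]))
  structure(list(foreground = fg, cluster_means = cluster_means,
                 n_components = ncomp),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("<segmentation_mask> ", sum(x$foreground), " foreground / ",
      length(x$foreground), " px\n", sep = "")
  invisible(x)
}

#' Descatter foreground spectra (EMSC stand-in)
#'
#' Foreground pixel spectra are EMSC-corrected against the foreground
#' mean spectrum with a quadratic baseline polynomial and then
#' Savitzky-Golay smoothed, removing smooth scatter baselines and
#' multiplicative path-length variation. Background pixels are returned
#' untouched. The interface (cube + mask in, cube out) is fixed so that a
#' model-based scatter correction can replace the internals.
#'
#' @param cube a [hyper_cube()].
#' @param mask a [segment_cube()] result.
#' @param sg smoothing parameters (default window 9, order 2, no
#'   derivative).
#' @param min_foreground skip (with a warning) below this many foreground
#'   pixels (default 10).
#' @return The corrected `hyper_cube`.
#' @export
descatter <- function(cube, mask, sg = sg_params(9L, 2L, 0L),
                      min_foreground = 10L) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "segmentation_mask"))
  fg <- which(mask$foreground)
  if (length(fg) < min_foreground) {
    warning("foreground has ", length(fg), " pixels (< ", min_foreground,
            "); descattering skipped")
    return(cube)
  }
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1L] * d[2L], d[3L])  # pixels x bands
  sub <- flat[fg, , drop = FALSE]
  coll <- ir_collection(cube$wavenumber, sub)
  corr <- emsc_fit_correct(coll, reference = "mean", poly_order = 2L)$corrected
  sm <- savitzky_golay(corr, sg)
  flat[fg, ] <- sm$data
  hyper_cube(array(flat, d), cube$wavenumber, cube$pixel_size)
}

#' Band images and foreground ratio maps
#'
#' Extracts nearest-band images for the requested bands and computes
#' per-pixel ratio maps for the requested pairs, restricted to the
#' foreground. Ratios with denominator absorbance below `denom_floor` are
#' masked (NA) and counted, never divided.
#'
#' @param cube a [hyper_cube()].
#' @param mask a [segment_cube()] result.
#' @param bands bands to extract in cm^-1.
#' @param ratio_pairs list of `(numerator, denominator)` pairs; default
#'   the lipid-to-protein pair (1742, 1650).
#' @param denom_floor denominator floor in absorbance units (default 1e-3).
#' @return List with `band_images` (named list of matrices), `ratio_maps`
#'   (named list of class `ratio_map` matrices, NA off-foreground),
#'   `flagged` (per-pair count of floored denominators) and `scale`
#'   (per-image ranges, since display scaling is per image).
#' @export
band_and_ratio_maps <- function(cube, mask, bands = FPA_SEGMENT_BANDS,
                                ratio_pairs = list(c(1742, 1650)),
                                denom_floor = 1e-3) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "segmentation_mask"))
  band_image <- function(b) {
    j <- which.min(abs(cube$wavenumber - b))
    cube$values[, , j]
  }
  imgs <- lapply(bands, band_image)
  names(imgs) <- as.character(bands)
  ratios <- list(); flagged <- integer(0)
  for (pr in ratio_pairs) {
    num <- band_image(pr[1L]); den <- band_image(pr[2L])
    rmap <- matrix(NA_real_, nrow(num), ncol(num))
    ok <- mask$foreground & den >= denom_floor
    rmap[ok] <- num[ok] / den[ok]
    nm <- sprintf("%g:%g", pr[1L], pr[2L])
    ratios[[nm]] <- structure(rmap, class = c("ratio_map", "matrix"))
    flagged[nm] <- sum(mask$foreground & den < denom_floor)
  }
  list(band_images = imgs, ratio_maps = ratios, flagged = flagged,
       scale = lapply(imgs, range))
}
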