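# AFM-IR map corrections: topography levelling (plane + scan-line
# medians), contact-loss repair, rigid drift registration between
# per-wavenumber acquisitions, topography rescaling/unit change,
# laser-power normalisation, k-means segmentation and log10 ratio maps,
# plus point-spectrum preprocessing.

#' Level an AFM topography map
#'
#' Removes the background tilt (scanner slope/bow) by a least-squares 2-D
#' polynomial surface fit (default order 1, a plane), made robust to
#' raised features by iteratively refitting on the lower-residual half of
#' the pixels, and then removes per-scan-line height offsets by
#' subtracting each line's median. Scan lines are rows.
#'
#' @param topo numeric height matrix.
#' @param poly_order surface polynomial order (default 1 = plane).
#' @param robust_iter robust refit iterations (default 3; 0 = plain fit).
#' @return The levelled matrix.
#' @export
level_topography <- function(topo, poly_order = 1L, robust_iter = 3L) {
  stopifnot(is.matrix(topo))
  nr <- nrow(topo); nc <- ncol(topo)
  if (nr < 3L || nc < 3L) stop("map must be at least 3x3")
  xi <- rep(seq_len(nc), each = nr) / nc  # column coordinate
  yi <- rep(seq_len(nr), times = nc) / nr # row coordinate
  terms <- list(rep(1, nr * nc))
  for (o in seq_len(poly_order))
    for (px in 0:o) terms[[length(terms) + 1L]] <- xi^px * yi^(o - px)
  B <- do.call(cbind, terms)
  if (ncol(B) >= nr * nc) stop("polynomial order too high for map size")
  z <- as.vector(topo)
  use <- rep(TRUE, length(z))
  for (it in 0:robust_iter) {
    cf <- stats::lm.fit(B[use, , drop = FALSE], z[use])$coefficients
    cf[is.na(cf)] <- 0
    resid <- z - as.vector(B %*% cf)
    if (it < robust_iter) use <- resid <= stats::median(resid)
  }
  out <- matrix(resid, nr, nc)
  out - apply(out, 1L, stats::median)
}

# Contact-loss dropout flagging. Dropouts are confined to scan lines
# (rows) while adjacent lines image the same structure cleanly, so each
# pixel is screened against the running median of its COLUMN (window 5):
# a pixel is flagged when its column residual falls below -k scaled MADs
# of the residual map AND it has lost more than half of the local signal
# level. One-sided, so bright droplet pixels are never flagged; the
# signal-loss condition keeps smooth clean maps untouched. Absorption
# maps are assumed non-negative.
flag_contact_loss <- function(map, k = 3, window = 5L) {
  nr <- nrow(map)
  window <- min(window, nr - (1 - nr %% 2))
  colmed <- apply(map, 2L, stats::runmed, k = window)
  r <- map - colmed
  s <- stats::mad(r)
  if (s == 0) s <- stats::sd(r)
  flags <- matrix(FALSE, nrow(map), ncol(map))
  if (is.na(s) || s == 0) return(flags)
  flags <- (r < -k * s) & ((colmed - map) > 0.5 * abs(colmed))
  # a dropout lives in ONE scan line: both vertical neighbours must sit
  # at the column level, which excludes genuine 2-D structure boundaries
  above <- rbind(map[1L, ], map[-nr, ])
  below <- rbind(map[-1L, ], map[nr, ])
  flags <- flags & ((pmin(above, below) - map) > 0.5 * abs(colmed))
  flags[c(1L, nr), ] <- FALSE  # unverifiable at the frame edge
  for (i in seq_len(nrow(map)))
    if (all(flags[i, ]))
      stop("entire scan line ", i, " flagged as contact loss")
  flags
}

#' Repair contact-loss pixels in an AFM-IR absorption map
#'
#' Momentary loss of tip-sample contact produces dropout pixels with no
#' usable absorption signal. Because dropouts are confined to single
#' scan lines, pixels are screened against the running median of their
#' image column: a pixel whose column residual falls more than k scaled
#' MADs below zero and which has lost over half the local signal level
#' is flagged (the detection rule is a package convention; one-sided, so
#' bright droplet pixels are never flagged) and replaced by the mean of
#' its non-flagged 8-neighbours, iterating while isolated clusters
#' remain.
#'
#' @param map numeric absorption matrix (at least 3x3).
#' @param k threshold in scaled MADs (default 3).
#' @param max_iter repair iteration cap (default 10).
#' @return List: `map` (repaired), `flags` (logical matrix of detected
#'   pixels).
#' @export
repair_contact_loss <- function(map, k = 3, max_iter = 10L) {
  stopifnot(is.matrix(map))
  if (nrow(map) < 3L || ncol(map) < 3L) stop("map must be at least 3x3")
  flags <- flag_contact_loss(map, k)
  img <- map
  flagged <- flags
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
    stop("unrecoverable contact-loss pixels: ",
         paste(sprintf("(%d,%d)", pos[, 1L], pos[, 2L]), collapse = " "))
  }
  list(map = img, flags = flags)
}

#' Construct a rigid transform
#'
#' Convention: a point p (column = x, row = y, pixels) in the source
#' image maps to R(theta) (p - c) + c + (dx, dy) in the transformed
#' image, where c is the image centre and theta is counter-clockwise in
#' degrees (with y pointing down the scan).
#'
#' @param dx,dy translation in pixels.
#' @param theta rotation in degrees.
#' @param estimated logical: was this estimated (vs applied)?
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0, estimated = FALSE) {
  structure(list(dx = dx, dy = dy, theta = theta, estimated = estimated),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx = %.3f px, dy = %.3f px, theta = %.3f deg%s\n",
              x$dx, x$dy, x$theta, if (x$estimated) " (estimated)" else ""))
  invisible(x)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  th <- -tf$theta * pi / 180
  rigid_transform(-(cos(th) * tf$dx - sin(th) * tf$dy),
                  -(sin(th) * tf$dx + cos(th) * tf$dy),
                  -tf$theta, estimated = tf$estimated)
}

#' Apply a rigid transform to an image
#'
#' Bilinear resampling; pixels that map outside the source frame become
#' `NA` (and are excluded from downstream statistics).
#'
#' @param img numeric matrix.
#' @param tf a [rigid_transform()].
#' @param fill value for out-of-frame pixels (default `NA`).
#' @return Transformed matrix.
#' @export
apply_transform <- function(img, tf, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  th <- tf$theta * pi / 180
  # output(q) = img(R^-1 (q - c - t) + c)
  xq <- rep(seq_len(nc), each = nr) - cx - tf$dx
  yq <- rep(seq_len(nr), times = nc) - cy - tf$dy
  xs <- cos(th) * xq + sin(th) * yq + cx
  ys <- -sin(th) * xq + cos(th) * yq + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 + 1 <= nc & y0 >= 1 & y0 + 1 <= nr
  out <- rep(fill, nr * nc)
  if (any(ok)) {
    i00 <- (x0[ok] - 1L) * nr + y0[ok]
    v <- img[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      img[i00 + nr] * fx[ok] * (1 - fy[ok]) +
      img[i00 + 1L] * (1 - fx[ok]) * fy[ok] +
      img[i00 + nr + 1L] * fx[ok] * fy[ok]
    out[ok] <- v
  }
  matrix(out, nr, nc)
}

# sub-pixel translation between two same-size images via zero-padded FFT
# cross-correlation with parabolic peak refinement; returns the shift s
# such that moving ~ fixed shifted by s
cc_translation <- function(fixed, moving) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  f0 <- fixed - mean(fixed); m0 <- moving - mean(moving)
  FP <- matrix(0, 2 * nr, 2 * nc); MP <- FP
  FP[1:nr, 1:nc] <- f0; MP[1:nr, 1:nc] <- m0
  cc <- Re(stats::fft(stats::fft(MP) * Conj(stats::fft(FP)), inverse = TRUE)) /
    length(FP)
  pk <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) if (i - 1L > n) i - 1L - 2L * n else i - 1L
  dy <- wrap(pk[1L], nr); dx <- wrap(pk[2L], nc)
  ref <- function(along) {
    g <- function(k) {
      i <- ((pk[1L] - 1L + if (along == 1L) k else 0L) %% (2L * nr)) + 1L
      j <- ((pk[2L] - 1L + if (along == 2L) k else 0L) %% (2L * nc)) + 1L
      cc[i, j]
    }
    c0 <- g(0L); cm <- g(-1L); cp <- g(1L)
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else 0.5 * (cm - cp) / den
  }
  list(dx = dx + ref(2L), dy = dy + ref(1L))
}

#' Estimate the rigid drift between two maps
#'
#' Coarse-to-fine intensity-based registration: for each candidate
#' rotation on a grid (default +/- `max_theta` degrees at `theta_step`),
#' the moving image is unrotated, the sub-pixel translation estimated by
#' zero-padded FFT cross-correlation with parabolic peak refinement, and
#' the fully aligned candidate scored by its mean squared mismatch with
#' the fixed image over the valid overlap; the best rotation is refined
#' on a five-fold finer local grid plus a final parabolic step. The
#' returned transform maps the fixed image onto the
#' moving one, i.e. `moving ~ apply_transform(fixed, tf)`; apply
#' [invert_transform()] to align the moving image back.
#'
#' @param fixed,moving numeric matrices of the same shape.
#' @param max_theta rotation search half-range in degrees (default 10).
#' @param theta_step rotation grid step in degrees (default 0.25).
#' @return A [rigid_transform()] with `estimated = TRUE`.
#' @export
register_maps <- function(fixed, moving, max_theta = 10, theta_step = 0.25) {
  stopifnot(is.matrix(fixed), identical(dim(fixed), dim(moving)))
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    stop("flat image: similarity peak is not unique")
  fill_na <- function(m) { m[is.na(m)] <- stats::median(m, na.rm = TRUE); m }
  # candidate evaluation: unrotate, estimate the sub-pixel shift by FFT
  # cross-correlation, then score the candidate SYMMETRICALLY: half the
  # transform applied to the fixed image, the inverse half to the moving
  # one, so both sides suffer the same one resampling and the mismatch
  # at the true transform is not inflated by one-sided interpolation
  # smoothing (which would bias the optimum on near-degenerate content)
  half_of <- function(tf) {
    th <- tf$theta / 2 * pi / 180
    Rh <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    s_ <- solve(diag(2L) + Rh, c(tf$dx, tf$dy))
    rigid_transform(s_[1L], s_[2L], tf$theta / 2)
  }
  sym_sse <- function(cand) {
    h <- half_of(cand)
    af <- apply_transform(fixed, h)
    am <- apply_transform(moving, invert_transform(h))
    ok <- !is.na(af) & !is.na(am)
    if (!any(ok)) return(Inf)
    mean((af[ok] - am[ok])^2)
  }
  fill_na2 <- function(m) { m[is.na(m)] <- stats::median(m, na.rm = TRUE); m }
  eval_theta <- function(th) {
    unrot <- fill_na2(apply_transform(moving, rigid_transform(0, 0, -th)))
    r <- cc_translation(fixed, unrot)
    thr <- th * pi / 180
    cand <- rigid_transform(cos(thr) * r$dx - sin(thr) * r$dy,
                            sin(thr) * r$dx + cos(thr) * r$dy, th)
    list(transform = cand, sse = sym_sse(cand))
  }
  thetas <- seq(-max_theta, max_theta, by = theta_step)
  coarse <- vapply(thetas, function(th) eval_theta(th)$sse, numeric(1L))
  b <- thetas[which.min(coarse)]
  fine <- seq(b - theta_step, b + theta_step, by = theta_step / 5)
  fsse <- vapply(fine, function(th) eval_theta(th)$sse, numeric(1L))
  theta <- fine[which.min(fsse)]
  tf <- eval_theta(theta)$transform
  # final joint polish of (dx, dy, theta) on the symmetric objective
  opt <- stats::optim(c(tf$dx, tf$dy, tf$theta),
                      function(p) sym_sse(rigid_transform(p[1L], p[2L], p[3L])),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
  rigid_transform(opt$par[1L], opt$par[2L], opt$par[3L], estimated = TRUE)
}

#' Rescale a topography map and convert its units
#'
#' Shifts values so the minimum is zero, replaces values below the 5th
#' percentile (linear-interpolation percentile convention) by that
#' percentile, and converts to micrometres.
#'
#' @param topo numeric height matrix.
#' @param from_units units of the input: `"um"` (default) or `"nm"`.
#' @param probs clipping percentile in \[0, 1\] (default 0.05).
#' @return Rescaled matrix in micrometres.
#' @export
rescale_topography <- function(topo, from_units = c("um", "nm"), probs = 0.05) {
  from_units <- match.arg(from_units)
  out <- topo / if (from_units == "nm") 1000 else 1
  out <- out - min(out, na.rm = TRUE)
  thr <- stats::quantile(out, probs, na.rm = TRUE, type = 7, names = FALSE)
  out[!is.na(out) & out < thr] <- thr
  out
}

#' Normalise an absorption map by laser power
#'
#' Divides the map by the source (background) power interpolated at the
#' acquisition wavenumber, making maps at different wavenumbers directly
#' comparable.
#'
#' @param map numeric absorption matrix.
#' @param wavenumber acquisition wavenumber in cm^-1.
#' @param power a [laser_power()].
#' @return Normalised matrix.
#' @export
normalize_absorption <- function(map, wavenumber, power) {
  p <- power_at(power, wavenumber)
  if (!is.finite(p) || p <= 0) stop("laser power not positive at ", wavenumber, " cm^-1")
  map / p
}

#' Run the full AFM-IR correction chain on a map set
#'
#' In order: refuse thick samples (the tip loses contact on surfaces more
#' than ~2-3 um tall, so no reliable maps can be acquired), topography
#' levelling, contact-loss repair on absorption, rigid-drift registration
#' of every non-fixed wavenumber's maps onto the fixed wavenumber's
#' topography (estimated transform inverted and applied to that
#' wavenumber's topography, deflection and absorption), topography
#' rescaling/unit conversion, and laser-power normalisation of
#' absorption.
#'
#' @param set an [afmir_set()].
#' @param fixed_wavenumber reference wavenumber whose topography is the
#'   fixed registration image (default 1600).
#' @param level_order topography surface fit order (default 1).
#' @param topo_units units of the raw topography (default `"nm"`).
#' @param level_absorption also line-level absorption maps? Default
#'   `FALSE`: absorption receives only repair and normalisation.
#' @return List: `set` (corrected `afmir_set`), `transforms` (named list
#'   of estimated [rigid_transform()]s), `contact_flags` (named list of
#'   detection masks).
#' @export
correct_afmir_set <- function(set, fixed_wavenumber = 1600, level_order = 1L,
                              topo_units = "nm", level_absorption = FALSE) {
  stopifnot(inherits(set, "afmir_set"))
  if (isTRUE(set$meta$thick_sample))
    stop("sample too thick in z-direction (> 2-3 um): the AFM tip loses ",
         "contact with the surface and no reliable AFM-IR maps can be acquired")
  if (!fixed_wavenumber %in% set$wavenumbers)
    stop("fixed wavenumber ", fixed_wavenumber, " not in the acquired set")
  maps <- set$maps
  contact_flags <- list()
  for (nm in names(maps)) {
    maps[[nm]]$topography <- level_topography(maps[[nm]]$topography,
                                              poly_order = level_order)
    rep_ <- repair_contact_loss(maps[[nm]]$absorption)
    maps[[nm]]$absorption <- rep_$map
    contact_flags[[nm]] <- rep_$flags
    if (level_absorption)
      maps[[nm]]$absorption <- maps[[nm]]$absorption -
        apply(maps[[nm]]$absorption, 1L, stats::median)
  }
  fixed_nm <- format(fixed_wavenumber)
  fixed_topo <- maps[[fixed_nm]]$topography
  transforms <- list()
  for (nm in names(maps)) {
    if (nm == fixed_nm) {
      transforms[[nm]] <- rigid_transform(0, 0, 0, estimated = TRUE)
      next
    }
    tf <- register_maps(fixed_topo, maps[[nm]]$topography)
    transforms[[nm]] <- tf
    # estimates below the interpolation accuracy floor are treated as
    # identity so that already-registered maps pass through untouched
    if (abs(tf$dx) < 0.05 && abs(tf$dy) < 0.05 && abs(tf$theta) < 0.05) next
    inv <- invert_transform(tf)
    for (role in c("topography", "deflection", "absorption")) {
      moved <- apply_transform(maps[[nm]][[role]], inv)
      moved[is.na(moved)] <- stats::median(moved, na.rm = TRUE)
      maps[[nm]][[role]] <- moved
    }
  }
  for (nm in names(maps)) {
    maps[[nm]]$topography <- rescale_topography(maps[[nm]]$topography,
                                                from_units = topo_units)
    maps[[nm]]$absorption <- normalize_absorption(maps[[nm]]$absorption,
                                                  as.numeric(nm), set$power)
  }
  out <- afmir_set(maps, set$scan_size, set$power, set$meta)
  list(set = out, transforms = transforms, contact_flags = contact_flags)
}

#' Segment an AFM-IR map set into hypha and background
#'
#' Per-pixel features: the fixed wavenumber's topography and deflection
#' plus every normalised absorption map; standardised and clustered by
#' k-means (k = 2, k-means++ seeding). The hypha is the cluster with the
#' higher mean topography. Background pixels are excluded from ratio
#' calculations downstream.
#'
#' @param set a corrected [afmir_set()].
#' @param fixed_wavenumber wavenumber providing topography/deflection
#'   features (default 1600).
#' @param seed RNG seed (default 0).
#' @return Object of class `segmentation_mask` (logical `foreground`).
#' @export
segment_afmir <- function(set, fixed_wavenumber = 1600, seed = 0L) {
  stopifnot(inherits(set, "afmir_set"))
  fixed_nm <- format(fixed_wavenumber)
  feat <- cbind(topography = as.vector(set$maps[[fixed_nm]]$topography),
                deflection = as.vector(set$maps[[fixed_nm]]$deflection))
  for (nm in names(set$maps))
    feat <- cbind(feat, as.vector(set$maps[[nm]]$absorption))
  sds <- apply(feat, 2L, stats::sd)
  if (all(sds == 0)) stop("degenerate map set: all features constant")
  feat <- feat[, sds > 0, drop = FALSE]
  Z <- scale(feat)
  km <- kmeanspp(Z, k = 2L, seed = seed)
  topo <- as.vector(set$maps[[fixed_nm]]$topography)
  m1 <- mean(topo[km$cluster == 1L]); m2 <- mean(topo[km$cluster == 2L])
  fg_cluster <- if (m1 >= m2) 1L else 2L
  fg <- matrix(km$cluster == fg_cluster, nrow(set$maps[[fixed_nm]]$topography),
               ncol(set$maps[[fixed_nm]]$topography))
  structure(list(foreground = fg, cluster_means = NULL, n_components = ncol(feat)),
            class = "segmentation_mask")
}

#' Log10 ratio maps from an AFM-IR map set
#'
#' Computes log10 ratios of absorption maps for the requested pairs
#' (default 1742:1600 and 1708:1600) and the log10 absorption-to-
#' topography ratio at every acquired wavenumber, restricted to the
#' foreground. Pixels with a non-positive numerator or denominator are
#' masked (NA) and counted, never clipped.
#'
#' @param set a corrected [afmir_set()].
#' @param mask a [segment_afmir()] result.
#' @param pairs list of `(numerator, denominator)` wavenumber pairs.
#' @return List: `absorption_ratios` (named list of matrices),
#'   `topography_ratios` (named list), `masked` (named count of masked
#'   foreground pixels per map).
#' @export
log_ratio_maps <- function(set, mask,
                           pairs = list(c(1742, 1600), c(1708, 1600))) {
  stopifnot(inherits(set, "afmir_set"), inherits(mask, "segmentation_mask"))
  if (!any(mask$foreground)) stop("empty foreground")
  masked <- integer(0)
  log_ratio <- function(num, den) {
    out <- matrix(NA_real_, nrow(num), ncol(num))
    ok <- mask$foreground & num > 0 & den > 0
    out[ok] <- log10(num[ok] / den[ok])
    attr(out, "n_masked") <- sum(mask$foreground & !ok)
    out
  }
  abs_r <- list()
  for (pr in pairs) {
    nm <- sprintf("%g:%g", pr[1L], pr[2L])
    r <- log_ratio(set$maps[[format(pr[1L])]]$absorption,
                   set$maps[[format(pr[2L])]]$absorption)
    masked[nm] <- attr(r, "n_masked")
    abs_r[[nm]] <- r
  }
  topo_r <- list()
  for (nm in names(set$maps)) {
    r <- log_ratio(set$maps[[nm]]$absorption, set$maps[[nm]]$topography)
    masked[paste0("abs/topo ", nm)] <- attr(r, "n_masked")
    topo_r[[nm]] <- r
  }
  list(absorption_ratios = abs_r, topography_ratios = topo_r, masked = masked)
}

#' Preprocess repeated AFM-IR point spectra
#'
#' Repeat spectra from one acquisition point (typically 4-5) are
#' averaged, Savitzky-Golay smoothed (default window 15, order 1) and,
#' if a reference is supplied, EMSC-corrected against it. A
#' second-derivative variant (SG window 15, order 2, derivative 2 applied
#' after smoothing) is available for band resolution.
#'
#' @param repeats an [ir_collection()] of repeat spectra on one axis.
#' @param sg smoothing parameters (default `sg_params(15, 1, 0)`).
#' @param reference optional [ir_spectrum()] EMSC reference (e.g. the
#'   mean over all acquisition points).
#' @param second_derivative also return the SG second derivative.
#' @return An [ir_spectrum()]; if `second_derivative`, a list
#'   `(spectrum, second_derivative)`.
#' @export
preprocess_point_spectra <- function(repeats, sg = sg_params(15L, 1L, 0L),
                                     reference = NULL,
                                     second_derivative = FALSE) {
  stopifnot(inherits(repeats, "ir_collection"))
  avg <- mean_spectrum(repeats)
  sm <- savitzky_golay(avg, sg)
  if (!is.null(reference)) {
    coll <- ir_collection(sm$wavenumber, matrix(sm$absorbance, 1L))
    sm <- get_spectrum(
      emsc_fit_correct(coll, reference = reference, poly_order = 2L)$corrected, 1L)
  }
  if (!second_derivative) return(sm)
  d2 <- savitzky_golay(sm, sg_params(15L, 2L, 2L))
  list(spectrum = sm, second_derivative = d2)
}
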