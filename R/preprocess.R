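# Bulk-spectrum preprocessing: absorbance computation, Savitzky-Golay
# smoothing/derivatives, EMSC correction, spectral-region selection and
# replicate averaging.

#' Compute absorbance from single-beam sample and background intensities
#'
#' Absorbance is the negative base-10 logarithm of the ratio of the sample
#' to the background single-beam spectrum: A = -log10(S/B).
#'
#' @param sample numeric sample intensity vector.
#' @param background numeric background intensity vector, same axis,
#'   strictly positive.
#' @param wavenumber ascending axis in cm^-1.
#' @param meta metadata for the resulting spectrum.
#' @return An [ir_spectrum()] of absorbance.
#' @examples
#' w <- seq(1000, 1800, by = 4)
#' s <- compute_absorbance(rep(0.5, length(w)), rep(1, length(w)), w)
#' all.equal(s$absorbance, rep(log10(2), length(w)))
#' @export
compute_absorbance <- function(sample, background, wavenumber, meta = list()) {
  if (length(sample) != length(background))
    stop("sample and background must share one axis")
  if (any(background <= 0)) stop("background intensity must be strictly positive")
  if (any(sample <= 0)) stop("sample intensity must be strictly positive")
  ir_spectrum(wavenumber, -log10(sample / background), meta)
}

#' Savitzky-Golay parameters
#'
#' @param window odd window length in points (default 15).
#' @param polyorder polynomial order (default 2), less than `window`.
#' @param deriv derivative order (default 0), at most `polyorder`.
#' @return List of class `sg_params`.
#' @export
sg_params <- function(window = 15L, polyorder = 2L, deriv = 0L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2L == 0L) stop("SG window must be odd")
  if (polyorder >= window) stop("SG polynomial order must be below the window length")
  if (deriv < 0L || deriv > polyorder)
    stop("derivative order must be between 0 and the polynomial order")
  structure(list(window = window, polyorder = polyorder, deriv = deriv),
            class = "sg_params")
}

# filter a plain numeric vector; derivative is with respect to wavenumber,
# so a quadratic a*w^2 has second derivative exactly 2a.
sg_filter_vec <- function(x, p, spacing) {
  if (length(x) < p$window)
    stop("signal length (", length(x), ") shorter than SG window (", p$window, ")")
  as.numeric(signal::sgolayfilt(x, p = p$polyorder, n = p$window,
                                m = p$deriv, ts = spacing))
}

#' Apply a Savitzky-Golay filter to a spectrum or collection
#'
#' Local least-squares polynomial smoothing, optionally returning a
#' derivative. Derivatives are taken with respect to wavenumber (cm^-1),
#' assuming an evenly spaced axis; the output has the same length as the
#' input, with edge points obtained from the polynomial fitted at the
#' nearest full window.
#'
#' @param x an [ir_spectrum()] or [ir_collection()].
#' @param p an [sg_params()] object.
#' @return Same class as `x`, filtered.
#' @export
savitzky_golay <- function(x, p = sg_params()) {
  stopifnot(inherits(p, "sg_params"))
  if (inherits(x, "ir_spectrum")) {
    sp <- axis_resolution(x$wavenumber)
    ir_spectrum(x$wavenumber, sg_filter_vec(x$absorbance, p, sp), x$meta)
  } else if (inherits(x, "ir_collection")) {
    sp <- axis_resolution(x$wavenumber)
    out <- t(apply(x$data, 1L, sg_filter_vec, p = p, spacing = sp))
    rownames(out) <- rownames(x$data)
    ir_collection(x$wavenumber, out, x$meta)
  } else stop("x must be an ir_spectrum or ir_collection")
}

#' Fit and apply extended multiplicative signal correction (EMSC)
#'
#' Each spectrum s is modelled by least squares as
#' s = a + b m + d1 t + d2 t^2 + e, where m is the reference spectrum and
#' t is the wavenumber axis mapped affinely onto \[-1, 1\] (for numerical
#' conditioning). The corrected spectrum is (s - a - d1 t - d2 t^2) / b,
#' which removes additive baseline, multiplicative scaling and polynomial
#' baseline trends while preserving the chemical signal.
#'
#' @param coll an [ir_collection()].
#' @param reference an [ir_spectrum()] on the same axis, or `"mean"`
#'   (default) for the collection mean.
#' @param poly_order polynomial baseline order, 0, 1 or 2 (default 2).
#' @param b_tol spectra whose multiplicative coefficient has `|b|` below
#'   this tolerance are flagged and returned uncorrected.
#' @return List with elements `corrected` (an `ir_collection`), and
#'   `model` (class `emsc_model`: the reference, polynomial order, a
#'   coefficient table with columns `a`, `b`, `d1`, `d2`, and a logical
#'   `flagged` vector).
#' @examples
#' w <- seq(1000, 1800, by = 4)
#' m <- exp(-((w - 1650) / 30)^2)
#' coll <- ir_collection(w, rbind(2 + 3 * m, m))
#' fit <- emsc_fit_correct(coll, ir_spectrum(w, m))
#' fit$model$coefficients[1, c("a", "b")]  # (2, 3)
#' @export
emsc_fit_correct <- function(coll, reference = "mean", poly_order = 2L,
                             b_tol = 1e-8) {
  stopifnot(inherits(coll, "ir_collection"))
  poly_order <- as.integer(poly_order)
  if (poly_order < 0L || poly_order > 2L) stop("poly_order must be 0, 1 or 2")
  if (identical(reference, "mean")) reference <- mean_spectrum(coll)
  stopifnot(inherits(reference, "ir_spectrum"))
  if (!isTRUE(all.equal(reference$wavenumber, coll$wavenumber)))
    stop("reference axis does not match collection axis")
  m <- reference$absorbance
  if (stats::sd(m) == 0) stop("reference spectrum is constant")
  w <- coll$wavenumber
  t1 <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
  basis <- cbind(offset = rep(1, length(w)))
  if (poly_order >= 1L) basis <- cbind(basis, d1 = t1)
  if (poly_order >= 2L) basis <- cbind(basis, d2 = t1^2)
  X <- cbind(basis, b = m)
  fit <- stats::lm.fit(X, t(coll$data))
  cf <- t(fit$coefficients)  # n_spectra x ncol(X)
  b <- cf[, "b"]
  flagged <- abs(b) < b_tol
  corrected <- coll$data
  baseline <- cf[, colnames(basis), drop = FALSE] %*% t(basis)
  ok <- !flagged
  if (any(ok))
    corrected[ok, ] <- (coll$data[ok, , drop = FALSE] -
                          baseline[ok, , drop = FALSE]) / b[ok]
  coefs <- data.frame(a = cf[, "offset"],
                      b = b,
                      d1 = if (poly_order >= 1L) cf[, "d1"] else 0,
                      d2 = if (poly_order >= 2L) cf[, "d2"] else 0,
                      row.names = rownames(coll$data))
  model <- structure(list(reference = reference, poly_order = poly_order,
                          coefficients = coefs, flagged = flagged),
                     class = "emsc_model")
  list(corrected = ir_collection(coll$wavenumber, corrected, coll$meta),
       model = model)
}

#' @export
print.emsc_model <- function(x, ...) {
  cat("<emsc_model> polynomial order ", x$poly_order, ", ",
      nrow(x$coefficients), " spectra fitted",
      if (any(x$flagged)) paste0(" (", sum(x$flagged), " flagged degenerate)"),
      "\n", sep = "")
  cat("  b range: ", paste(format(range(x$coefficients$b), digits = 4),
                           collapse = " to "), "\n", sep = "")
  invisible(x)
}

#' Spectral region presets and construction
#'
#' A spectral region is a union of closed wavenumber intervals. Named
#' presets follow the biochemical window convention for fungal biomass:
#' `lipid_combined` (3050--2800 and 1800--1700 cm^-1), `protein`
#' (1700--1500), `mixed` (1500--1200), `polysaccharide` (1200--700),
#' `protein_mixed` (1700--1200) and `full` (4000--700).
#'
#' @param x a preset name, or a numeric matrix/2-column data source with
#'   one `(lo, hi)` interval per row.
#' @return Matrix of class `spectral_region` with columns `lo`, `hi`,
#'   intervals sorted and merged so they do not overlap.
#' @examples
#' spectral_region("lipid_combined")
#' spectral_region(rbind(c(1700, 1500), c(1550, 1400)))  # merged
#' @export
spectral_region <- function(x) {
  presets <- list(
    lipid_combined = rbind(c(2800, 3050), c(1700, 1800)),
    protein        = rbind(c(1500, 1700)),
    mixed          = rbind(c(1200, 1500)),
    polysaccharide = rbind(c(700, 1200)),
    protein_mixed  = rbind(c(1200, 1700)),
    full           = rbind(c(700, 4000)))
  if (is.character(x)) {
    x <- presets[[match.arg(x, names(presets))]]
  }
  x <- matrix(as.numeric(x), ncol = 2L)
  x <- t(apply(x, 1L, sort))
  x <- x[order(x[, 1L]), , drop = FALSE]
  # merge overlapping/adjacent intervals
  merged <- x[1L, , drop = FALSE]
  if (nrow(x) > 1L) for (i in 2L:nrow(x)) {
    k <- nrow(merged)
    if (x[i, 1L] <= merged[k, 2L]) {
      merged[k, 2L] <- max(merged[k, 2L], x[i, 2L])
    } else merged <- rbind(merged, x[i, , drop = FALSE])
  }
  colnames(merged) <- c("lo", "hi")
  structure(merged, class = c("spectral_region", "matrix"))
}

#' Restrict a spectrum or collection to a spectral region
#'
#' @param x an [ir_spectrum()], [ir_collection()] or [hyper_cube()].
#' @param region a [spectral_region()] or preset name.
#' @return Same class as `x`, with the axis restricted to the union of
#'   the region's intervals (disjoint blocks are concatenated).
#' @export
select_region <- function(x, region) {
  region <- spectral_region(region)
  pick <- function(w) {
    keep <- rep(FALSE, length(w))
    for (i in seq_len(nrow(region)))
      keep <- keep | (w >= region[i, "lo"] & w <= region[i, "hi"])
    keep
  }
  if (inherits(x, "ir_spectrum")) {
    keep <- pick(x$wavenumber)
    if (!any(keep)) stop("region does not intersect the spectrum axis")
    ir_spectrum(x$wavenumber[keep], x$absorbance[keep], x$meta)
  } else if (inherits(x, "ir_collection")) {
    keep <- pick(x$wavenumber)
    if (!any(keep)) stop("region does not intersect the collection axis")
    ir_collection(x$wavenumber[keep], x$data[, keep, drop = FALSE], x$meta)
  } else if (inherits(x, "hyper_cube")) {
    keep <- pick(x$wavenumber)
    if (!any(keep)) stop("region does not intersect the cube axis")
    hyper_cube(x$values[, , keep, drop = FALSE], x$wavenumber[keep],
               x$pixel_size)
  } else stop("unsupported input class")
}

#' Average technical replicates within design groups
#'
#' @param coll an [ir_collection()] whose metadata contains the grouping
#'   factors.
#' @param by character vector of metadata column names to group by.
#' @return An `ir_collection` with one mean spectrum per group; the
#'   metadata keeps the grouping columns plus a `group_size` count.
#' @export
average_replicates <- function(coll, by) {
  stopifnot(inherits(coll, "ir_collection"))
  missing_by <- setdiff(by, names(coll$meta))
  if (length(missing_by))
    stop("grouping factors absent from metadata: ",
         paste(missing_by, collapse = ", "))
  key <- interaction(coll$meta[by], drop = TRUE, lex.order = TRUE)
  if (any(table(key) == 0L)) stop("empty replicate group")
  groups <- split(seq_len(nrow(coll$data)), key)
  out <- t(vapply(groups, function(idx) colMeans(coll$data[idx, , drop = FALSE]),
                  numeric(ncol(coll$data))))
  meta <- do.call(rbind, lapply(groups, function(idx)
    coll$meta[idx[1L], by, drop = FALSE]))
  meta$group_size <- lengths(groups)
  meta$spectrum_id <- names(groups)
  rownames(out) <- names(groups)
  ir_collection(coll$wavenumber, out, meta)
}
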