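#' @keywords internal
"_PACKAGE"

# Core spectral containers.
#
# All wavenumber axes are stored ascending, in cm^-1, as numeric (double)
# vectors; instrument files with descending axes are normalised on read.
# Absorbance is unitless. Images are 0-based conceptually but stored as
# ordinary R matrices (row 1 = top scan line).

#' Validate a wavenumber axis
#'
#' A valid axis is a strictly increasing numeric vector of positive
#' wavenumbers (cm^-1) with at least two points.
#'
#' @param wavenumber numeric vector of wavenumbers in cm^-1.
#' @return The axis, invisibly, if valid; otherwise an error is thrown.
#' @keywords internal
validate_axis <- function(wavenumber) {
  if (!is.numeric(wavenumber) || length(wavenumber) < 2L)
    stop("wavenumber axis must be numeric with at least 2 points")
  if (anyNA(wavenumber) || any(!is.finite(wavenumber)))
    stop("wavenumber axis contains non-finite values")
  if (any(wavenumber <= 0))
    stop("wavenumbers must be positive (cm^-1)")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing (duplicate or unsorted values)")
  invisible(wavenumber)
}

#' Nominal axis resolution
#'
#' Median spacing of an axis in cm^-1, used when choosing a common grid.
#'
#' @param wavenumber numeric axis.
#' @return Scalar spacing in cm^-1.
#' @keywords internal
axis_resolution <- function(wavenumber) stats::median(diff(wavenumber))

#' Construct a single infrared spectrum
#'
#' @param wavenumber ascending numeric axis in cm^-1.
#' @param absorbance numeric vector of absorbance values, same length.
#' @param meta named list of metadata (e.g. `technique`, `sample`,
#'   `pi_level`, `replicate`, `day`). `technique` if given must be one of
#'   `"HTS"`, `"ATR"`, `"AFMIR_POINT"`.
#' @return An object of class `ir_spectrum`: a list with elements
#'   `wavenumber`, `absorbance`, `meta`.
#' @examples
#' s <- ir_spectrum(seq(1000, 1800, by = 4), rep(0.1, 201))
#' print(s)
#' @export
ir_spectrum <- function(wavenumber, absorbance, meta = list()) {
  validate_axis(wavenumber)
  if (length(absorbance) != length(wavenumber))
    stop("absorbance length (", length(absorbance),
         ") does not match axis length (", length(wavenumber), ")")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance contains non-finite values at index ",
         which(!is.finite(absorbance))[1L])
  if (!is.null(meta$technique))
    meta$technique <- match.arg(meta$technique, c("HTS", "ATR", "AFMIR_POINT"))
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = as.numeric(absorbance),
                 meta = meta),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat("<ir_spectrum> ", length(x$wavenumber), " points, ",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)), " cm^-1",
      if (!is.null(x$meta$technique)) paste0(" [", x$meta$technique, "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.ir_spectrum <- function(x, xlab = expression(tilde(nu) ~ (cm^-1)),
                             ylab = "Absorbance", rev_x = TRUE, type = "l", ...) {
  xlim <- if (rev_x) rev(range(x$wavenumber)) else range(x$wavenumber)
  graphics::plot(x$wavenumber, x$absorbance, type = type,
                 xlab = xlab, ylab = ylab, xlim = xlim, ...)
  invisible(x)
}

#' Construct a collection of spectra on a shared axis
#'
#' The collection is the workhorse container for designed measurement
#' campaigns: a spectra-by-channel matrix plus a metadata table with one
#' row per spectrum (design factors such as phosphate condition, replicate
#' and storage day).
#'
#' @param wavenumber shared ascending axis in cm^-1.
#' @param data numeric matrix, one row per spectrum, `length(wavenumber)`
#'   columns. Row names are used as spectrum ids (generated if absent).
#' @param meta data.frame with one row per spectrum. A `spectrum_id`
#'   column is added from the data row names if missing.
#' @return An object of class `ir_collection`.
#' @export
ir_collection <- function(wavenumber, data, meta = NULL) {
  validate_axis(wavenumber)
  data <- as.matrix(data)
  if (ncol(data) != length(wavenumber))
    stop("data has ", ncol(data), " columns but axis has ",
         length(wavenumber), " points")
  if (nrow(data) < 1L) stop("collection must contain at least one spectrum")
  bad <- which(!is.finite(data))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(data))
    stop("non-finite absorbance in spectrum ", rc[1L], ", channel ", rc[2L])
  }
  if (is.null(rownames(data)) || anyDuplicated(rownames(data)) ||
      any(!nzchar(rownames(data))))
    rownames(data) <- paste0("s", seq_len(nrow(data)))
  if (is.null(meta)) {
    meta <- data.frame(spectrum_id = rownames(data), stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != nrow(data))
      stop("meta has ", nrow(meta), " rows for ", nrow(data), " spectra")
    if (is.null(meta$spectrum_id)) meta$spectrum_id <- rownames(data)
  }
  rownames(meta) <- NULL
  structure(list(wavenumber = as.numeric(wavenumber), data = data, meta = meta),
            class = "ir_collection")
}

#' Number of spectra in a collection
#' @param coll an `ir_collection`.
#' @return Integer count.
#' @export
n_spectra <- function(coll) nrow(coll$data)

#' @export
print.ir_collection <- function(x, ...) {
  cat("<ir_collection> ", nrow(x$data), " spectra x ", ncol(x$data),
      " channels, ", format(min(x$wavenumber)), "-", format(max(x$wavenumber)),
      " cm^-1\n", sep = "")
  extra <- setdiff(names(x$meta), "spectrum_id")
  if (length(extra)) cat("  metadata: ", paste(extra, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.ir_collection <- function(x, ...) x$data

#' Extract one spectrum from a collection
#'
#' @param coll an `ir_collection`.
#' @param i row index or spectrum id.
#' @return An `ir_spectrum` carrying that row's metadata.
#' @export
get_spectrum <- function(coll, i) {
  if (is.character(i)) i <- match(i, coll$meta$spectrum_id)
  if (is.na(i) || i < 1L || i > nrow(coll$data)) stop("no such spectrum")
  ir_spectrum(coll$wavenumber, coll$data[i, ], as.list(coll$meta[i, , drop = FALSE]))
}

#' Mean spectrum of a collection
#'
#' @param coll an `ir_collection`.
#' @return An `ir_spectrum` whose absorbance is the channel-wise mean.
#' @export
mean_spectrum <- function(coll) {
  ir_spectrum(coll$wavenumber, colMeans(coll$data),
              list(sample = "mean", n = nrow(coll$data)))
}

#' Band definitions for synthesis and interpretation
#'
#' A band definition library is a data.frame with one Gaussian (or
#' Lorentzian) band per row, assigning each band to a biochemical
#' component. It drives both the forward simulator and the interpretation
#' of picked peaks.
#'
#' @param center band centre in cm^-1, within 400--4000.
#' @param half_width band half-width in cm^-1, positive.
#' @param relative_amplitude non-negative amplitude relative to the
#'   component's strongest band.
#' @param component component label; one of `TAG`, `FFA`, `FFA_ionized`,
#'   `protein`, `polysaccharide`, `polyphosphate`, `CH_chain`,
#'   `unsaturation`, `water`.
#' @param assignment free-text vibrational assignment.
#' @return data.frame of class `band_library`.
#' @seealso [default_band_library()]
#' @export
band_definition <- function(center, half_width, relative_amplitude,
                            component, assignment = "") {
  comp_levels <- c("TAG", "FFA", "FFA_ionized", "protein", "polysaccharide",
                   "polyphosphate", "CH_chain", "unsaturation", "water")
  stopifnot(all(center >= 400 & center <= 4000),
            all(half_width > 0),
            all(relative_amplitude >= 0))
  if (!all(component %in% comp_levels))
    stop("unknown component: ",
         paste(setdiff(component, comp_levels), collapse = ", "))
  structure(data.frame(center = center, half_width = half_width,
                       relative_amplitude = relative_amplitude,
                       component = component, assignment = assignment,
                       stringsAsFactors = FALSE),
            class = c("band_library", "data.frame"))
}
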