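# Transmission (HTS) vs attenuated-total-reflectance (ATR) comparison:
# interpolation onto a common axis, second-derivative peak selection,
# greedy closest-counterpart peak matching with shift computation, and
# lipid band-ratio tables.

#' Interpolate two collections onto a common wavenumber grid
#'
#' The common grid spans the overlap of the two axes at the coarser
#' nominal resolution; both collections are linearly interpolated onto it.
#'
#' @param a,b [ir_collection()] objects with overlapping axes.
#' @return List with elements `a` and `b`, the aligned collections.
#' @export
align_axes <- function(a, b) {
  stopifnot(inherits(a, "ir_collection"), inherits(b, "ir_collection"))
  lo <- max(min(a$wavenumber), min(b$wavenumber))
  hi <- min(max(a$wavenumber), max(b$wavenumber))
  if (lo >= hi) stop("wavenumber ranges do not overlap")
  step <- max(axis_resolution(a$wavenumber), axis_resolution(b$wavenumber))
  grid <- seq(lo, hi, by = step)
  interp <- function(coll) {
    out <- t(apply(coll$data, 1L, function(y)
      stats::approx(coll$wavenumber, y, xout = grid)$y))
    rownames(out) <- rownames(coll$data)
    ir_collection(grid, out, coll$meta)
  }
  list(a = interp(a), b = interp(b))
}

#' Pick band maxima from the Savitzky-Golay second derivative
#'
#' Absorption band maxima appear as local minima of the second
#' derivative. Within the requested region the SG second derivative is
#' computed and its local minima kept if their depth (negative excursion)
#' exceeds `prominence` times the deepest minimum in the region.
#'
#' @param sp an [ir_spectrum()] (typically a mean sample spectrum).
#' @param region a [spectral_region()] or preset name.
#' @param sg [sg_params()]; the default (window 15, order 2, derivative 2)
#'   is the standard second-derivative setting.
#' @param prominence relative depth threshold in (0, 1); default 0.05.
#' @param instrument tag recorded in the result.
#' @return data.frame of class `peak_list`, sorted ascending, with
#'   columns `position` (cm^-1), `absorbance` (of the input spectrum at
#'   the peak) and `depth` (positive second-derivative depth).
#' @export
pick_peaks <- function(sp, region = "full", sg = sg_params(15L, 2L, 2L),
                       prominence = 0.05, instrument = sp$meta$technique) {
  stopifnot(inherits(sp, "ir_spectrum"))
  if (length(sp$wavenumber) < sg$window)
    stop("SG window exceeds the spectrum length")
  # filter the full spectrum first, then restrict: filtering a
  # region-restricted signal would create edge artifacts at every
  # interval boundary of a disjoint region
  d2_full <- sg_filter_vec(sp$absorbance, sg, axis_resolution(sp$wavenumber))
  sub <- select_region(sp, region)
  d2 <- d2_full[match(sub$wavenumber, sp$wavenumber)]
  n <- length(d2)
  out <- data.frame(position = numeric(0), absorbance = numeric(0),
                    depth = numeric(0))
  if (n >= 3L) {
    is_min <- d2[2:(n - 1L)] < d2[1:(n - 2L)] & d2[2:(n - 1L)] <= d2[3:n] &
      d2[2:(n - 1L)] < 0
    idx <- which(is_min) + 1L
    if (length(idx)) {
      depth <- -d2[idx]
      # floor guards against numerical noise on featureless spectra
      if (max(depth) < 1e-12) idx <- integer(0)
      else idx <- idx[depth >= prominence * max(depth)]
      if (length(idx))
        out <- data.frame(position = sub$wavenumber[idx],
                          absorbance = sub$absorbance[idx],
                          depth = -d2[idx])
    }
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "instrument") <- if (is.null(instrument)) NA_character_ else instrument
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Match peaks between two instruments
#'
#' Greedy one-to-one nearest-neighbour matching: candidate pairs within
#' `window` cm^-1 are accepted in order of ascending distance (ties broken
#' by lower wavenumber), each peak used at most once. The shift is
#' reported as (b position - a position); with a = HTS and b = ATR this is
#' the ATR displacement.
#'
#' @param a,b [pick_peaks()] results (e.g. HTS and ATR).
#' @param window maximum matching distance in cm^-1 (default 20).
#' @return data.frame of class `peak_match_table` with columns
#'   `a_position`, `b_position`, `shift`, `matched`; unmatched peaks from
#'   either list appear as rows with `matched = FALSE`.
#' @export
match_peaks <- function(a, b, window = 20) {
  pa <- a$position; pb <- b$position
  if (length(pa) && length(pb)) {
    cand <- expand.grid(i = seq_along(pa), j = seq_along(pb))
    cand$dist <- abs(pa[cand$i] - pb[cand$j])
    cand <- cand[cand$dist <= window, , drop = FALSE]
    cand <- cand[order(cand$dist, pmin(pa[cand$i], pb[cand$j])), , drop = FALSE]
  } else cand <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  used_a <- logical(length(pa)); used_b <- logical(length(pb))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    rows[[length(rows) + 1L]] <-
      data.frame(a_position = pa[i], b_position = pb[j],
                 shift = pb[j] - pa[i], matched = TRUE)
  }
  for (i in which(!used_a))
    rows[[length(rows) + 1L]] <- data.frame(a_position = pa[i],
                                            b_position = NA_real_,
                                            shift = NA_real_, matched = FALSE)
  for (j in which(!used_b))
    rows[[length(rows) + 1L]] <- data.frame(a_position = NA_real_,
                                            b_position = pb[j],
                                            shift = NA_real_, matched = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a_position = numeric(0), b_position = numeric(0),
               shift = numeric(0), matched = logical(0))
  out <- out[order(is.na(out$a_position), out$a_position, out$b_position), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_match_table", "data.frame")
  out
}

#' Absorbance ratios at detected counterparts of nominal band positions
#'
#' For each spectrum, each nominal position in a pair is replaced by the
#' detected second-derivative peak closest to it (within `window`); the
#' ratio of the spectrum's absorbance at those two detected positions is
#' reported. Rows where either peak is absent are flagged, not dropped.
#'
#' @param coll an [ir_collection()].
#' @param pairs list of numeric pairs `(numerator, denominator)` in
#'   cm^-1; defaults to the lipid/protein trio (1742, 1650), (3010, 1742),
#'   (3010, 1650).
#' @param window peak search window in cm^-1 (default 20).
#' @param sg [sg_params()] for the underlying peak picking.
#' @param prominence relative depth threshold passed to [pick_peaks()].
#' @return data.frame of class `ratio_table`: one row per spectrum and
#'   pair, with detected positions, the ratio, and an `ok` flag.
#' @export
band_ratios <- function(coll, pairs = list(c(1742, 1650), c(3010, 1742),
                                           c(3010, 1650)),
                        window = 20, sg = sg_params(15L, 2L, 2L),
                        prominence = 0.05) {
  stopifnot(inherits(coll, "ir_collection"))
  rows <- list()
  for (i in seq_len(nrow(coll$data))) {
    sp <- get_spectrum(coll, i)
    pk <- pick_peaks(sp, "full", sg = sg, prominence = prominence)
    nearest <- function(nominal) {
      if (!nrow(pk)) return(NA_real_)
      d <- abs(pk$position - nominal)
      if (min(d) > window) return(NA_real_)
      pk$position[which.min(d)]
    }
    for (pr in pairs) {
      p_num <- nearest(pr[1L]); p_den <- nearest(pr[2L])
      ok <- !is.na(p_num) && !is.na(p_den)
      a_num <- if (!is.na(p_num))
        sp$absorbance[which.min(abs(sp$wavenumber - p_num))] else NA_real_
      a_den <- if (!is.na(p_den))
        sp$absorbance[which.min(abs(sp$wavenumber - p_den))] else NA_real_
      ratio <- if (ok && is.finite(a_den) && a_den != 0) a_num / a_den else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = coll$meta$spectrum_id[i],
        nominal_num = pr[1L], nominal_den = pr[2L],
        position_num = p_num, position_den = p_den,
        ratio = ratio, ok = ok && !is.na(ratio))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ratio_table", "data.frame")
  out
}
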