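# Readers and writers for the on-disk formats:
#   * spectra: CSV matrix (wavenumber column + one column per spectrum)
#     with a CSV metadata sidecar keyed by spectrum_id,
#   * hyperspectral cubes: JSON header + raw little-endian float32,
#     band-sequential,
#   * AFM-IR map sets: per-wavenumber TSV matrices + JSON metadata +
#     two-column laser-power CSV.
# These formats are conventions of this package, not instrument formats.

#' Read a spectra matrix with its metadata sidecar
#'
#' The data file is comma-separated with a header row; the first column is
#' the wavenumber axis, remaining columns are spectra named by id. The
#' sidecar has one row per spectrum keyed by `spectrum_id`, with design
#' columns `technique`, `sample`, `pi_level`, `replicate`, `day`.
#' Descending axes (instrument order) are normalised to ascending.
#'
#' @param path path to the spectra CSV.
#' @param meta_path path to the sidecar CSV.
#' @return An [ir_collection()].
#' @export
read_spectra <- function(path, meta_path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2L) stop("spectra file must have a wavenumber column and at least one spectrum")
  w <- as.numeric(tab[[1L]])
  mat <- t(as.matrix(tab[, -1L, drop = FALSE]))
  ord <- order(w)
  w <- w[ord]
  mat <- mat[, ord, drop = FALSE]
  validate_axis(w)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (is.null(meta$spectrum_id)) stop("sidecar must have a spectrum_id column")
  ids <- rownames(mat)
  missing_meta <- setdiff(ids, meta$spectrum_id)
  if (length(missing_meta))
    stop("sidecar is missing spectrum ids: ", paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(meta$spectrum_id, ids)
  if (length(extra_meta))
    stop("sidecar lists spectra absent from the data file: ",
         paste(extra_meta, collapse = ", "))
  meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  ir_collection(w, mat, meta)
}

#' Write a spectra matrix and metadata sidecar
#'
#' Inverse of [read_spectra()]: values are written as text with 9
#' significant digits, so a round trip reproduces the collection to
#' single-precision accuracy.
#'
#' @param coll an [ir_collection()].
#' @param path output path for the spectra CSV.
#' @param meta_path output path for the sidecar CSV; defaults to
#'   `path` with a `_meta.csv` suffix.
#' @param descending write the axis in descending (instrument) order.
#' @return Invisibly, the paths written.
#' @export
write_spectra <- function(coll, path, meta_path = NULL, descending = FALSE) {
  stopifnot(inherits(coll, "ir_collection"))
  if (nrow(coll$data) < 1L) stop("refusing to write an empty collection")
  if (is.null(meta_path))
    meta_path <- paste0(sub("\\.csv$", "", path), "_meta.csv")
  idx <- if (descending) rev(seq_along(coll$wavenumber)) else seq_along(coll$wavenumber)
  tab <- data.frame(wavenumber = formatC(coll$wavenumber[idx], format = "g", digits = 9))
  for (i in seq_len(nrow(coll$data)))
    tab[[rownames(coll$data)[i]]] <-
      formatC(coll$data[i, idx], format = "g", digits = 9)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(coll$meta, meta_path, row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Construct a hyperspectral cube
#'
#' @param values numeric array `rows x cols x n_wavenumbers` of absorbance.
#' @param wavenumber ascending axis, length `dim(values)[3]`.
#' @param pixel_size pixel pitch in micrometres.
#' @return Object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, wavenumber, pixel_size = 0.7) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  validate_axis(wavenumber)
  if (dim(values)[3L] != length(wavenumber))
    stop("cube has ", dim(values)[3L], " bands but axis has ",
         length(wavenumber), " points")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop("non-finite value at pixel (", rc[1L], ",", rc[2L], "), band ", rc[3L])
  }
  structure(list(values = values, wavenumber = as.numeric(wavenumber),
                 pixel_size = pixel_size),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat("<hyper_cube> ", d[1L], "x", d[2L], " px x ", d[3L], " bands, ",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)),
      " cm^-1, ", x$pixel_size, " um/px\n", sep = "")
  invisible(x)
}

#' Read a hyperspectral cube (JSON header + raw float32)
#'
#' The header declares `rows`, `cols`, `pixel_size_um`, `wavenumbers`,
#' `byte_order` (`"little"`) and `data_file` (relative to the header).
#' The payload is band-sequential little-endian float32: band 1 as a full
#' row-major image, then band 2, and so on.
#'
#' @param header_path path to the JSON header.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(header_path) {
  hdr <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  need <- c("rows", "cols", "wavenumbers", "data_file")
  if (!all(need %in% names(hdr)))
    stop("cube header missing fields: ", paste(setdiff(need, names(hdr)), collapse = ", "))
  w <- as.numeric(hdr$wavenumbers)
  nb <- length(w)
  if (!is.null(hdr$n_wavenumbers) && hdr$n_wavenumbers != nb)
    stop("header n_wavenumbers (", hdr$n_wavenumbers,
         ") disagrees with wavenumber list length (", nb, ")")
  raw_path <- file.path(dirname(header_path), hdr$data_file)
  n_expect <- hdr$rows * hdr$cols * nb
  sz <- file.info(raw_path)$size
  if (is.na(sz) || sz != n_expect * 4L)
    stop("raw payload is ", sz, " bytes; expected ", n_expect * 4L,
         " (", hdr$rows, "x", hdr$cols, "x", nb, " float32)")
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n_expect, size = 4L, endian = "little")
  ord <- order(w)
  # payload is row-major per band; R arrays are column-major
  arr <- aperm(array(vals, dim = c(hdr$cols, hdr$rows, nb)), c(2L, 1L, 3L))
  hyper_cube(arr[, , ord, drop = FALSE], w[ord],
             pixel_size = if (is.null(hdr$pixel_size_um)) 0.7 else hdr$pixel_size_um)
}

#' Write a hyperspectral cube (JSON header + raw float32)
#'
#' @param cube a [hyper_cube()].
#' @param header_path output path for the JSON header; the raw payload is
#'   written next to it with extension `.raw`.
#' @return Invisibly, the header path.
#' @export
write_cube <- function(cube, header_path) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  data_file <- paste0(tools::file_path_sans_ext(basename(header_path)), ".raw")
  hdr <- list(rows = d[1L], cols = d[2L], n_wavenumbers = d[3L],
              pixel_size_um = cube$pixel_size, byte_order = "little",
              wavenumbers = cube$wavenumber, data_file = data_file)
  jsonlite::write_json(hdr, header_path, auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dirname(header_path), data_file), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube$values, c(2L, 1L, 3L))), con,
           size = 4L, endian = "little")
  invisible(header_path)
}

#' Construct a laser-power (background) spectrum
#'
#' Relative emitted power of the tunable QCL source over its range, used
#' to normalise AFM-IR absorption maps and point spectra.
#'
#' @param wavenumber ascending axis in cm^-1 (QCL range).
#' @param power strictly positive relative power.
#' @return Object of class `laser_power`.
#' @export
laser_power <- function(wavenumber, power) {
  validate_axis(wavenumber)
  if (length(power) != length(wavenumber))
    stop("power length does not match axis")
  if (any(!is.finite(power)) || any(power <= 0))
    stop("laser power must be finite and strictly positive")
  structure(list(wavenumber = as.numeric(wavenumber), power = as.numeric(power)),
            class = "laser_power")
}

#' Interpolated laser power at a wavenumber
#' @param lp a [laser_power()] object.
#' @param wavenumber scalar wavenumber within the power axis range.
#' @return Scalar relative power.
#' @export
power_at <- function(lp, wavenumber) {
  if (wavenumber < min(lp$wavenumber) || wavenumber > max(lp$wavenumber))
    stop("wavenumber ", wavenumber, " outside laser power range [",
         min(lp$wavenumber), ", ", max(lp$wavenumber), "]")
  stats::approx(lp$wavenumber, lp$power, xout = wavenumber)$y
}

#' Construct an AFM-IR map set
#'
#' Co-registered per-wavenumber AFM/AFM-IR acquisitions: for each acquired
#' wavenumber a topography map (height), a deflection map and an
#' absorption map, all the same shape, plus the scan size and the laser
#' power spectrum.
#'
#' @param maps named list (names = wavenumbers as character) of lists with
#'   elements `topography`, `deflection`, `absorption` (numeric matrices).
#' @param scan_size scan edge length in micrometres.
#' @param power a [laser_power()] covering all acquired wavenumbers.
#' @param meta optional named list (e.g. `truth` from the simulator).
#' @return Object of class `afmir_set`.
#' @export
afmir_set <- function(maps, scan_size, power, meta = list()) {
  wn <- as.numeric(names(maps))
  if (anyNA(wn)) stop("maps must be named by wavenumber")
  if (anyDuplicated(wn)) stop("duplicate wavenumbers in map set")
  shp <- NULL
  for (nm in names(maps)) {
    m <- maps[[nm]]
    need <- c("topography", "deflection", "absorption")
    if (!all(need %in% names(m)))
      stop("map set at ", nm, " cm^-1 missing: ",
           paste(setdiff(need, names(m)), collapse = ", "))
    for (role in need) {
      if (!is.matrix(m[[role]])) stop(role, " at ", nm, " cm^-1 is not a matrix")
      if (is.null(shp)) shp <- dim(m[[role]])
      if (!identical(dim(m[[role]]), shp))
        stop("shape mismatch: ", role, " at ", nm, " cm^-1 is ",
             paste(dim(m[[role]]), collapse = "x"), ", expected ",
             paste(shp, collapse = "x"))
    }
  }
  for (v in wn)
    if (v < min(power$wavenumber) || v > max(power$wavenumber))
      stop("acquired wavenumber ", v, " outside laser power range")
  structure(list(wavenumbers = wn, maps = maps, scan_size = scan_size,
                 power = power, pixel_size = scan_size / shp[2L], meta = meta),
            class = "afmir_set")
}

#' @export
print.afmir_set <- function(x, ...) {
  shp <- dim(x$maps[[1L]]$topography)
  cat("<afmir_set> ", length(x$wavenumbers), " wavenumbers (",
      paste(x$wavenumbers, collapse = ", "), " cm^-1), ",
      shp[1L], "x", shp[2L], " px, scan ", x$scan_size, " um\n", sep = "")
  invisible(x)
}

#' Read an AFM-IR map set from a directory
#'
#' Expects `metadata.json` (fields `wavenumbers`, `scan_size_um`),
#' `laser_power.csv` (columns wavenumber, power) and, for each wavenumber
#' W, files `topography_W.tsv`, `deflection_W.tsv`, `absorption_W.tsv`
#' holding plain numeric matrices.
#'
#' @param dir_path directory containing the set.
#' @return An [afmir_set()].
#' @export
read_afmir_set <- function(dir_path) {
  meta <- jsonlite::read_json(file.path(dir_path, "metadata.json"),
                              simplifyVector = TRUE)
  lp_tab <- utils::read.csv(file.path(dir_path, "laser_power.csv"))
  ordp <- order(lp_tab[[1L]])
  lp <- laser_power(lp_tab[[1L]][ordp], lp_tab[[2L]][ordp])
  maps <- list()
  for (w in meta$wavenumbers) {
    entry <- list()
    for (role in c("topography", "deflection", "absorption")) {
      f <- file.path(dir_path, sprintf("%s_%s.tsv", role, format(w)))
      if (!file.exists(f)) stop("missing map file: ", f)
      entry[[role]] <- as.matrix(utils::read.table(f, sep = "\t"))
    }
    entry <- lapply(entry, function(m) { dimnames(m) <- NULL; m })
    maps[[format(w)]] <- entry
  }
  afmir_set(maps, scan_size = meta$scan_size_um, power = lp)
}

#' Write an AFM-IR map set to a directory
#'
#' Inverse of [read_afmir_set()].
#'
#' @param set an [afmir_set()].
#' @param dir_path output directory (created if absent).
#' @return Invisibly, `dir_path`.
#' @export
write_afmir_set <- function(set, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(wavenumbers = set$wavenumbers,
                            scan_size_um = set$scan_size),
                       file.path(dir_path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(wavenumber = set$power$wavenumber,
                              power = set$power$power),
                   file.path(dir_path, "laser_power.csv"), row.names = FALSE)
  for (nm in names(set$maps))
    for (role in c("topography", "deflection", "absorption"))
      utils::write.table(set$maps[[nm]][[role]],
                         file.path(dir_path, sprintf("%s_%s.tsv", role, nm)),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(dir_path)
}
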