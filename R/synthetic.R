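# Forward models generating bulk spectra, designed measurement campaigns,
# FPA hyperspectral scenes and AFM-IR scenes with known ground truth.
# Every generator is deterministic given its seed; ground truth is
# returned alongside the data so recovery tests never re-derive it.

#' Default mid-infrared band library for fungal biomass
#'
#' Gaussian band centres follow the standard vibrational assignments for
#' oleaginous fungal biomass (ester carbonyl of triacylglycerides at
#' 1742 cm^-1, acid-dimer carbonyl of free fatty acids at 1708, amide I
#' at 1650, amide II at 1545, COO- of ionized fatty acids at 1600,
#' polysaccharide C-O-C near 1025, polyphosphate P=O at 1265, acyl C-H
#' stretches at 2955/2925/2855, =C-H unsaturation at 3010, C-H bends at
#' 1465/1415/1375). Relative amplitudes and widths are order-of-magnitude
#' modelling choices of this package, not measured values.
#'
#' @return A [band_definition()] library.
#' @export
default_band_library <- function() {
  rbind(
    band_definition(1742, 9, 1.00, "TAG", "C=O stretching (ester), total lipid content"),
    band_definition(1160, 16, 0.30, "TAG", "C-O-C antisymmetric stretching (esters)"),
    band_definition(1708, 9, 1.00, "FFA", "C=O stretching (carboxylic acid dimers)"),
    band_definition(1600, 18, 1.00, "FFA_ionized", "antisymmetric COO- stretching"),
    band_definition(1415, 12, 0.40, "FFA_ionized", "symmetric COO- / C-H deformation"),
    band_definition(1650, 16, 1.00, "protein", "amide I (C=O stretching)"),
    band_definition(1545, 16, 0.70, "protein", "amide II (N-H bending, C-N stretching)"),
    band_definition(3290, 55, 0.25, "protein", "amide A (N-H stretching)"),
    band_definition(1240, 18, 0.15, "protein", "amide III"),
    band_definition(1025, 22, 1.00, "polysaccharide", "C-O-C stretching (alkyl aryl ethers)"),
    band_definition(1080, 18, 0.60, "polysaccharide", "C-O stretching"),
    band_definition(895, 12, 0.10, "polysaccharide", "beta-glycosidic linkage"),
    band_definition(1265, 18, 1.00, "polyphosphate", "P=O asymmetrical stretching"),
    band_definition(885, 15, 0.25, "polyphosphate", "P-O-P stretching"),
    band_definition(2925, 16, 1.00, "CH_chain", "CH2 asymmetrical stretching"),
    band_definition(2855, 13, 0.60, "CH_chain", "CH2/CH3 symmetrical stretching"),
    band_definition(2955, 11, 0.45, "CH_chain", "CH3 asymmetrical stretching"),
    band_definition(1465, 12, 0.30, "CH_chain", "CH2/CH3 bending"),
    band_definition(1375, 10, 0.20, "CH_chain", "symmetric CH3 bending"),
    band_definition(730, 12, 0.06, "CH_chain", "CH2 rocking"),
    band_definition(3010, 10, 1.00, "unsaturation", "=C-H stretching"),
    band_definition(3400, 160, 1.00, "water", "O-H stretching"),
    band_definition(1640, 40, 0.25, "water", "O-H bending"))
}

#' ATR evanescent-wave optics model
#'
#' Parameters of the attenuated-total-reflectance sampling geometry: a
#' high-index crystal (diamond, n1 = 2.40), a biological sample
#' (n2 = 1.50) and 45 degree incidence in single-reflection mode, plus a
#' phenomenological dispersion-induced peak-shift law
#' delta(nu) = delta0 (nu0 / nu)^gamma towards lower wavenumbers
#' (larger shifts at lower wavenumber, as refractive-index dispersion
#' produces).
#'
#' @param n1 crystal refractive index (default 2.40, diamond).
#' @param n2 sample refractive index (default 1.50).
#' @param theta incidence angle in degrees (default 45); must satisfy
#'   the total-internal-reflection condition sin(theta) > n2/n1.
#' @param dispersion_delta0 shift at `dispersion_nu0`, cm^-1 (default 7).
#' @param dispersion_nu0 anchor wavenumber (default 1375 cm^-1).
#' @param dispersion_gamma shift-law exponent (default 2, giving under
#'   2 cm^-1 at 2925 cm^-1 and 7 cm^-1 at 1375 cm^-1).
#' @return Object of class `atr_optics`.
#' @export
atr_optics <- function(n1 = 2.40, n2 = 1.50, theta = 45,
                       dispersion_delta0 = 7, dispersion_nu0 = 1375,
                       dispersion_gamma = 2) {
  if (sin(theta * pi / 180) <= n2 / n1)
    stop("total internal reflection requires sin(theta) > n2/n1")
  structure(list(n1 = n1, n2 = n2, theta = theta,
                 dispersion_delta0 = dispersion_delta0,
                 dispersion_nu0 = dispersion_nu0,
                 dispersion_gamma = dispersion_gamma),
            class = "atr_optics")
}

#' Evanescent-wave penetration depth
#'
#' d_p = lambda / (2 pi n1 sqrt(sin^2(theta) - (n2/n1)^2)) with
#' lambda = 10^4 / nu micrometres: the depth at which the evanescent
#' field decays to 1/e. Strictly decreasing in wavenumber, so ATR spectra
#' weight low-wavenumber bands more heavily than transmission spectra.
#'
#' @param optics an [atr_optics()] model.
#' @param wavenumber wavenumber(s) in cm^-1.
#' @return Penetration depth(s) in micrometres.
#' @examples
#' penetration_depth(atr_optics(), 1742)  # ~1.15 um
#' penetration_depth(atr_optics(), 1100)  # ~1.82 um
#' @export
penetration_depth <- function(optics, wavenumber) {
  stopifnot(inherits(optics, "atr_optics"))
  s2 <- sin(optics$theta * pi / 180)^2 - (optics$n2 / optics$n1)^2
  if (s2 <= 0) stop("total internal reflection condition violated")
  (1e4 / wavenumber) / (2 * pi * optics$n1 * sqrt(s2))
}

# dispersion-induced displacement of a band centre towards lower
# wavenumber (cm^-1)
dispersion_shift <- function(optics, wavenumber) {
  optics$dispersion_delta0 *
    (optics$dispersion_nu0 / wavenumber)^optics$dispersion_gamma
}

# evaluate one band profile on an axis
band_profile <- function(wavenumber, center, half_width,
                         shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  z <- (wavenumber - center) / half_width
  if (shape == "gaussian") exp(-0.5 * z^2) else 1 / (1 + z^2)
}

# map a composition profile (mass fractions of TAG, FFA, FFA_ionized,
# protein, polysaccharide, polyphosphate, water) to amounts of the band
# library's spectral components: acyl chains scale with total acyl lipid,
# unsaturation with the unsaturation index of the TAG pool.
profile_components <- function(profile, unsat_index = 0.3) {
  comp <- c(TAG = 0, FFA = 0, FFA_ionized = 0, protein = 0,
            polysaccharide = 0, polyphosphate = 0, water = 0)
  comp[names(profile)] <- unlist(profile)
  acyl <- comp[["TAG"]] + comp[["FFA"]]
  c(comp, CH_chain = 0.9 * acyl, unsaturation = unsat_index * acyl)
}

# component-by-channel matrix of unit spectra for a technique
component_matrix <- function(wavenumber, technique = c("HTS", "ATR"),
                             optics = atr_optics(),
                             bands = default_band_library(),
                             shape = "gaussian", ref_wavenumber = 1742) {
  technique <- match.arg(technique)
  comps <- unique(bands$component)
  M <- matrix(0, length(comps), length(wavenumber),
              dimnames = list(comps, NULL))
  for (i in seq_len(nrow(bands))) {
    center <- bands$center[i]
    amp <- bands$relative_amplitude[i]
    if (technique == "ATR") {
      amp <- amp * penetration_depth(optics, center) /
        penetration_depth(optics, ref_wavenumber)
      center <- center - dispersion_shift(optics, center)
    }
    M[bands$component[i], ] <- M[bands$component[i], ] +
      amp * band_profile(wavenumber, center, bands$half_width[i], shape)
  }
  M
}

#' Synthesise one bulk absorbance spectrum
#'
#' Beer-Lambert style forward model: absorbance is the composition-
#' weighted sum of per-component Gaussian band sums, plus a linear
#' baseline and Gaussian noise. In ATR mode every band is weighted by the
#' relative penetration depth d_p(center)/d_p(1742) and displaced towards
#' lower wavenumber by the dispersion shift law, reproducing the relative
#' intensity and peak-position differences between transmission and ATR
#' measurements.
#'
#' @param profile named mass fractions (subset of TAG, FFA, FFA_ionized,
#'   protein, polysaccharide, polyphosphate, water), summing to 1 for
#'   real material.
#' @param technique `"HTS"` (transmission) or `"ATR"`.
#' @param wavenumber axis in cm^-1.
#' @param optics an [atr_optics()] (used in ATR mode).
#' @param noise_sd absorbance noise standard deviation (default 0).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @param bands a [band_definition()] library.
#' @param shape `"gaussian"` or `"lorentzian"` band shapes.
#' @param baseline `c(offset, slope)` linear baseline over the axis.
#' @param scale overall absorbance scale (default 1).
#' @param meta metadata for the result.
#' @return An [ir_spectrum()].
#' @export
synth_bulk_spectrum <- function(profile, technique = "HTS",
                                wavenumber = seq(500, 4000, by = 3),
                                optics = atr_optics(), noise_sd = 0,
                                seed = NULL, bands = default_band_library(),
                                shape = "gaussian", baseline = c(0, 0),
                                scale = 1, meta = list()) {
  if (!length(profile)) stop("empty composition profile")
  comps <- profile_components(profile)
  M <- component_matrix(wavenumber, technique, optics, bands, shape)
  a <- scale * as.vector(comps[rownames(M)] %*% M)
  x01 <- (wavenumber - min(wavenumber)) / diff(range(wavenumber))
  a <- a + baseline[1L] + baseline[2L] * x01
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    a <- a + stats::rnorm(length(a), sd = noise_sd)
  }
  meta$technique <- technique
  ir_spectrum(wavenumber, a, meta)
}

#' Phosphate campaign design
#'
#' The six-condition phosphate series Pi4, Pi2, Pi1, Pi0.5, Pi0.25, Pi0
#' (grams per litre of KH2PO4 in the nitrogen-limited medium; Pi1 is the
#' control), three technical replicates, and for ATR a seven-day storage
#' series, giving 6 x 3 = 18 transmission spectra or 6 x 3 x 7 = 126 ATR
#' spectra.
#'
#' @param technique `"ATR"` or `"HTS"`.
#' @param conditions condition labels (default the Pi series).
#' @param pi_levels phosphate amounts (g/L) paired with the conditions.
#' @param replicates technical replicates per condition (default 3).
#' @param days storage days (default 7 for ATR, 1 for HTS).
#' @param condition_amp,day_amp effect amplitude scalars (defaults 1 and
#'   0.2: condition effects five times the day effects).
#' @param noise_sd replicate noise standard deviation (default 0.002).
#' @param seed campaign seed (default 1).
#' @return List of class `campaign_design`.
#' @export
campaign_design <- function(technique = c("ATR", "HTS"),
                            conditions = c("Pi4", "Pi2", "Pi1", "Pi0.5",
                                           "Pi0.25", "Pi0"),
                            pi_levels = c(4, 2, 1, 0.5, 0.25, 0),
                            replicates = 3L,
                            days = if (match.arg(technique) == "ATR") 7L else 1L,
                            condition_amp = 1, day_amp = 0.2,
                            noise_sd = 0.002, seed = 1L) {
  technique <- match.arg(technique)
  stopifnot(length(conditions) == length(pi_levels), replicates >= 1L, days >= 1L)
  structure(list(technique = technique, conditions = conditions,
                 pi_levels = pi_levels, replicates = as.integer(replicates),
                 days = as.integer(days), condition_amp = condition_amp,
                 day_amp = day_amp, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "campaign_design")
}

#' Simulate a designed measurement campaign
#'
#' Forward model of the phosphate/storage campaign: each condition gets a
#' composition whose triacylglyceride content varies with the condition
#' effect amplitude and whose polyphosphate content scales with the
#' phosphate amount in the medium (polyphosphate storage tracks
#' available phosphorus); each storage day adds a small water and lipid
#' drift; replicates add i.i.d. Gaussian noise. Ground truth (the
#' noiseless spectra and the design labels) is returned for recovery
#' tests.
#'
#' @param design a [campaign_design()].
#' @param optics an [atr_optics()] model.
#' @param wavenumber axis; defaults to the digitised instrument grid
#'   (2 cm^-1 point spacing from 400 for ATR, 3 cm^-1 from 500 for HTS,
#'   up to 4000 - half the nominal 4 / 6 cm^-1 optical resolution, as
#'   spectrometers digitise with twofold zero-filling).
#' @return List: `collection` (an [ir_collection()] with design
#'   metadata), `truth` (list with the noiseless matrix `clean`,
#'   `condition` and `day` labels, and per-spectrum TAG multipliers).
#' @export
synth_campaign <- function(design = campaign_design("ATR"),
                           optics = atr_optics(),
                           wavenumber = NULL) {
  stopifnot(inherits(design, "campaign_design"))
  if (is.null(wavenumber))
    wavenumber <- if (design$technique == "ATR") seq(400, 4000, by = 2)
                  else seq(500, 4000, by = 3)
  nc <- length(design$conditions)
  cond_dev <- seq(-0.4, 0.4, length.out = nc)
  day_dev <- if (design$days > 1L) seq(-0.4, 0.4, length.out = design$days) else 0
  base <- c(TAG = 0.30, FFA = 0.06, FFA_ionized = 0.04, protein = 0.25,
            polysaccharide = 0.20, polyphosphate = 0.05, water = 0.10)
  n <- nc * design$replicates * design$days
  rows <- vector("list", n)
  meta <- data.frame(spectrum_id = character(n), technique = design$technique,
                     sample = character(n), pi_level = numeric(n),
                     replicate = integer(n), day = integer(n))
  clean <- matrix(0, n, length(wavenumber))
  tag_mult <- numeric(n)
  set.seed(design$seed)
  i <- 0L
  for (ci in seq_len(nc)) for (d in seq_len(design$days))
    for (r in seq_len(design$replicates)) {
      i <- i + 1L
      prof <- base
      tm <- (1 + design$condition_amp * cond_dev[ci]) *
        (1 + design$day_amp * day_dev[if (design$days > 1L) d else 1L])
      prof["TAG"] <- base[["TAG"]] * tm
      pi_norm <- design$pi_levels / max(design$pi_levels, 1)
      prof["polyphosphate"] <- base[["polyphosphate"]] *
        (1 + design$condition_amp * 0.8 * (pi_norm[ci] - mean(pi_norm)))
      prof["water"] <- base[["water"]] *
        (1 + 2 * design$day_amp * day_dev[if (design$days > 1L) d else 1L])
      prof <- prof / sum(prof)
      sp <- synth_bulk_spectrum(prof, design$technique, wavenumber, optics)
      clean[i, ] <- sp$absorbance
      tag_mult[i] <- tm
      meta$spectrum_id[i] <- sprintf("%s_%s_d%d_r%d", design$technique,
                                     design$conditions[ci], d, r)
      meta$sample[i] <- design$conditions[ci]
      meta$pi_level[i] <- design$pi_levels[ci]
      meta$replicate[i] <- r
      meta$day[i] <- d
    }
  noisy <- clean + matrix(stats::rnorm(length(clean), sd = design$noise_sd),
                          nrow(clean))
  rownames(noisy) <- meta$spectrum_id
  list(collection = ir_collection(wavenumber, noisy, meta),
       truth = list(clean = clean, condition = meta$sample, day = meta$day,
                    tag_multiplier = tag_mult))
}

# ---- FPA scenes ------------------------------------------------------------

# distance of every pixel to a segment (capsule geometry helper)
capsule_mask <- function(rows, cols, center, length, width, angle_deg) {
  th <- angle_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  px <- rep(seq_len(cols), each = rows) - center[2L]
  py <- rep(seq_len(rows), times = cols) - center[1L]
  t_ <- pmax(-length / 2, pmin(length / 2, px * ux + py * uy))
  d2 <- (px - t_ * ux)^2 + (py - t_ * uy)^2
  matrix(d2 <= (width / 2)^2, rows, cols)
}

disk_mask <- function(rows, cols, center, radius) {
  px <- rep(seq_len(cols), each = rows) - center[2L]
  py <- rep(seq_len(rows), times = cols) - center[1L]
  matrix(px^2 + py^2 <= radius^2, rows, cols)
}

#' Default cell geometries for an FPA scene
#'
#' Builds the per-form default geometry set on a `rows x cols` frame:
#' flat hyphae (three thin capsules, lowest lipid-to-protein scalar, small
#' edge droplets), swollen hyphae (two wide capsules, intermediate lipid,
#' central droplets) or yeast-like cells (a field of disks, highest
#' lipid). The default lipid-to-protein scalars enforce the biological
#' ordering flat < swollen < yeast.
#'
#' @param form `"flat_hypha"`, `"swollen_hypha"` or `"yeast"`.
#' @param rows,cols frame size in pixels (defaults 128).
#' @return List of geometry descriptors (masks plus droplet tables).
#' @export
default_fpa_geometries <- function(form = c("flat_hypha", "swollen_hypha",
                                            "yeast"),
                                   rows = 128L, cols = 128L) {
  form <- match.arg(form)
  g <- list()
  if (form == "flat_hypha") {
    offs <- c(-38, 0, 38)
    for (k in seq_along(offs)) {
      ctr <- c(rows / 2 + offs[k], cols / 2)
      g[[k]] <- list(form = form, lipid_scale = 0.6,
                     mask_fun = function(ctr) capsule_mask(rows, cols, ctr, 118, 20, 15),
                     center = ctr,
                     droplets = data.frame(
                       row = ctr[1L] + c(-6, 6), col = ctr[2L] + c(-42, 44),
                       radius = 4, boost = 0.5))
    }
  } else if (form == "swollen_hypha") {
    offs <- c(-30, 32)
    for (k in seq_along(offs)) {
      ctr <- c(rows / 2 + offs[k], cols / 2)
      g[[k]] <- list(form = form, lipid_scale = 1.2,
                     mask_fun = function(ctr) capsule_mask(rows, cols, ctr, 116, 36, 10),
                     center = ctr,
                     droplets = data.frame(
                       row = ctr[1L], col = ctr[2L] + c(-18, 16),
                       radius = 8, boost = 0.6))
    }
  } else {
    set_centers <- expand.grid(row = seq(18, rows - 18, length.out = 4),
                               col = seq(18, cols - 18, length.out = 4))
    for (k in seq_len(nrow(set_centers))) {
      ctr <- c(set_centers$row[k], set_centers$col[k])
      g[[k]] <- list(form = form, lipid_scale = 2.2,
                     mask_fun = function(ctr) disk_mask(rows, cols, ctr, 13),
                     center = ctr,
                     droplets = data.frame(row = ctr[1L], col = ctr[2L],
                                           radius = 6, boost = 0.8))
    }
  }
  g
}

#' Simulate an FPA-FTIR hyperspectral scene
#'
#' Per-pixel compositions are derived from the cell geometries (droplet
#' pixels are triacylglyceride-enriched); each pixel's spectrum is the
#' transmission forward model for its composition, multiplied by a cell
#' thickness factor, plus a smooth per-pixel scatter baseline (quadratic
#' in wavenumber, random coefficients - emulating the Mie-type baseline
#' variation of real single-cell maps), Gaussian noise, and planted
#' hot-pixel outliers whose amplitude is ten scaled MADs of the affected
#' band. Ground truth (foreground/droplet masks, clean cube, outlier
#' positions) is returned.
#'
#' @param form cell form preset passed to [default_fpa_geometries()], or
#'   a geometry list built by it.
#' @param rows,cols frame size (defaults 128).
#' @param wavenumber axis (default 900--3900 cm^-1 at 8 cm^-1, so every
#'   marker band lies within the 4 cm^-1 FPA resolution of a grid point).
#' @param outlier_rate fraction of (pixel, band) entries replaced by hot
#'   outliers (default 0.001).
#' @param scatter_sd scatter-baseline coefficient sd (default 0.02).
#' @param noise_sd additive noise sd (default 0.02).
#' @param thickness cell thickness factor (default 1).
#' @param seed RNG seed (default 1).
#' @return List: `cube` (a [hyper_cube()]), `truth` (list with
#'   `foreground`, `droplets`, `clean` cube array, `outliers` logical
#'   array, `composition` matrix).
#' @export
synth_fpa_scene <- function(form = "flat_hypha", rows = 128L, cols = 128L,
                            wavenumber = seq(900, 3900, by = 8),
                            outlier_rate = 0.001, scatter_sd = 0.02,
                            noise_sd = 0.02, thickness = 1, seed = 1L) {
  geoms <- if (is.character(form))
    default_fpa_geometries(form, rows, cols) else form
  set.seed(seed)
  npix <- rows * cols
  comps <- c("TAG", "FFA", "FFA_ionized", "protein", "polysaccharide",
             "polyphosphate", "water")
  C <- matrix(0, npix, length(comps), dimnames = list(NULL, comps))
  fg <- matrix(FALSE, rows, cols)
  droplets <- matrix(FALSE, rows, cols)
  for (g in geoms) {
    m <- g$mask_fun(g$center)
    fg <- fg | m
    idx <- which(m)
    C[idx, "protein"] <- 0.30
    C[idx, "polysaccharide"] <- 0.16
    C[idx, "FFA"] <- 0.05
    C[idx, "FFA_ionized"] <- 0.03
    C[idx, "polyphosphate"] <- 0.04
    C[idx, "water"] <- 0.06
    C[idx, "TAG"] <- 0.18 * g$lipid_scale
    if (!is.null(g$droplets)) for (di in seq_len(nrow(g$droplets))) {
      dm <- disk_mask(rows, cols, c(g$droplets$row[di], g$droplets$col[di]),
                      g$droplets$radius[di]) & m
      droplets <- droplets | dm
      C[which(dm), "TAG"] <- C[which(dm), "TAG"] + g$droplets$boost[di]
      C[which(dm), "FFA"] <- C[which(dm), "FFA"] + 0.3 * g$droplets$boost[di]
    }
  }
  cell <- which(as.vector(fg))
  C[cell, ] <- C[cell, ] / rowSums(C[cell, , drop = FALSE])
  M <- component_matrix(wavenumber, "HTS")
  amounts <- t(apply(C, 1L, profile_components))
  S <- thickness * (amounts[, rownames(M)] %*% M)
  clean <- array(S, c(rows, cols, length(wavenumber)))
  # smooth per-pixel scatter baseline
  x01 <- (wavenumber - min(wavenumber)) / diff(range(wavenumber))
  a0 <- stats::rnorm(npix, sd = scatter_sd)
  a1 <- stats::rnorm(npix, sd = scatter_sd)
  a2 <- stats::rnorm(npix, sd = scatter_sd / 2)
  vals <- S + outer(a0, rep(1, length(x01))) + outer(a1, x01) + outer(a2, x01^2)
  vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd), npix)
  cube_vals <- array(vals, c(rows, cols, length(wavenumber)))
  outliers <- array(FALSE, dim(cube_vals))
  if (outlier_rate > 0) {
    n_out <- round(outlier_rate * length(cube_vals))
    pos <- sample.int(length(cube_vals), n_out)
    for (b in seq_along(wavenumber)) {
      band_lin <- pos[(pos - 1L) %/% npix + 1L == b]
      if (!length(band_lin)) next
      img <- cube_vals[, , b]
      amp <- stats::median(img) + 10 * stats::mad(img)
      pix <- band_lin - (b - 1L) * npix
      img[pix] <- amp
      cube_vals[, , b] <- img
      ob <- outliers[, , b]; ob[pix] <- TRUE; outliers[, , b] <- ob
    }
  }
  list(cube = hyper_cube(cube_vals, wavenumber, pixel_size = 0.7),
       truth = list(foreground = fg, droplets = droplets, clean = clean,
                    outliers = outliers, composition = C))
}

# ---- AFM-IR scenes ---------------------------------------------------------

#' AFM-IR scene parameters
#'
#' Artifact and content parameters for the AFM-IR forward model. Heights
#' are in nanometres (the raw instrument unit); the hypha body is a
#' vertical capsule (so each scan line crosses it over less than half its
#' width) with lipid droplets as Gaussian height bumps placed at the
#' hypha edges for flat hyphae and at the centre for swollen hyphae.
#'
#' @param form `"flat_hypha"` or `"swollen_hypha"` (yeast-like cells are
#'   refused downstream: they are too thick for reliable tip contact).
#' @param hypha_height body height in nm (default 150 for flat, 200 for
#'   swollen).
#' @param droplet_height droplet bump height in nm (default 80).
#' @param droplet_strength multiplier on the droplet-localised TAG/FFA
#'   amounts relative to the cytoplasmic baseline (default 1).
#' @param droplet_ratios TAG:FFA amount ratios of the droplets (default
#'   `c(2, 2)`; use e.g. `c(2, 0.5)` for sign-separated droplets).
#' @param tilt plane tilt across the frame in nm, `c(x_span, y_span)`
#'   (default `c(120, 80)`).
#' @param line_offset_sd per-scan-line height offset sd in nm (default 5).
#' @param drift named list of per-wavenumber [rigid_transform()]s; the
#'   default drifts 1708 by (1.5, -1, 1 deg) and 1742 by (-2, 1, -1.5 deg)
#'   while 1600 (the registration reference) stays fixed.
#' @param contact_rate fraction of scan-line pixels hit by contact-loss
#'   dropouts (default 0.01).
#' @param noise_sd relative absorption/height noise sd (default 0.01).
#' @param thick_sample simulate an over-thick sample (> 2-3 um); the
#'   correction pipeline refuses such scenes.
#' @param seed RNG seed (default 1).
#' @return List of class `afmir_scene_params`.
#' @export
afmir_scene_params <- function(form = c("flat_hypha", "swollen_hypha"),
                               hypha_height = NULL, droplet_height = 80,
                               droplet_strength = 1, droplet_ratios = c(2, 2),
                               tilt = c(120, 80), line_offset_sd = 5,
                               drift = list(
                                 "1600" = rigid_transform(0, 0, 0),
                                 "1708" = rigid_transform(1.5, -1, 1),
                                 "1742" = rigid_transform(-2, 1, -1.5)),
                               contact_rate = 0.01, noise_sd = 0.01,
                               thick_sample = FALSE, seed = 1L) {
  form <- match.arg(form)
  if (is.null(hypha_height))
    hypha_height <- if (form == "flat_hypha") 150 else 200
  for (tf in drift)
    if (abs(tf$dx) > 10 || abs(tf$dy) > 10 || abs(tf$theta) > 10)
      stop("drift magnitudes must stay within +/-10 px and +/-10 degrees")
  stopifnot(contact_rate >= 0, contact_rate < 1)
  structure(list(form = form, hypha_height = hypha_height,
                 droplet_height = droplet_height,
                 droplet_strength = droplet_strength,
                 droplet_ratios = droplet_ratios, tilt = tilt,
                 line_offset_sd = line_offset_sd, drift = drift,
                 contact_rate = contact_rate, noise_sd = noise_sd,
                 thick_sample = thick_sample, seed = as.integer(seed)),
            class = "afmir_scene_params")
}

#' Default QCL laser-power (background) spectrum
#'
#' A smooth positive emission curve over the 1510--1800 cm^-1 tuning
#' range, peaking near the centre of the range as tunable QCL sources do.
#'
#' @param wavenumber axis (default 1510--1800 cm^-1 at 1 cm^-1).
#' @return A [laser_power()].
#' @export
default_laser_power <- function(wavenumber = seq(1510, 1800, by = 1)) {
  laser_power(wavenumber, 0.4 + 0.6 * exp(-0.5 * ((wavenumber - 1660) / 120)^2))
}

#' Simulate an AFM-IR scene
#'
#' Builds clean topography (hypha body + droplet bumps), deflection
#' (topography gradient magnitude) and absorption maps at the acquired
#' wavenumbers (absorptivity of TAG, FFA and the COO-/matrix component
#' evaluated from the band library, times local amounts, times laser
#' power), then applies the artifact chain: per-wavenumber rigid drift,
#' plane tilt, scan-line offsets, noise, and contact-loss dropout
#' segments on absorption. Ground truth (clean maps, transforms, droplet
#' masks) is retained.
#'
#' @param params an [afmir_scene_params()].
#' @param shape map shape in pixels (default `c(64, 64)`).
#' @param wavenumbers acquired bands (default 1600, 1708, 1742).
#' @param scan_size scan size in micrometres (default 5).
#' @param power a [laser_power()] (default [default_laser_power()]).
#' @return List: `set` (an [afmir_set()], with `meta$thick_sample`
#'   forwarded), `truth` (clean maps in the corrected frame, the applied
#'   transforms, droplet and hypha masks, contact-loss masks).
#' @export
synth_afmir_scene <- function(params = afmir_scene_params(),
                              shape = c(64L, 64L),
                              wavenumbers = c(1600, 1708, 1742),
                              scan_size = 5, power = default_laser_power()) {
  stopifnot(inherits(params, "afmir_scene_params"))
  set.seed(params$seed)
  nr <- shape[1L]; nc <- shape[2L]
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), times = nc)
  # vertical capsule body with a smooth rounded cross-section (zero edge
  # slope, as real hyphae present); the centreline meanders and the
  # height is modulated along the length
  # (hyphae are not straight cylinders), which also anchors registration
  # in the scan direction
  width <- if (params$form == "flat_hypha") 0.28 * nc else 0.42 * nc
  cx <- nc / 2 + 0.05 * nc * sin(2 * pi * py / nr + 0.7)
  d <- abs(px - cx) / (width / 2)
  modl <- 1 + 0.18 * sin(2 * pi * 1.7 * py / nr + 2.1)
  # cell-wall step at the edge: hyphae present steep sides to the AFM
  # tip, so the height jumps from the bare substrate to the wall height
  body <- matrix(ifelse(d <= 1, (0.45 + 0.55 * sqrt(pmax(0, 1 - d^2))) * modl, 0),
                 nr, nc)
  hypha_mask <- body > 0
  topo_clean <- params$hypha_height * body
  # droplets: edge-placed for flat hyphae, centred for swollen
  n_drop <- length(params$droplet_ratios)
  drop_rows <- seq(0.3, 0.7, length.out = max(2L, n_drop))[seq_len(n_drop)] * nr
  cl_at <- nc / 2 + 0.05 * nc * sin(2 * pi * drop_rows / nr + 0.7)
  drop_cols <- if (params$form == "flat_hypha")
    cl_at + (width / 2 - 3) * rep_len(c(-1, 1), n_drop) else cl_at
  drop_r <- 0.09 * min(nr, nc)
  droplet_mask <- matrix(FALSE, nr, nc)
  # cytoplasmic baseline lipids throughout the body, droplet-concentrated
  # TAG/FFA added below
  tag_amount <- matrix(0.08 * body, nr, nc)
  ffa_amount <- matrix(0.05 * body, nr, nc)
  matrix_amount <- matrix(0.3 * body, nr, nc)  # cell-wall / ionized pool
  for (k in seq_len(n_drop)) {
    r2 <- (px - drop_cols[k])^2 + (py - drop_rows[k])^2
    bump <- matrix(exp(-0.5 * r2 / (drop_r / 1.5)^2), nr, nc)
    bump[bump < exp(-4.5)] <- 0  # truncate at 3 sigma: exact-zero background
    topo_clean <- topo_clean + params$droplet_height * bump
    dm <- matrix(r2, nr, nc) <= drop_r^2
    droplet_mask <- droplet_mask | dm
    ratio <- params$droplet_ratios[k]
    tag_amount <- tag_amount + params$droplet_strength * bump * ratio / (1 + ratio)
    ffa_amount <- ffa_amount + params$droplet_strength * bump * 1 / (1 + ratio)
  }
  if (params$thick_sample) topo_clean <- topo_clean * 20  # > 2-3 um
  # deflection: error signal tracks the topography gradient
  gx <- cbind(topo_clean[, -1L], topo_clean[, nc]) - topo_clean
  gy <- rbind(topo_clean[-1L, ], topo_clean[nr, ]) - topo_clean
  defl_clean <- sqrt(gx^2 + gy^2) / max(1e-9, max(abs(topo_clean)))
  # absorptivity of each species at each wavenumber, from the band library
  bands <- default_band_library()
  absy <- function(component, wn) {
    rows <- bands[bands$component == component, , drop = FALSE]
    sum(rows$relative_amplitude *
          band_profile(wn, rows$center, rows$half_width))
  }
  maps <- list()
  truth_clean <- list()
  contact_masks <- list()
  thick <- 0.3 + body  # optical thickness factor
  for (wn in wavenumbers) {
    nm <- format(wn)
    p <- power_at(power, wn)
    a_clean <- p * thick * (tag_amount * absy("TAG", wn) +
                              ffa_amount * absy("FFA", wn) +
                              matrix_amount * absy("FFA_ionized", wn))
    tf <- params$drift[[nm]]
    if (is.null(tf)) tf <- rigid_transform(0, 0, 0)
    move <- function(m) {
      if (tf$dx == 0 && tf$dy == 0 && tf$theta == 0) return(m)
      out <- apply_transform(m, tf)
      out[is.na(out)] <- 0
      out
    }
    topo <- move(topo_clean)
    defl <- move(defl_clean)
    a <- move(a_clean)
    # artifacts
    tiltmap <- params$tilt[1L] * (matrix(px, nr, nc) - 1) / (nc - 1) +
      params$tilt[2L] * (matrix(py, nr, nc) - 1) / (nr - 1)
    topo <- topo + tiltmap
    if (params$line_offset_sd > 0)
      topo <- topo + stats::rnorm(nr, sd = params$line_offset_sd)
    if (params$noise_sd > 0) {
      topo <- topo + stats::rnorm(nr * nc,
                                  sd = params$noise_sd * max(abs(topo_clean)))
      a <- a + stats::rnorm(nr * nc, sd = params$noise_sd * max(a_clean))
      defl <- defl + stats::rnorm(nr * nc, sd = params$noise_sd)
    }
    cmask <- matrix(FALSE, nr, nc)
    if (params$contact_rate > 0) {
      n_seg <- max(1L, round(params$contact_rate * nr * nc / 5))
      for (s in seq_len(n_seg)) {
        i <- sample.int(nr, 1L)
        j0 <- sample.int(nc - 4L, 1L)
        cmask[i, j0:(j0 + 4L)] <- TRUE
      }
      a[cmask] <- 0
    }
    maps[[nm]] <- list(topography = topo, deflection = defl, absorption = a)
    truth_clean[[nm]] <- list(topography = topo_clean, deflection = defl_clean,
                              absorption = a_clean / p)
    contact_masks[[nm]] <- cmask
  }
  set <- afmir_set(maps, scan_size = scan_size, power = power,
                   meta = list(thick_sample = params$thick_sample,
                               form = params$form))
  list(set = set,
       truth = list(clean = truth_clean, transforms = params$drift,
                    hypha = hypha_mask, droplets = droplet_mask,
                    droplet_centers = cbind(row = drop_rows, col = drop_cols),
                    droplet_radius = drop_r,
                    droplet_ratios = params$droplet_ratios,
                    tag_amount = tag_amount, ffa_amount = ffa_amount,
                    contact = contact_masks))
}

#' Simulate the full AFM-IR acquisition campaign
#'
#' Two samples (phosphate control, flat hyphae; phosphate-free, swollen
#' hyphae) times five areas each, three wavenumbers per area: 30
#' absorption maps with matching topography and deflection maps.
#'
#' @param seed campaign seed (default 1).
#' @param shape per-scene map shape (default `c(32, 32)` to keep the
#'   campaign light; individual analyses use larger scenes).
#' @return List of scene results as returned by [synth_afmir_scene()].
#' @export
synth_afmir_campaign <- function(seed = 1L, shape = c(32L, 32L)) {
  scenes <- list()
  k <- 0L
  for (sample in c("Pi1", "Pi0")) for (area in 1:5) {
    k <- k + 1L
    form <- if (sample == "Pi1") "flat_hypha" else "swollen_hypha"
    scenes[[sprintf("%s_area%d", sample, area)]] <-
      synth_afmir_scene(afmir_scene_params(form = form, seed = seed + k))
  }
  scenes
}
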