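# End-to-end orchestration of the three measurement scales as
# reproducible runs: configuration handling, stage sequencing, CSV/JSON
# outputs and a machine-readable run manifest.

#' Load a run configuration
#'
#' @param config a named list, or the path to a YAML file containing one.
#' @return The configuration list with defaults filled in.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) config$seed <- 1L
  config
}

write_manifest <- function(out_dir, stage, inputs, params, outputs) {
  manifest <- list(
    stage = stage,
    package = "mirlipid",
    version = as.character(utils::packageVersion("mirlipid")),
    inputs = inputs,
    parameters = params,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

file_md5 <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the bulk-spectrum analysis stage
#'
#' Orchestrates the macroscale workflow: load (or simulate) the ATR and
#' HTS campaigns, preprocess per spectral region (Savitzky-Golay second
#' derivative then EMSC), partition the ATR matrix by the condition and
#' day factors (ANOVA-PCA) per region, compare the instruments (peak
#' matching and lipid band ratios on day-1 mean sample spectra), and
#' write contribution, score, loading, peak, match and ratio tables plus
#' a run manifest.
#'
#' Config keys: `out_dir` (required); either `atr_path`/`atr_meta_path`
#' and `hts_path`/`hts_meta_path` or `preset: paper` (simulate the
#' default campaigns); `seed`; `regions` (preset names; default the four
#' biochemical windows); `sg` (window/polyorder/deriv);
#' `emsc_poly_order`.
#'
#' @param config list or YAML path, see [load_config()].
#' @return Invisibly, a list with the per-region ANOVA-PCA results, the
#'   comparison tables and the output paths.
#' @export
run_bulk <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  regions <- if (is.null(cfg$regions))
    c("lipid_combined", "protein", "mixed", "polysaccharide") else cfg$regions
  sgp <- if (is.null(cfg$sg)) sg_params(15L, 2L, 2L) else
    sg_params(cfg$sg$window, cfg$sg$polyorder, cfg$sg$deriv)
  emsc_order <- if (is.null(cfg$emsc_poly_order)) 2L else cfg$emsc_poly_order
  inputs <- list()
  if (!is.null(cfg$atr_path)) {
    if (!file.exists(cfg$atr_path) || !file.exists(cfg$atr_meta_path))
      stop("input spectra or sidecar file missing: ", cfg$atr_path)
    atr <- read_spectra(cfg$atr_path, cfg$atr_meta_path)
    hts <- read_spectra(cfg$hts_path, cfg$hts_meta_path)
    inputs <- file_md5(c(cfg$atr_path, cfg$atr_meta_path,
                         cfg$hts_path, cfg$hts_meta_path))
  } else {
    atr_sim <- synth_campaign(campaign_design("ATR", seed = cfg$seed))
    hts_sim <- synth_campaign(campaign_design("HTS", seed = cfg$seed))
    atr <- atr_sim$collection
    hts <- hts_sim$collection
    inputs <- list(simulated = sprintf("paper preset, seed %d", cfg$seed))
  }
  outputs <- character(0)
  results <- list(anova_pca = list())
  # ANOVA-PCA of the ATR campaign, per region
  d_cond <- build_design(atr$meta$sample, "condition")
  d_day <- build_design(atr$meta$day, "day")
  contrib_rows <- list()
  for (rg in regions) {
    sub <- select_region(atr, rg)
    der <- savitzky_golay(sub, sgp)
    cor <- emsc_fit_correct(der, "mean", emsc_order)$corrected
    dec <- decompose_effects(cor$data, d_cond, d_day)
    ctr <- effect_contributions(dec)
    ctr$region <- rg
    contrib_rows[[rg]] <- ctr
    for (fac in c("condition", "day")) {
      pca <- effect_pca(dec, fac, n_components = 2L)
      sc_path <- file.path(cfg$out_dir, sprintf("scores_%s_%s.csv", rg, fac))
      utils::write.csv(pca$scores, sc_path, row.names = FALSE)
      ld_path <- file.path(cfg$out_dir, sprintf("loadings_%s_%s.csv", rg, fac))
      utils::write.csv(data.frame(wavenumber = cor$wavenumber, pca$loadings),
                       ld_path, row.names = FALSE)
      outputs <- c(outputs, sc_path, ld_path)
      results$anova_pca[[rg]][[fac]] <- pca
    }
    results$anova_pca[[rg]]$contributions <- ctr
  }
  contrib <- do.call(rbind, contrib_rows)
  ctr_path <- file.path(cfg$out_dir, "contributions.csv")
  utils::write.csv(contrib, ctr_path, row.names = FALSE)
  outputs <- c(outputs, ctr_path)
  # instrument comparison on day-1 mean sample spectra
  atr_d1 <- ir_collection(atr$wavenumber,
                          atr$data[atr$meta$day == min(atr$meta$day), ,
                                   drop = FALSE],
                          atr$meta[atr$meta$day == min(atr$meta$day), ])
  atr_mean <- average_replicates(atr_d1, "sample")
  hts_mean <- average_replicates(hts, "sample")
  al <- align_axes(hts_mean, atr_mean)
  emsc_h <- emsc_fit_correct(al$a, "mean", 2L)$corrected
  emsc_a <- emsc_fit_correct(al$b, "mean", 2L)$corrected
  pk_h <- pick_peaks(mean_spectrum(emsc_h), "lipid_combined", sgp,
                     instrument = "HTS")
  pk_a <- pick_peaks(mean_spectrum(emsc_a), "lipid_combined", sgp,
                     instrument = "ATR")
  matches <- match_peaks(pk_h, pk_a)
  ratios_h <- band_ratios(emsc_h)
  ratios_a <- band_ratios(emsc_a)
  ratios_h$instrument <- "HTS"; ratios_a$instrument <- "ATR"
  cmp_paths <- file.path(cfg$out_dir, c("peaks_hts.csv", "peaks_atr.csv",
                                        "matches.csv", "ratios.csv"))
  utils::write.csv(pk_h, cmp_paths[1L], row.names = FALSE)
  utils::write.csv(pk_a, cmp_paths[2L], row.names = FALSE)
  utils::write.csv(matches, cmp_paths[3L], row.names = FALSE)
  utils::write.csv(rbind(ratios_h, ratios_a), cmp_paths[4L], row.names = FALSE)
  outputs <- c(outputs, cmp_paths)
  results$peaks <- list(hts = pk_h, atr = pk_a)
  results$matches <- matches
  results$ratios <- rbind(ratios_h, ratios_a)
  results$n_atr <- n_spectra(atr)
  results$n_hts <- n_spectra(hts)
  write_manifest(cfg$out_dir, "bulk",
                 c(inputs, list(n_atr_spectra = n_spectra(atr),
                                n_hts_spectra = n_spectra(hts))),
                 list(regions = regions, seed = cfg$seed,
                      sg = unclass(sgp), emsc_poly_order = emsc_order),
                 as.list(basename(outputs)))
  results$outputs <- outputs
  invisible(results)
}

#' Run the FPA hyperspectral stage
#'
#' Trim to the 3200--1000 cm^-1 working range, flag and repair scaled-MAD
#' outliers, segment foreground cells, descatter the foreground, and
#' export band images, the lipid-to-protein ratio map and a QC report.
#'
#' Config keys: `out_dir`; either `cube_header` (path) or `preset: paper`
#' with `form`; `seed`; `bands`; `ratio_pairs`.
#'
#' @param config list or YAML path.
#' @return Invisibly, a list with the processed cube, mask, maps and QC
#'   counts.
#' @export
run_fpa <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list()
  if (!is.null(cfg$cube_header)) {
    cube <- read_cube(cfg$cube_header)
    inputs <- file_md5(cfg$cube_header)
  } else {
    form <- if (is.null(cfg$form)) "flat_hypha" else cfg$form
    cube <- synth_fpa_scene(form, seed = cfg$seed)$cube
    inputs <- list(simulated = sprintf("%s scene, seed %d", form, cfg$seed))
  }
  bands <- if (is.null(cfg$bands)) FPA_SEGMENT_BANDS else cfg$bands
  pairs <- if (is.null(cfg$ratio_pairs)) list(c(1742, 1650)) else cfg$ratio_pairs
  cube <- trim_cube(cube)
  om <- flag_outliers(cube)
  cube <- repair_outliers(cube, om)
  mask <- segment_cube(cube, bands, seed = cfg$seed)
  cube <- descatter(cube, mask)
  maps <- band_and_ratio_maps(cube, mask, bands, pairs)
  outputs <- character(0)
  for (nm in names(maps$band_images)) {
    p <- file.path(cfg$out_dir, sprintf("band_%s.tsv", nm))
    utils::write.table(maps$band_images[[nm]], p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    outputs <- c(outputs, p)
  }
  for (nm in names(maps$ratio_maps)) {
    p <- file.path(cfg$out_dir, sprintf("ratio_%s.tsv", gsub(":", "_", nm)))
    utils::write.table(maps$ratio_maps[[nm]], p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    outputs <- c(outputs, p)
  }
  mask_path <- file.path(cfg$out_dir, "foreground_mask.tsv")
  utils::write.table(mask$foreground * 1L, mask_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  qc <- list(n_outlier_flags = sum(om$mask), n_global_outliers = sum(om$global),
             foreground_pixels = sum(mask$foreground),
             foreground_fraction = mean(mask$foreground),
             flagged_ratio_pixels = as.list(maps$flagged))
  qc_path <- file.path(cfg$out_dir, "qc_report.json")
  jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- c(outputs, mask_path, qc_path)
  write_manifest(cfg$out_dir, "fpa", inputs,
                 list(bands = bands, seed = cfg$seed),
                 as.list(basename(outputs)))
  invisible(list(cube = cube, mask = mask, maps = maps, qc = qc,
                 outputs = outputs))
}

#' Run the AFM-IR stage
#'
#' Full correction chain (levelling, contact-loss repair, drift
#' registration, rescaling, laser-power normalisation), segmentation and
#' log10 ratio maps; writes corrected maps, transforms, the mask, ratio
#' maps and a masked-pixel QC report.
#'
#' Config keys: `out_dir`; either `scene_dir` (a [read_afmir_set()]
#' directory) or `preset: paper` with `form`; `fixed_wavenumber`
#' (default 1600); `ratio_pairs`; `seed`.
#'
#' @param config list or YAML path.
#' @return Invisibly, a list with the corrected set, transforms, mask and
#'   ratio maps.
#' @export
run_afmir <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$scene_dir)) {
    set <- read_afmir_set(cfg$scene_dir)
    inputs <- list(scene_dir = cfg$scene_dir)
  } else {
    form <- if (is.null(cfg$form)) "flat_hypha" else cfg$form
    set <- synth_afmir_scene(afmir_scene_params(form = form,
                                                seed = cfg$seed))$set
    inputs <- list(simulated = sprintf("%s scene, seed %d", form, cfg$seed))
  }
  fixed <- if (is.null(cfg$fixed_wavenumber)) 1600 else cfg$fixed_wavenumber
  pairs <- if (is.null(cfg$ratio_pairs)) list(c(1742, 1600), c(1708, 1600)) else
    cfg$ratio_pairs
  corr <- correct_afmir_set(set, fixed_wavenumber = fixed)
  mask <- segment_afmir(corr$set, fixed_wavenumber = fixed, seed = cfg$seed)
  ratios <- log_ratio_maps(corr$set, mask, pairs)
  outputs <- character(0)
  for (nm in names(corr$set$maps))
    for (role in c("topography", "deflection", "absorption")) {
      p <- file.path(cfg$out_dir, sprintf("corrected_%s_%s.tsv", role, nm))
      utils::write.table(corr$set$maps[[nm]][[role]], p, sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      outputs <- c(outputs, p)
    }
  tf_path <- file.path(cfg$out_dir, "transforms.json")
  jsonlite::write_json(lapply(corr$transforms, unclass), tf_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mask_path <- file.path(cfg$out_dir, "hypha_mask.tsv")
  utils::write.table(mask$foreground * 1L, mask_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  outputs <- c(outputs, tf_path, mask_path)
  for (nm in names(ratios$absorption_ratios)) {
    p <- file.path(cfg$out_dir, sprintf("logratio_%s.tsv", gsub(":", "_", nm)))
    utils::write.table(ratios$absorption_ratios[[nm]], p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    outputs <- c(outputs, p)
  }
  qc <- list(masked_pixels = as.list(ratios$masked),
             contact_loss_pixels = lapply(corr$contact_flags, sum),
             transforms = lapply(corr$transforms, unclass))
  qc_path <- file.path(cfg$out_dir, "qc_report.json")
  jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- c(outputs, qc_path)
  write_manifest(cfg$out_dir, "afmir", inputs,
                 list(fixed_wavenumber = fixed, seed = cfg$seed),
                 as.list(basename(outputs)))
  invisible(list(set = corr$set, transforms = corr$transforms, mask = mask,
                 ratios = ratios, qc = qc, outputs = outputs))
}
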