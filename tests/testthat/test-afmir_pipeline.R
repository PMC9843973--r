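test_that("topography levelling removes planes, line offsets, and keeps bumps", {
  nr <- 32L; nc <- 32L
  xg <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  yg <- matrix(rep(seq_len(nr), nc), nr, nc)
  plane <- 2 * xg + 3 * yg
  expect_lt(max(abs(level_topography(plane))), 1e-9)
  # plane plus per-scan-line offsets
  set.seed(6)
  offs <- runif(nr, -10, 10)
  expect_lt(max(abs(level_topography(plane + offs))), 1e-9)
  # plane plus a Gaussian droplet bump: the bump survives, the rest is flat
  bump <- 80 * exp(-0.5 * ((xg - 22)^2 + (yg - 10)^2) / 9)
  lev <- level_topography(plane + bump)
  off_bump <- bump < 1e-3
  expect_lt(sqrt(mean(lev[off_bump]^2)), 0.01 * 80)
  expect_gt(max(lev), 70)
  expect_error(level_topography(matrix(0, 2, 2)), "at least 3x3")
  expect_error(level_topography(matrix(0, 5, 5), poly_order = 10L), "too high")
})

test_that("contact-loss dropouts are detected per line and repaired", {
  set.seed(3)
  base <- matrix(1, 16, 16) + outer(sin(seq(0, 1, length.out = 16)),
                                    cos(seq(0, 2, length.out = 16))) * 0.05
  hit <- base
  hit[7, 4] <- 0
  r <- repair_contact_loss(hit)
  expect_true(r$flags[7, 4])
  expect_equal(r$map[7, 4], mean(base[6:8, 3:5][-5]), tolerance = 0.05)
  # a clean smooth map passes through unchanged
  rc <- repair_contact_loss(base)
  expect_identical(rc$map, base)
  expect_equal(sum(rc$flags), 0L)
  # a fully dropped line cannot be repaired from itself
  gone <- base + matrix(rnorm(256, sd = 0.001), 16)
  gone[5, ] <- -99
  expect_error(repair_contact_loss(gone), "entire scan line")
  # planted 5-pixel dropout segments on a synthetic scene are recovered
  sc <- synth_afmir_scene(afmir_scene_params(seed = 7, contact_rate = 0.02,
    drift = list("1600" = rigid_transform(0, 0, 0),
                 "1708" = rigid_transform(0, 0, 0),
                 "1742" = rigid_transform(0, 0, 0))))
  nm <- "1742"
  planted <- sc$truth$contact[[nm]]
  rep_ <- repair_contact_loss(sc$set$maps[[nm]]$absorption)
  truth_map <- sc$truth$clean[[nm]]$absorption *
    power_at(sc$set$power, as.numeric(nm))
  # recovery is judged on dropouts that hit actual signal away from the
  # frame edge (dropouts on the empty substrate are zero both ways)
  err <- abs(rep_$map - truth_map)
  sel <- planted & truth_map > 0.1 * max(truth_map) &
    !(row(truth_map) %in% c(1L, nrow(truth_map)))
  expect_gte(mean(err[sel] <= 0.1 * truth_map[sel]), 0.95)
  # dropouts on the substrate remain equal to the (zero) truth
  bg <- planted & truth_map <= 1e-6
  expect_lt(max(err[bg]), 0.02 * max(truth_map))
})

test_that("rigid registration recovers known transforms", {
  set.seed(1)
  img <- matrix(0, 64, 64)
  px <- rep(1:64, each = 64); py <- rep(1:64, 64)
  for (k in 1:6) {
    ctr <- c(runif(1, 12, 52), runif(1, 12, 52))
    img <- img + exp(-0.5 * ((px - ctr[2])^2 + (py - ctr[1])^2) / 9) *
      runif(1, 0.5, 1.5)
  }
  # pure translation
  mv <- apply_transform(img, rigid_transform(3, -2, 0)); mv[is.na(mv)] <- 0
  tf <- register_maps(img, mv)
  expect_lt(abs(tf$dx - 3), 0.5)
  expect_lt(abs(tf$dy + 2), 0.5)
  expect_lt(abs(tf$theta), 0.5)
  # translation plus rotation
  mv2 <- apply_transform(img, rigid_transform(1.5, 0, 5)); mv2[is.na(mv2)] <- 0
  tf2 <- register_maps(img, mv2)
  expect_lt(abs(tf2$dx - 1.5), 0.5)
  expect_lt(abs(tf2$dy), 0.5)
  expect_lt(abs(tf2$theta - 5), 0.5)
  # identity
  tf0 <- register_maps(img, img)
  expect_lt(abs(tf0$dx) + abs(tf0$dy), 0.1)
  expect_lt(abs(tf0$theta), 0.1)
  # a flat image has no unique similarity peak
  expect_error(register_maps(matrix(1, 32, 32), matrix(1, 32, 32)), "flat image")
  # transforms invert within interpolation error on smooth images
  back <- apply_transform(apply_transform(img, rigid_transform(1.5, 0.5, 3)),
                          invert_transform(rigid_transform(1.5, 0.5, 3)))
  ok <- !is.na(back)
  expect_lt(sqrt(mean((back[ok] - img[ok])^2)), 0.05 * max(img))
})

test_that("drift estimates stay within half a pixel and half a degree across seeds", {
  for (s in 0:7) {
    sc <- synth_afmir_scene(afmir_scene_params(seed = s))
    corr <- correct_afmir_set(sc$set)
    for (nm in c("1708", "1742")) {
      tf <- corr$transforms[[nm]]; tt <- sc$truth$transforms[[nm]]
      expect_lt(abs(tf$dx - tt$dx), 0.5)
      expect_lt(abs(tf$dy - tt$dy), 0.5)
      expect_lt(abs(tf$theta - tt$theta), 0.5)
    }
  }
})

test_that("topography rescaling shifts, clips at the 5th percentile and converts units", {
  m <- matrix(c(-2, 0, 2, -2, 0, 2, -2, 0, 2), 3)
  out <- rescale_topography(m)
  expect_equal(min(out), 0)
  # uniform map is unchanged (the percentile equals the value)
  u <- matrix(4, 3, 3)
  expect_equal(rescale_topography(u), matrix(0, 3, 3))
  # a 100-pixel ramp: values below the 4.95 threshold are raised, exactly 5
  ramp <- matrix(0:99, 10, 10)
  rr <- rescale_topography(ramp)
  expect_equal(sum(rr == 4.95), 5L)
  expect_equal(min(rr), 4.95)
  # nanometre input lands in micrometres
  expect_equal(max(rescale_topography(matrix(c(0, 1000), 1, 2) %x%
                                        matrix(1, 2, 1), from_units = "nm")), 1)
})

test_that("laser-power normalisation divides by the interpolated power", {
  lp <- laser_power(c(1500, 1700, 1900), c(1, 2, 1))
  m <- matrix(4, 3, 3)
  expect_equal(normalize_absorption(m, 1700, lp), matrix(2, 3, 3))
  expect_equal(normalize_absorption(m, 1500, lp), m)
  expect_equal(power_at(lp, 1600), 1.5)
  expect_error(normalize_absorption(m, 1400, lp), "outside")
  # equal true absorptivity at two wavenumbers with different source power
  # gives equal normalised maps
  sc <- synth_afmir_scene(clean_afmir_params())
  corr <- correct_afmir_set(sc$set)
  for (nm in names(corr$set$maps))
    expect_equal(corr$set$maps[[nm]]$absorption,
                 sc$truth$clean[[nm]]$absorption, tolerance = 1e-10)
})

test_that("the full correction chain is the identity on artifact-free scenes", {
  sc <- synth_afmir_scene(clean_afmir_params())
  corr <- correct_afmir_set(sc$set)
  for (nm in names(corr$set$maps)) {
    tr <- sc$truth$clean[[nm]]
    expect_lt(max(abs(corr$set$maps[[nm]]$topography - tr$topography / 1000)),
              1e-6)
    expect_lt(max(abs(corr$set$maps[[nm]]$absorption - tr$absorption)), 1e-6)
    expect_lt(abs(corr$transforms[[nm]]$dx) + abs(corr$transforms[[nm]]$dy), 0.1)
  }
})

test_that("over-thick samples are refused", {
  sc <- synth_afmir_scene(afmir_scene_params(thick_sample = TRUE, seed = 1))
  expect_error(correct_afmir_set(sc$set), "too thick")
})

test_that("segmentation and log ratios recover droplet chemistry", {
  # noiseless scene: exact hypha mask
  sc0 <- synth_afmir_scene(clean_afmir_params())
  c0 <- correct_afmir_set(sc0$set)
  m0 <- segment_afmir(c0$set, seed = 0)
  expect_gte(jaccard(m0$foreground, sc0$truth$hypha | sc0$truth$droplets), 0.95)
  # noisy scene with artifacts
  sc <- synth_afmir_scene(afmir_scene_params(seed = 4))
  corr <- correct_afmir_set(sc$set)
  mask <- segment_afmir(corr$set, seed = 0)
  expect_gte(jaccard(mask$foreground, sc$truth$hypha | sc$truth$droplets), 0.9)
  expect_identical(segment_afmir(corr$set, seed = 7)$foreground,
                   mask$foreground)
  # trivial log ratios
  lp <- laser_power(seq(1510, 1800, 10), rep(1, 30))
  mk <- function(a) list(topography = matrix(1, 4, 4),
                         deflection = matrix(0.1, 4, 4),
                         absorption = matrix(a, 4, 4))
  set2 <- afmir_set(list("1600" = mk(1), "1708" = mk(1), "1742" = mk(10)), 5, lp)
  allfg <- structure(list(foreground = matrix(TRUE, 4, 4)),
                     class = "segmentation_mask")
  lr <- log_ratio_maps(set2, allfg)
  expect_equal(lr$absorption_ratios[["1742:1600"]][1, 1], 1)
  expect_equal(lr$absorption_ratios[["1708:1600"]][1, 1], 0)
  # droplet TAG:FFA amplitude 2:1 appears as log10(2) in the 1742/1708 map
  dr <- suppressWarnings(log10(corr$set$maps[["1742"]]$absorption /
                               corr$set$maps[["1708"]]$absorption))
  in_drop <- sc$truth$droplets & mask$foreground
  expect_lt(abs(median(dr[in_drop], na.rm = TRUE) - log10(2)), 0.05)
  # log ratios are invariant to a global laser-power rescale
  sc_p <- synth_afmir_scene(afmir_scene_params(seed = 4),
                            power = laser_power(seq(1510, 1800, 1),
                                                3 * default_laser_power()$power))
  corr_p <- correct_afmir_set(sc_p$set)
  mask_p <- segment_afmir(corr_p$set, seed = 0)
  lr1 <- log_ratio_maps(corr$set, mask)
  lr2 <- log_ratio_maps(corr_p$set, mask)
  expect_equal(lr2$absorption_ratios[["1742:1600"]],
               lr1$absorption_ratios[["1742:1600"]], tolerance = 1e-6)
})

test_that("droplets with inverted TAG:FFA ratios separate in sign", {
  sc <- synth_afmir_scene(afmir_scene_params(seed = 4,
                                             droplet_ratios = c(2, 0.5)))
  corr <- correct_afmir_set(sc$set)
  mask <- segment_afmir(corr$set, seed = 0)
  lr <- suppressWarnings(log10(corr$set$maps[["1742"]]$absorption /
                                 corr$set$maps[["1708"]]$absorption))
  dc <- sc$truth$droplet_centers
  r <- sc$truth$droplet_radius
  meds <- sapply(1:2, function(k) {
    dm <- mirlipid:::disk_mask(64, 64, dc[k, ], r) & mask$foreground
    median(lr[dm], na.rm = TRUE)
  })
  expect_gt(meds[1], 0)
  expect_lt(meds[2], 0)
})

test_that("point spectra average, smooth and resolve the carbonyl bands", {
  w <- seq(1510, 1800, by = 1)
  prof <- c(TAG = 0.5, FFA = 0.4, FFA_ionized = 0.1)
  # identical repeats average to themselves
  one <- synth_bulk_spectrum(prof, "HTS", w)
  reps_id <- ir_collection(w, rbind(one$absorbance, one$absorbance,
                                    one$absorbance, one$absorbance))
  expect_equal(mean_spectrum(reps_id)$absorbance, one$absorbance)
  # noisy repeats: carbonyl peaks at 1742 and 1708 within 2 cm^-1
  set.seed(33)
  reps <- t(sapply(1:4, function(i)
    synth_bulk_spectrum(prof, "HTS", w, noise_sd = 0.004,
                        seed = 100 + i)$absorbance))
  out <- preprocess_point_spectra(ir_collection(w, reps),
                                  second_derivative = TRUE)
  pk <- pick_peaks(out$spectrum, spectral_region(rbind(c(1690, 1800))),
                   prominence = 0.1)
  expect_lte(min(abs(pk$position - 1742)), 2)
  expect_lte(min(abs(pk$position - 1708)), 2)
  # EMSC against a reference is applied when requested
  ref <- ir_spectrum(w, one$absorbance)
  cor_ <- preprocess_point_spectra(ir_collection(w, 2 * reps + 0.3),
                                   reference = ref)
  plain <- preprocess_point_spectra(ir_collection(w, reps))
  expect_lt(max(abs(cor_$absorbance - plain$absorbance)), 0.05)
  # a narrow mono/diglyceride shoulder at 1735 resolves as its own
  # second-derivative minimum, distinct from the main ester band
  bands2 <- rbind(default_band_library(),
                  band_definition(1735, 4, 0.3, "TAG", "MAG/DAG C=O shoulder"))
  sp <- synth_bulk_spectrum(prof, "HTS", w, bands = bands2)
  d2 <- savitzky_golay(sp, sg_params(9L, 2L, 2L))
  v <- d2$absorbance; n <- length(v)
  mins <- w[which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n] &
                    v[2:(n - 1)] < 0) + 1]
  expect_true(any(mins >= 1733 & mins <= 1738))
  expect_true(any(mins >= 1741 & mins <= 1747))
})
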