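test_that("cube trimming keeps the 3200-1000 working range", {
  vals <- array(0.1, c(3, 3, 7))
  cube <- hyper_cube(vals, c(900, 1000, 1500, 2500, 3200, 3500, 3900))
  tr <- trim_cube(cube)
  expect_equal(tr$wavenumber, c(1000, 1500, 2500, 3200))
  # already inside: identity
  inside <- hyper_cube(array(0.1, c(3, 3, 2)), c(1200, 1800))
  expect_equal(trim_cube(inside)$wavenumber, c(1200, 1800))
  above <- hyper_cube(array(0.1, c(3, 3, 2)), c(3300, 3600))
  expect_error(trim_cube(above), "no bands remain")
})

test_that("scaled-MAD flagging isolates spikes and obeys the normal tail rate", {
  # a zero map with one hot pixel: only that pixel flagged (MAD = 0
  # falls back to the standard deviation, with a warning)
  vals <- array(0, c(8, 8, 2))
  vals[3, 5, 1] <- 10
  vals[3, 5, 2] <- 10
  cube <- hyper_cube(vals, c(1000, 1100))
  suppressWarnings(expect_warning(om <- flag_outliers(cube), "zero MAD"))
  expect_equal(sum(om$mask), 2L)
  expect_true(om$mask[3, 5, 1])
  # the hot-in-every-band pixel is a global outlier
  expect_equal(which(om$global), (5L - 1L) * 8L + 3L)
  # i.i.d. Gaussian maps: flagged fraction ~ 2 Phi(-3) within 3 MC s.e.
  set.seed(11)
  rates <- replicate(40, {
    v <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
    mean(flag_outliers(hyper_cube(v, c(1000, 1008)))$mask)
  })
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 2 * pnorm(-3)), 3 * se)
})

test_that("neighbour-mean repair restores planted outliers", {
  # a flagged pixel surrounded by 2s becomes 2
  vals <- array(2, c(5, 5, 2))
  vals[3, 3, 1] <- 50
  cube <- hyper_cube(vals, c(1000, 1100))
  mask <- structure(list(mask = array(vals > 10, dim(vals)),
                         global = matrix(FALSE, 5, 5),
                         band_counts = c(1L, 0L)), class = "outlier_mask")
  rep_ <- repair_outliers(cube, mask)
  expect_equal(rep_$values[3, 3, 1], 2)
  # corner pixel with clean neighbours {1, 2, 3}
  v2 <- array(0, c(3, 3, 2))
  v2[1, 1, 1] <- 99
  v2[2, 1, 1] <- 1; v2[1, 2, 1] <- 2; v2[2, 2, 1] <- 3
  m2 <- structure(list(mask = array(v2 > 10, dim(v2)),
                       global = matrix(FALSE, 3, 3),
                       band_counts = c(1L, 0L)), class = "outlier_mask")
  r2 <- repair_outliers(hyper_cube(v2, c(1000, 1100)), m2)
  expect_equal(r2$values[1, 1, 1], 2)
  # planted 1% outliers at ten scaled MADs: full recall, and repair cuts
  # the error at the damaged pixels by far more than 10x
  sc <- synth_fpa_scene("flat_hypha", seed = 13, outlier_rate = 0.01)
  cube3 <- trim_cube(sc$cube)
  keep <- sc$cube$wavenumber >= 1000 & sc$cube$wavenumber <= 3200
  truth_out <- sc$truth$outliers[, , keep]
  clean <- sc$truth$clean[, , keep]
  om <- flag_outliers(cube3)
  expect_equal(sum(om$mask & truth_out) / sum(truth_out), 1)
  r3 <- repair_outliers(cube3, om)
  pre <- sqrt(mean((cube3$values[truth_out] - clean[truth_out])^2))
  post <- sqrt(mean((r3$values[truth_out] - clean[truth_out])^2))
  expect_lt(post, pre / 10)
})

test_that("flag/repair is idempotent up to the false-positive floor", {
  sc <- synth_fpa_scene("yeast", seed = 12, outlier_rate = 0.01)
  cube <- trim_cube(sc$cube)
  repaired <- repair_outliers(cube, flag_outliers(cube))
  refl <- flag_outliers(repaired)
  expect_lt(mean(refl$mask), 2 * pnorm(-3) + 0.001)
})

test_that("PCA + k-means segmentation recovers cell masks", {
  # a noiseless disk on an empty slide is recovered exactly
  sc0 <- synth_fpa_scene("yeast", rows = 48L, cols = 48L, seed = 1,
                         outlier_rate = 0, scatter_sd = 0, noise_sd = 0)
  m0 <- segment_cube(sc0$cube, seed = 0)
  expect_equal(m0$foreground, sc0$truth$foreground)
  # SNR 10 (band amplitude about ten times the noise sd)
  sc <- synth_fpa_scene("flat_hypha", seed = 3, noise_sd = 0.04)
  cube <- repair_outliers(trim_cube(sc$cube), flag_outliers(trim_cube(sc$cube)))
  m <- segment_cube(cube, seed = 0)
  expect_gte(jaccard(m$foreground, sc$truth$foreground), 0.95)
  # foreground + background tile the frame
  expect_equal(sum(m$foreground) + sum(!m$foreground), 128L * 128L)
  # stability across seeds on well-separated data
  m2 <- segment_cube(cube, seed = 99)
  expect_identical(m$foreground, m2$foreground)
  # invariance to per-band affine intensity rescaling
  cube_s <- cube
  for (b in seq_along(cube$wavenumber))
    cube_s$values[, , b] <- 3.7 * cube$values[, , b] + 0.21
  m3 <- segment_cube(cube_s, seed = 0)
  expect_identical(m3$foreground, m$foreground)
})

test_that("descattering corrects foreground spectra and leaves background alone", {
  # pixel-wise affine distortions of the mean collapse back onto it
  w <- seq(1000, 3200, by = 8)
  m <- synth_bulk_spectrum(typical_profile(), "HTS", w)$absorbance
  nr <- 6L; nc <- 6L
  vals <- array(0, c(nr, nc, length(w)))
  set.seed(9)
  fg_truth <- matrix(FALSE, nr, nc); fg_truth[2:5, 2:5] <- TRUE
  flat <- matrix(0, nr * nc, length(w))
  for (p in which(fg_truth)) flat[p, ] <- runif(1, -.2, .2) + runif(1, 0.5, 2) * m
  cube <- hyper_cube(array(flat, c(nr, nc, length(w))), w)
  mask <- structure(list(foreground = fg_truth, cluster_means = NULL,
                         n_components = 1L), class = "segmentation_mask")
  out <- descatter(cube, mask, sg = sg_params(9L, 2L, 0L))
  flat_out <- matrix(out$values, nr * nc, length(w))
  # every affine-distorted spectrum collapses onto the foreground mean
  ref <- colMeans(flat[which(fg_truth), ])
  sm_ref <- savitzky_golay(ir_spectrum(w, ref), sg_params(9L, 2L, 0L))$absorbance
  for (p in which(fg_truth))
    expect_lt(max(abs(flat_out[p, ] - sm_ref)), 1e-8)
  # background bitwise unchanged
  expect_identical(flat_out[which(!fg_truth), ], flat[which(!fg_truth), ])
  # planted smooth baseline ripple on a uniform-composition scene is
  # suppressed at least five-fold
  geom <- list(list(form = "flat_hypha", lipid_scale = 1,
                    mask_fun = function(ctr) {
                      m <- matrix(FALSE, 64, 64); m[10:54, 20:44] <- TRUE; m
                    },
                    center = c(32, 32), droplets = NULL))
  scr <- synth_fpa_scene(geom, rows = 64L, cols = 64L, outlier_rate = 0,
                         scatter_sd = 0.03, noise_sd = 0, seed = 17)
  msk <- structure(list(foreground = scr$truth$foreground, cluster_means = NULL,
                        n_components = 1L), class = "segmentation_mask")
  cor_ <- descatter(scr$cube, msk)
  fg <- which(scr$truth$foreground)
  d <- dim(scr$cube$values)
  pre <- matrix(scr$cube$values, d[1] * d[2], d[3])
  post <- matrix(cor_$values, d[1] * d[2], d[3])
  clean <- matrix(scr$truth$clean, d[1] * d[2], d[3])
  # compare each side against its own smoothness class: the corrected
  # spectra carry the stand-in's SG smoothing, so their baseline residual
  # is measured against the smoothed clean truth
  clean_s <- t(apply(clean, 1L, function(x)
    savitzky_golay(ir_spectrum(scr$cube$wavenumber, x),
                   sg_params(9L, 2L, 0L))$absorbance))
  resid <- function(M, ref) mean(sapply(fg, function(p) {
    b <- sum(M[p, ] * ref[p, ]) / sum(ref[p, ]^2)
    sqrt(mean((M[p, ] - b * ref[p, ])^2))
  }))
  expect_lt(resid(post, clean_s), resid(pre, clean) / 5)
  # tiny foregrounds are skipped with a warning
  tiny <- structure(list(foreground = matrix(FALSE, nr, nc),
                         cluster_means = NULL, n_components = 1L),
                    class = "segmentation_mask")
  expect_warning(same <- descatter(cube, tiny), "skipped")
  expect_identical(same$values, cube$values)
})

test_that("band and ratio maps floor small denominators and order cell forms", {
  vals <- array(0, c(2, 2, 2))
  vals[, , 1] <- 0.6; vals[, , 2] <- 0.3   # 1742 and 1650 band images
  vals[2, 2, 2] <- 1e-5
  cube <- hyper_cube(vals[, , 2:1], c(1650, 1742))
  mask <- structure(list(foreground = matrix(TRUE, 2, 2), cluster_means = NULL,
                        n_components = 1L), class = "segmentation_mask")
  out <- band_and_ratio_maps(cube, mask, bands = c(1742, 1650),
                             ratio_pairs = list(c(1742, 1650)))
  rm_ <- out$ratio_maps[["1742:1650"]]
  expect_equal(rm_[1, 1], 2)
  expect_true(is.na(rm_[2, 2]))
  expect_equal(unname(out$flagged["1742:1650"]), 1L)
  # lipid-to-protein ratio medians order the three cell forms
  med <- sapply(c("flat_hypha", "swollen_hypha", "yeast"), function(f) {
    s <- synth_fpa_scene(f, seed = 3)
    cb <- trim_cube(s$cube)
    cb <- repair_outliers(cb, flag_outliers(cb))
    m <- segment_cube(cb, seed = 0)
    median(band_and_ratio_maps(cb, m)$ratio_maps[[1]], na.rm = TRUE)
  })
  expect_true(med["flat_hypha"] < med["swollen_hypha"])
  expect_true(med["swollen_hypha"] < med["yeast"])
})
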