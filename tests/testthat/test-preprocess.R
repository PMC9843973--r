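test_that("absorbance is the negative log10 ratio of sample to background", {
  w <- seq(1000, 1200, by = 4)
  n <- length(w)
  expect_equal(compute_absorbance(rep(2, n), rep(2, n), w)$absorbance,
               rep(0, n))
  expect_equal(compute_absorbance(rep(0.1, n), rep(1, n), w)$absorbance,
               rep(1, n))
  expect_equal(compute_absorbance(rep(0.5, n), rep(1, n), w)$absorbance,
               rep(log10(2), n), tolerance = 1e-12)
  expect_error(compute_absorbance(rep(1, n), rep(0, n), w), "positive")
  expect_error(compute_absorbance(rep(-1, n), rep(1, n), w), "positive")
})

test_that("Savitzky-Golay reproduces polynomials and their derivatives", {
  w <- seq(1000, 1200, by = 4)
  a <- 3e-4
  quad <- ir_spectrum(w, a * w^2)
  # interior points of a quadratic pass through untouched
  sm <- savitzky_golay(quad, sg_params(15L, 2L, 0L))
  expect_equal(sm$absorbance, quad$absorbance, tolerance = 1e-9)
  # second derivative of a*w^2 is the constant 2a (derivative taken with
  # respect to wavenumber)
  d2 <- savitzky_golay(quad, sg_params(15L, 2L, 2L))
  expect_equal(d2$absorbance[8:44], rep(2 * a, 37), tolerance = 1e-10)
  # a Gaussian band's second derivative has its minimum at the band
  # centre, within one grid step
  g <- gauss_spectrum(w, centers = 1100, widths = 15, amps = 1)
  gd2 <- savitzky_golay(g, sg_params(15L, 2L, 2L))
  expect_lte(abs(w[which.min(gd2$absorbance)] - 1100), 4)
  # parameter validation
  expect_error(sg_params(14L, 2L, 2L), "odd")
  expect_error(sg_params(15L, 2L, 3L), "derivative order")
  expect_error(savitzky_golay(ir_spectrum(w[1:10], rep(0, 10)),
                              sg_params(15L, 2L, 0L)), "shorter")
})

test_that("the SG filter is linear", {
  w <- seq(700, 1800, by = 4)
  set.seed(8)
  x <- rnorm(length(w)); y <- rnorm(length(w))
  p <- sg_params(15L, 2L, 2L)
  fx <- savitzky_golay(ir_spectrum(w, x), p)$absorbance
  fy <- savitzky_golay(ir_spectrum(w, y), p)$absorbance
  fxy <- savitzky_golay(ir_spectrum(w, 2.5 * x - 1.3 * y), p)$absorbance
  expect_equal(fxy, 2.5 * fx - 1.3 * fy, tolerance = 1e-12)
})

test_that("EMSC recovers the reference under affine and polynomial distortion", {
  w <- seq(700, 1800, by = 4)
  m <- gauss_spectrum(w)$absorbance
  t1 <- 2 * (w - min(w)) / diff(range(w)) - 1
  s1 <- 2 + 3 * m                      # affine
  s2 <- m + 0.001 * w                  # linear baseline (raw-axis slope)
  s3 <- 0.5 - 1.2 * t1 + 0.8 * t1^2 + 1.7 * m  # full quadratic distortion
  coll <- ir_collection(w, rbind(s1, s2, s3))
  fit <- emsc_fit_correct(coll, ir_spectrum(w, m), poly_order = 2L)
  for (i in 1:3)
    expect_lt(max(abs(fit$corrected$data[i, ] - m)), 1e-10)
  expect_equal(unname(unlist(fit$model$coefficients[1, c("a", "b")])),
               c(2, 3), tolerance = 1e-10)
  expect_equal(unname(unlist(fit$model$coefficients[3, ])),
               c(0.5, 1.7, -1.2, 0.8), tolerance = 1e-10)
})

test_that("EMSC matches an independent normal-equations oracle on noisy data", {
  w <- seq(700, 1800, by = 4)
  m <- gauss_spectrum(w)$absorbance
  set.seed(21)
  s <- m + rnorm(length(w), sd = 0.02)
  coll <- ir_collection(w, matrix(s, 1))
  fit <- emsc_fit_correct(coll, ir_spectrum(w, m), poly_order = 2L)
  # brute-force least squares via the normal equations
  t1 <- 2 * (w - min(w)) / diff(range(w)) - 1
  X <- cbind(1, t1, t1^2, m)
  beta <- solve(t(X) %*% X, t(X) %*% s)
  corrected_oracle <- m + (s - as.vector(X %*% beta)) / beta[4]
  expect_equal(as.vector(fit$corrected$data), corrected_oracle,
               tolerance = 1e-9)
})

test_that("EMSC is idempotent and the reference maps to itself", {
  w <- seq(700, 1800, by = 4)
  m <- gauss_spectrum(w)$absorbance
  set.seed(4)
  X <- rbind(m, 1 + 2 * m + rnorm(length(w), sd = 0.01),
             0.5 * m + rnorm(length(w), sd = 0.01))
  coll <- ir_collection(w, X)
  ref <- ir_spectrum(w, m)
  once <- emsc_fit_correct(coll, ref)$corrected
  twice_fit <- emsc_fit_correct(once, ref)
  expect_lt(max(abs(twice_fit$corrected$data - once$data)), 1e-10)
  # the reference spectrum itself: b = 1, all baseline terms 0
  cf <- emsc_fit_correct(coll, ref)$model$coefficients[1, ]
  expect_equal(unname(unlist(cf)), c(0, 1, 0, 0), tolerance = 1e-10)
  # a flat spectrum is flagged, not corrected
  flat <- ir_collection(w, rbind(rep(0.2, length(w)), m))
  ffit <- emsc_fit_correct(flat, ref)
  expect_true(ffit$model$flagged[1])
  expect_equal(ffit$corrected$data[1, ], rep(0.2, length(w)))
})

test_that("region selection handles unions, identity and nesting", {
  camp <- synth_campaign(campaign_design("ATR", seed = 2))
  coll <- camp$collection
  lip <- select_region(coll, "lipid_combined")
  # two contiguous blocks concatenated
  gaps <- which(diff(lip$wavenumber) > 4)
  expect_equal(length(gaps), 1L)
  expect_true(all(lip$wavenumber >= 1700 & lip$wavenumber <= 3050))
  expect_true(any(lip$wavenumber <= 1800) && any(lip$wavenumber >= 2800))
  # full-axis region is the identity
  full <- select_region(coll, spectral_region(rbind(c(400, 4000))))
  expect_equal(full$data, coll$data)
  expect_error(select_region(coll, spectral_region(rbind(c(4100, 4200)))),
               "does not intersect")
  # nested selection equals the inner selection
  inner <- spectral_region(rbind(c(1720, 1760)))
  expect_equal(select_region(select_region(coll, "lipid_combined"), inner)$data,
               select_region(coll, inner)$data)
  # overlapping intervals merge
  reg <- spectral_region(rbind(c(1700, 1500), c(1550, 1400)))
  expect_equal(nrow(reg), 1L)
  expect_equal(unname(reg[1, ]), c(1400, 1700))
})

test_that("replicate averaging produces one mean spectrum per design group", {
  w <- seq(1000, 1100, by = 10)
  X <- rbind(rep(0, 11), rep(1, 11), rep(0.2, 11))
  meta <- data.frame(spectrum_id = c("r1", "r2", "r3"),
                     sample = c("A", "A", "B"))
  coll <- ir_collection(w, X, meta)
  avg <- average_replicates(coll, "sample")
  expect_equal(n_spectra(avg), 2L)
  expect_equal(unname(avg$data[avg$meta$sample == "A", ]), rep(0.5, 11))
  expect_equal(avg$meta$group_size[avg$meta$sample == "A"], 2L)
  # identical replicates average to themselves
  same <- ir_collection(w, rbind(X[2, ], X[2, ], X[2, ]),
                        data.frame(sample = rep("A", 3)))
  expect_equal(unname(average_replicates(same, "sample")$data[1, ]), X[2, ])
  # the 126-spectrum campaign collapses to 6 x 7 = 42 condition-day means
  camp <- synth_campaign(campaign_design("ATR", seed = 2))
  means <- average_replicates(camp$collection, c("sample", "day"))
  expect_equal(n_spectra(means), 42L)
  expect_true(all(means$meta$group_size == 3L))
  expect_error(average_replicates(coll, "nope"), "absent from metadata")
})
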