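# Shared fixture builders (all fixtures are generated in code).

# a smooth two-band test spectrum on an even axis
gauss_spectrum <- function(w = seq(700, 1800, by = 4),
                           centers = c(1650, 1080),
                           widths = c(30, 40),
                           amps = c(1, 0.5)) {
  a <- rep(0, length(w))
  for (i in seq_along(centers))
    a <- a + amps[i] * exp(-0.5 * ((w - centers[i]) / widths[i])^2)
  ir_spectrum(w, a)
}

# a small designed collection: two factors with known planted effects
toy_design_matrix <- function(n_channels = 20, a_amp = 0, b_amp = 0,
                              noise_sd = 0, seed = 1) {
  set.seed(seed)
  lab_a <- rep(c("a1", "a2"), each = 6)
  lab_b <- rep(rep(c("b1", "b2"), each = 3), 2)
  base <- rnorm(n_channels)
  X <- outer(ifelse(lab_a == "a1", -a_amp, a_amp), base) +
    outer(ifelse(lab_b == "b1", -b_amp, b_amp), rev(base)) +
    matrix(rnorm(12 * n_channels, sd = noise_sd), 12)
  list(X = X, lab_a = lab_a, lab_b = lab_b)
}

# standard bulk composition used across tests
typical_profile <- function() {
  c(TAG = 0.30, FFA = 0.06, FFA_ionized = 0.04, protein = 0.25,
    polysaccharide = 0.20, polyphosphate = 0.05, water = 0.10)
}

# artifact-free AFM-IR scene parameters
clean_afmir_params <- function(seed = 1, ...) {
  afmir_scene_params(tilt = c(0, 0), line_offset_sd = 0,
                     drift = list("1600" = rigid_transform(0, 0, 0),
                                  "1708" = rigid_transform(0, 0, 0),
                                  "1742" = rigid_transform(0, 0, 0)),
                     contact_rate = 0, noise_sd = 0, seed = seed, ...)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
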