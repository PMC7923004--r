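# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# default phantom, noise-free (deterministic geometry/waveform reference)
default_phantom_nf <- function() fixture("ph_nf", function() {
  render_cine(lumen_geometry(), waveform_spec(), acquisition_spec(snr = Inf))
})

# same phantom with a pixel-centered larger lumen (low partial-volume case)
centered_phantom_nf <- function() fixture("ph_big", function() {
  render_cine(lumen_geometry(center = c(0.195, 0.195),
                             semi_axes = c(1.3, 1.3)),
              waveform_spec(), acquisition_spec(snr = Inf))
})

# corrected velocity maps for a phantom list
corrected_vmaps <- function(ph) {
  background_correct(phase_to_velocity(ph$series),
                     propose_nfa(ph$truth$true_mask))
}

default_vmaps_nf <- function() fixture("vm_nf", function() {
  corrected_vmaps(default_phantom_nf())
})

# random mask pair on a small grid (for Dice property tests)
random_mask <- function(ny = 12, nx = 12, p = 0.3) {
  matrix(runif(ny * nx) < p, ny, nx)
}

# direct (brute-force) Dice via explicit set arithmetic on coordinates
dice_bruteforce <- function(a, b) {
  ca <- which(a); cb <- which(b)
  if (length(ca) + length(cb) == 0) return(1)
  2 * length(intersect(ca, cb)) / (length(ca) + length(cb))
}

# independent ICC(A,1) oracle from stats::aov mean squares
icc_a1_aov <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subj = factor(rep(seq_len(n), k)),
                  rep = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rep, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
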