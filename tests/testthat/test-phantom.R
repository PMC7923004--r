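# Waveform template, cine rendering physics, analytic ground truth.

test_that("waveform template: null, sinusoid and two-lobe cases", {
  # null flow
  z <- make_waveform(waveform_spec(0, 0, net_offset = 0))
  expect_equal(as.numeric(z), rep(0, 32))

  # symmetric equal-amplitude case collapses to a pure sinusoid
  sp <- waveform_spec(systolic_amplitude = 5, diastolic_amplitude = 5,
                      net_offset = 0, systolic_fraction = 0.5,
                      rr_interval = 1, n_frames = 32L)
  v <- make_waveform(sp)
  t <- attr(v, "times")
  expect_equal(as.numeric(v), 5 * sin(2 * pi * t), tolerance = 1e-12)
  expect_equal(mean(v), 0, tolerance = 1e-12)

  # asymmetric two-lobe template against an independently coded oracle
  sp2 <- waveform_spec(systolic_amplitude = 10, diastolic_amplitude = 7,
                       net_offset = 0, systolic_fraction = 0.4,
                       rr_interval = 0.8, n_frames = 32L)
  v2 <- make_waveform(sp2)
  oracle <- function(tt) {
    u <- (tt / 0.8) %% 1
    c0 <- 0 - (2 / pi) * (10 * 0.4 - 7 * 0.6)
    ifelse(u < 0.4, 10 * sin(pi * u / 0.4),
           -7 * sin(pi * (u - 0.4) / 0.6)) + c0
  }
  expect_equal(as.numeric(v2), oracle(attr(v2, "times")), tolerance = 1e-12)
  # the 32-point midpoint mean carries a small discretization error when the
  # lobe boundary (0.4 * 32 = 12.8 frames) is not frame-aligned
  expect_equal(mean(v2), 0, tolerance = 5e-3)
  expect_equal(mean(centerline_velocity(sp2, seq(0, 0.8, length.out = 1e5 + 1)[-1] - 0.8 / 2e5)),
               0, tolerance = 1e-8)
  # caudal lobe occupies the systolic fraction of the cycle
  u <- (attr(v2, "times") / 0.8) %% 1
  c0 <- -(2 / pi) * (10 * 0.4 - 7 * 0.6)
  expect_true(all(v2[u < 0.4] > c0))
  expect_true(min(v2) < 0)
})

test_that("waveform invariants and aliasing guard", {
  expect_error(waveform_spec(systolic_fraction = 0), "systolic_fraction")
  expect_error(waveform_spec(systolic_amplitude = -1), ">= 0")
  expect_error(waveform_spec(n_frames = 4), "n_frames")
  sp <- waveform_spec(systolic_amplitude = 25)
  expect_error(make_waveform(sp, venc = 20), "aliases")
  expect_silent(make_waveform(sp, venc = 20, allow_wrap = TRUE))
})

test_that("rendering null and constant-offset cases are exact", {
  geo <- lumen_geometry(center = c(0, 0), semi_axes = c(1, 1))
  wf0 <- waveform_spec(0, 0, net_offset = 0)
  acq0 <- acquisition_spec(snr = Inf, phase_offset_field = c(0, 0, 0),
                           matrix_size = 32L)
  ph <- render_cine(geo, wf0, acq0)
  expect_equal(max(abs(ph$series$phase)), 0)

  acqc <- acquisition_spec(snr = Inf, phase_offset_field = c(0.3, 0, 0),
                           matrix_size = 32L)
  phc <- render_cine(geo, wf0, acqc)
  # every pixel (pure parenchyma and lumen alike at zero flow) carries c
  expect_equal(unique(round(as.vector(phc$series$phase), 12)), 0.3)
})

test_that("center-pixel phase matches a brute-force supersampled oracle", {
  geo <- lumen_geometry(center = c(0.195, 0.195), semi_axes = c(1.3, 1.3))
  sp <- waveform_spec(systolic_amplitude = 10, diastolic_amplitude = 7,
                      net_offset = 0.4)
  acq <- acquisition_spec(snr = Inf, phase_offset_field = c(0, 0, 0),
                          matrix_size = 32L, supersampling = 8L)
  ph <- render_cine(geo, sp, acq)
  v_c <- ph$truth$centerline
  k <- which.max(v_c)

  # independent oracle: double-loop phasor sum at supersampling 16
  n <- 32L; s <- 16L; sp_mm <- acq$pixel_spacing
  centers <- (seq_len(n) - (n + 1) / 2) * sp_mm
  iy <- which.min(abs(centers - 0.195)); ix <- iy
  offs <- ((seq_len(s) - 0.5) / s - 0.5) * sp_mm
  z <- 0 + 0i
  for (oy in offs) for (ox in offs) {
    e <- ((centers[iy] + oy - 0.195)^2 + (centers[ix] + ox - 0.195)^2) / 1.3^2
    z <- z + if (e <= 1) 1.5 * exp(1i * pi * v_c[k] * (1 - e) / 20) else 1 + 0i
  }
  expect_equal(ph$series$phase[iy, ix, k], Arg(z / s^2), tolerance = 2e-3)
})

test_that("fixed seed gives bit-identical series; noise obeys the seed", {
  geo <- lumen_geometry(); sp <- waveform_spec()
  a <- render_cine(geo, sp, acquisition_spec(snr = 20, seed = 123))
  b <- render_cine(geo, sp, acquisition_spec(snr = 20, seed = 123))
  d <- render_cine(geo, sp, acquisition_spec(snr = 20, seed = 124))
  expect_identical(a$series$phase, b$series$phase)
  expect_identical(a$series$magnitude, b$series$magnitude)
  expect_false(identical(a$series$phase, d$series$phase))
})

test_that("doubling supersampling changes rendered phase by < 1% of VENC", {
  geo <- lumen_geometry(); sp <- waveform_spec()
  a <- render_cine(geo, sp, acquisition_spec(snr = Inf, supersampling = 8L))
  b <- render_cine(geo, sp, acquisition_spec(snr = Inf, supersampling = 16L))
  dv <- 20 * max(abs(a$series$phase - b$series$phase)) / pi
  expect_lt(dv, 0.01 * 20)
})

test_that("summed pixel flux over the footprint matches analytic flow rate", {
  # offset-free, brightness-neutral rendering: pixel velocities then carry
  # lumen flux only (the CSF-brightness weighting is a separate, documented
  # boundary-flux bias)
  ph <- render_cine(lumen_geometry(center = c(0.195, 0.195),
                                   semi_axes = c(1.3, 1.3)),
                    waveform_spec(),
                    acquisition_spec(snr = Inf,
                                     phase_offset_field = c(0, 0, 0),
                                     lumen_brightness = 1))
  vm <- phase_to_velocity(ph$series)
  foot <- ph$truth$lumen_fraction_map > 0
  csa_true <- ph$truth$geometry$csa
  v_c <- ph$truth$centerline
  px_mm2 <- ph$series$pixel_spacing^2
  for (k in c(which.max(v_c), which.min(v_c))) {
    flux <- sum(vm$v[, , k][foot]) * px_mm2      # cm/s * mm^2
    analytic <- v_c[k] / 2 * csa_true
    expect_equal(flux, analytic, tolerance = 0.01)
  }
})

test_that("analytic true measures obey closed forms", {
  # zero waveform: all measures zero
  tr0 <- list(geometry = lumen_geometry(semi_axes = c(1.5, 1.5)),
              waveform = waveform_spec(0, 0, net_offset = 0))
  m0 <- true_measures(tr0)
  expect_equal(max(abs(unlist(unclass(m0)[aqueflow:::MEASURE_NAMES][-1]))), 0)
  # circular lumen radius 1.5 mm
  expect_equal(m0$csa_avg, 7.0686, tolerance = 1e-4)

  # sinusoidal flow rate: caudal volume Q*T/pi
  sp <- waveform_spec(systolic_amplitude = 8, diastolic_amplitude = 8,
                      net_offset = 0, systolic_fraction = 0.5,
                      rr_interval = 1)
  tr <- list(geometry = lumen_geometry(semi_axes = c(1, 1)), waveform = sp)
  m <- true_measures(tr)
  q_peak <- 8 / 2 * pi * 0.6                      # mL/min
  expect_equal(m$caudal_volume, q_peak * 1 / pi * 1000 / 60,
               tolerance = 1e-6)
  expect_equal(m$cranial_volume, -m$caudal_volume, tolerance = 1e-6)
  expect_equal(m$net_volume, 0, tolerance = 1e-9)
})

test_that("geometry outside the field of view is rejected", {
  expect_error(render_cine(lumen_geometry(center = c(13, 0)),
                           waveform_spec(), acquisition_spec(snr = Inf)),
               "field of view")
})
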