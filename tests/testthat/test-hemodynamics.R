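# Time courses, peaks, volume integration, Reynolds number, summaries.

flat_vmaps <- function(v_array) {
  velocity_maps(v_array, venc = 20, pixel_spacing = 1, rr_interval = 1,
                corrected = TRUE)
}

test_that("time courses obey the unit chain and single-pixel limits", {
  # vmean 1 cm/s over 1 mm^2 is 0.6 mL/min
  v <- array(1, dim = c(1, 1, 2))
  tc <- compute_timecourses(flat_vmaps(v), array(TRUE, dim = c(1, 1, 2)))
  expect_equal(tc$csa, c(1, 1))
  expect_equal(tc$flow_rate, c(0.6, 0.6))

  # single-pixel mask: vmean = vmax = that pixel's value
  v2 <- array(rnorm(3 * 3 * 4), dim = c(3, 3, 4))
  m <- array(FALSE, dim = c(3, 3, 4)); m[2, 2, ] <- TRUE
  tc2 <- compute_timecourses(flat_vmaps(v2), m)
  expect_equal(tc2$vmean, v2[2, 2, ])
  expect_equal(tc2$vmax, v2[2, 2, ])

  # uncorrected maps are rejected (ordering contract)
  vu <- velocity_maps(v2, 20, 1, 1, corrected = FALSE)
  expect_error(compute_timecourses(vu, m), "corrected")
  # empty mask at any frame is rejected
  m[, , 2] <- FALSE
  expect_error(compute_timecourses(flat_vmaps(v2), m), "empty mask")
})

test_that("vmax is the signed value at the largest-|v| pixel", {
  v <- array(0, dim = c(2, 2, 2))
  v[1, 1, 1] <- -8; v[2, 1, 1] <- 5
  v[1, 1, 2] <- 3;  v[2, 1, 2] <- 2
  tc <- compute_timecourses(flat_vmaps(v), array(TRUE, dim = c(2, 2, 2)))
  expect_equal(tc$vmax, c(-8, 3))
})

test_that("peak extraction is signed with earliest-frame tie-break", {
  p <- find_peaks(c(0, 5, -3))
  expect_equal(c(p$sys, p$dia), c(5, -3))
  expect_equal(c(p$sys_frame, p$dia_frame), c(2L, 3L))
  # all-positive series: diastolic peak is simply the smallest value
  p2 <- find_peaks(c(2, 1, 4))
  expect_equal(p2$dia, 1)
  p3 <- find_peaks(c(7, 1, 7, 1))
  expect_equal(p3$sys_frame, 1L)
})

test_that("volume integration matches closed forms", {
  expect_equal(unname(integrate_volumes(rep(0, 32), 1)), c(0, 0, 0))

  # half-sine rectification at dense sampling
  T_ <- 0.9; Q <- 8
  t_dense <- (seq_len(20000) - 0.5) / 20000 * T_
  fr_dense <- Q * sin(2 * pi * t_dense / T_)
  vol <- integrate_volumes(fr_dense, T_)
  expect_equal(vol[["caudal"]], Q * T_ / pi * 1000 / 60, tolerance = 1e-6)
  expect_equal(vol[["cranial"]], -vol[["caudal"]], tolerance = 1e-6)
  expect_equal(vol[["net"]], 0, tolerance = 1e-9)

  # 32 gated frames recover the analytic half-sine volume within 0.5%
  t32 <- (seq_len(32) - 0.5) / 32 * T_
  vol32 <- integrate_volumes(Q * sin(2 * pi * t32 / T_), T_)
  expect_equal(vol32[["caudal"]], Q * T_ / pi * 1000 / 60, tolerance = 5e-3)

  # non-monotone times rejected
  tc <- structure(list(flow_rate = 1:3, times = c(0.1, 0.3, 0.2),
                       rr_interval = 1), class = "time_courses")
  expect_error(integrate_volumes(tc), "increasing")
})

test_that("Reynolds number follows rho V D / mu", {
  expect_equal(reynolds(0, 5), 0)
  # 19 cm/s through 6.6 mm^2 (circular-equivalent D = 2.899 mm)
  re <- reynolds(19, 6.6)
  expect_equal(2 * sqrt(6.6 / pi), 2.899, tolerance = 1e-3)
  expect_equal(re, 1000 * 0.19 * 2.899e-3 / 1e-3, tolerance = 1e-3)
  expect_gt(re, 500); expect_lt(re, 600)
  # proportionalities
  expect_equal(reynolds(19, 6.6, viscosity = 0.5), 2 * re)
  # far below the turbulence threshold for the phantom regime
  ph <- default_phantom_nf()
  tm <- ph$truth$true_measures
  expect_lt(reynolds(tm$vmax_sys_peak, tm$csa_avg), 2000)
})

test_that("summary measures are internally consistent on the phantom", {
  ph <- default_phantom_nf()
  vm <- default_vmaps_nf()
  tc <- compute_timecourses(vm, ph$truth$true_mask)
  m <- summarize_measures(tc)
  # conservation to 1e-9 relative
  expect_equal(m$net_volume, m$caudal_volume + m$cranial_volume,
               tolerance = 1e-9)
  # average flow rate reconciles with net volume over the cycle
  expect_equal(m$fr_avg * attr(m, "rr_interval") * 1000 / 60, m$net_volume,
               tolerance = 1e-9)
  # max >= mean on the same pixels; signs of the peaks
  expect_gte(abs(m$vmax_sys_peak), m$vmean_sys_peak)
  expect_gte(m$vmean_sys_peak, 0)
  expect_lte(m$vmean_dia_peak, 0)
  # biphasic near-cancellation: cycle averages are small next to peaks
  expect_lt(abs(m$vmean_avg), 0.25 * m$vmean_sys_peak)
  expect_lt(abs(m$fr_avg), 0.25 * m$fr_sys_peak)
  expect_lt(abs(m$net_volume), 0.5 * m$caudal_volume)
})

test_that("true mask recovers truth within partial-volume limits", {
  # pixel-centered lumen, moderate phase, no background field: the only
  # Vmax error source left is in-pixel profile averaging
  ph <- render_cine(lumen_geometry(center = c(0.195, 0.195),
                                   semi_axes = c(1.3, 1.3)),
                    waveform_spec(systolic_amplitude = 6,
                                  diastolic_amplitude = 4.5,
                                  net_offset = 0.3),
                    acquisition_spec(snr = Inf,
                                     phase_offset_field = c(0, 0, 0)))
  vm <- corrected_vmaps(ph)
  tc <- compute_timecourses(vm, ph$truth$true_mask)
  v_c <- ph$truth$centerline
  strong <- abs(v_c) > 1.5
  # vmax within 2% of the true centerline velocity
  expect_lt(max(abs(tc$vmax[strong] / v_c[strong] - 1)), 0.02)
  # vmean below centerline/2 (partial-volume dilution over the mask)
  expect_true(all(abs(tc$vmean[strong]) < abs(v_c[strong]) / 2))
  # peaks land on the truth frames
  expect_identical(find_peaks(tc$vmax)$sys_frame, which.max(v_c))
  expect_identical(find_peaks(tc$vmax)$dia_frame, which.min(v_c))
})

test_that("ROI size moves Vmean but never the Vmax peaks", {
  ph <- default_phantom_nf()
  vm <- default_vmaps_nf()
  tmask <- ph$truth$true_mask
  base <- summarize_measures(compute_timecourses(vm, tmask))
  prev_sys <- base$vmean_sys_peak; prev_dia <- base$vmean_dia_peak
  for (d in 1:3) {
    m <- summarize_measures(
      compute_timecourses(vm, roi_mask(mask_dilate(tmask, d))))
    expect_lt(m$vmean_sys_peak, prev_sys)
    expect_lt(abs(m$vmean_dia_peak), abs(prev_dia))
    expect_identical(m$vmax_sys_peak, base$vmax_sys_peak)
    expect_identical(m$vmax_dia_peak, base$vmax_dia_peak)
    prev_sys <- m$vmean_sys_peak; prev_dia <- m$vmean_dia_peak
  }
  er <- summarize_measures(
    compute_timecourses(vm, roi_mask(mask_erode(tmask, 1))))
  expect_gt(er$vmean_sys_peak, base$vmean_sys_peak)
})
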