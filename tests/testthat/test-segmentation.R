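# Reference-frame selection and the three segmentation strategies.

test_that("reference frame maximizes windowed 99th-percentile |v|", {
  ph <- default_phantom_nf()
  vm <- default_vmaps_nf()
  win <- mask_dilate(ph$truth$true_mask, 2)
  expect_identical(select_reference_frame(vm, win),
                   which.max(ph$truth$centerline))

  # all-zero flow: tie-break to frame 1
  z <- velocity_maps(array(0, dim = c(4, 4, 3)), 20, 0.39, 1,
                     corrected = TRUE)
  expect_identical(select_reference_frame(z), 1L)

  # single nonzero frame wins
  z$v[2, 2, 3] <- 5
  expect_identical(select_reference_frame(z, matrix(TRUE, 4, 4)), 3L)
  expect_error(select_reference_frame(z, matrix(FALSE, 4, 4)), "empty")
})

test_that("border thresholding follows the clicked-border contract", {
  ph <- centered_phantom_nf()
  vm <- corrected_vmaps(ph)
  k <- which.max(ph$truth$centerline)
  av <- abs(vm$v[, , k])
  ctr <- which(av == max(av), arr.ind = TRUE)[1, ]

  # seed at the centerline pixel: tau = max -> single-pixel mask
  top <- segment_border_threshold(vm, seed_point(ctr, "BORDER", k))
  expect_identical(sum(top$mask$pixels), 1L)

  # seed near the half-max contour: mask close to the analytic half-max disc
  # (pi/2 R^2 for a parabolic profile), within one boundary-pixel ring
  half_target <- 0.5 * max(av)
  cand <- which(abs(av - half_target) == min(abs(av - half_target)),
                arr.ind = TRUE)[1, ]
  seg <- segment_border_threshold(vm, seed_point(cand, "BORDER", k))
  r_px <- 1.3 / 0.39
  a_half <- pi / 2 * r_px^2
  ring <- 2 * pi * r_px
  expect_lt(abs(sum(seg$mask$pixels) - a_half), ring)
  expect_true(aqueflow:::is_connected4(seg$mask$pixels))

  # far-parenchyma seed: threshold ~0 floods the image -> degenerate
  expect_error(segment_border_threshold(vm, seed_point(c(3, 3), "BORDER", k)),
               "degenerate")
})

test_that("region growing obeys alpha monotonicity and footprint limits", {
  ph <- centered_phantom_nf()
  vm <- corrected_vmaps(ph)
  k <- which.max(ph$truth$centerline)
  ctr <- which(abs(vm$v[, , k]) == max(abs(vm$v[, , k])), arr.ind = TRUE)[1, ]

  # alpha = 1: only the seed itself
  expect_identical(sum(segment_region_grow(vm, ctr, alpha = 1,
                                           ref_frame = k)$mask$pixels), 1L)

  # monotone non-increasing mask size in alpha
  sizes <- vapply(c(0.05, 0.2, 0.4, 0.6, 0.8),
                  function(a) sum(segment_region_grow(vm, ctr, alpha = a,
                                                      ref_frame = k)$mask$pixels),
                  0L)
  expect_true(all(diff(sizes) <= 0))

  # alpha = 0 grows to the full nonzero-velocity footprint (on a phantom
  # with no background offset field the only moving pixels are the lumen)
  ph0 <- render_cine(lumen_geometry(center = c(0.195, 0.195),
                                    semi_axes = c(1.3, 1.3)),
                     waveform_spec(),
                     acquisition_spec(snr = Inf,
                                      phase_offset_field = c(0, 0, 0)))
  vm0 <- phase_to_velocity(ph0$series)
  vm0$corrected <- TRUE                    # offset-free by construction
  k0 <- which.max(ph0$truth$centerline)
  ctr0 <- which(abs(vm0$v[, , k0]) == max(abs(vm0$v[, , k0])),
                arr.ind = TRUE)[1, ]
  full <- segment_region_grow(vm0, ctr0, alpha = 0, ref_frame = k0)
  foot <- ph0$truth$lumen_fraction_map > 0
  expect_identical(full$mask$pixels, foot)

  # analytic 20%-contour area within one boundary-pixel ring
  seg <- segment_region_grow(vm, ctr, alpha = 0.2, ref_frame = k)
  r_px <- 1.3 / 0.39
  a_20 <- 0.8 * pi * r_px^2
  expect_lt(abs(sum(seg$mask$pixels) - a_20), 2 * pi * r_px)

  # zero-velocity seed rejected
  vz <- vm; vz$v[1, 1, ] <- 0
  expect_error(segment_region_grow(vz, c(1, 1), ref_frame = k),
               "zero-velocity")
})

test_that("contour refinement sheds the rind and falls back gracefully", {
  ph <- centered_phantom_nf()
  vm <- corrected_vmaps(ph)
  k <- which.max(ph$truth$centerline)

  # from the true mask: near-perfect agreement with truth
  r1 <- refine_contour(vm, ph$truth$true_mask, ref_frame = k)
  expect_gte(dice(r1$mask, ph$truth$true_mask)$dsc, 0.9)

  # from a dilated true mask: sheds the low-velocity rind
  init2 <- mask_dilate(ph$truth$true_mask, 2)
  r2 <- refine_contour(vm, init2, ref_frame = k)
  expect_lt(sum(r2$mask$pixels), sum(init2))
  expect_gte(dice(r2$mask, ph$truth$true_mask)$dsc, 0.85)

  # uniform |v| in the region: Otsu degenerates, initial returned
  vu <- velocity_maps(array(1, dim = c(8, 8, 2)), 20, 0.39, 1,
                      corrected = TRUE)
  init <- matrix(FALSE, 8, 8); init[4:5, 4:5] <- TRUE
  expect_warning(ru <- refine_contour(vu, init, ref_frame = 1L),
                 "degenerate")
  expect_identical(ru$mask$pixels, init)

  # initial disjoint from moving pixels
  vz <- vm; vz$v[1:3, 1:3, ] <- 0
  bad <- matrix(FALSE, dim(vm$v)[1], dim(vm$v)[2]); bad[1:2, 1:2] <- TRUE
  expect_error(refine_contour(vz, bad, ref_frame = k), "disjoint")
})

test_that("mask propagation copies the ROI unchanged to every frame", {
  m <- matrix(FALSE, 5, 5); m[2:3, 2:3] <- TRUE
  for (T_ in c(2L, 32L)) {
    st <- propagate_mask(roi_mask(m), T_)
    expect_identical(dim(st), c(5L, 5L, T_))
    for (k in seq_len(T_)) expect_identical(st[, , k], m)
  }
  # manual adjustment callback applies per frame
  st <- propagate_mask(roi_mask(m), 2L,
                       adjust = function(px, k) if (k == 2) !px else px)
  expect_identical(st[, , 1], m)
  expect_identical(st[, , 2], !m)
})

test_that("all strategies segment the noise-free phantom with Dice >= 0.85", {
  ph <- default_phantom_nf()
  masks <- lapply(c("BORDER_THRESHOLD", "CONTOUR_REFINE", "REGION_GROW"),
                  function(s) quantify_series(ph$series, s)$segmentation$mask)
  for (m in masks) expect_gte(dice(m, ph$truth$true_mask)$dsc, 0.85)
})

test_that("Vmax peaks are identical across strategies and under seed jitter", {
  ph <- default_phantom_nf()
  jitters <- list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  vmax_all <- NULL; vmean_spread <- c()
  for (s in c("BORDER_THRESHOLD", "CONTOUR_REFINE", "REGION_GROW")) {
    ms <- lapply(jitters, function(j)
      quantify_series(ph$series, s, seed_jitter = j)$measures)
    vs <- vapply(ms, function(m) m$vmax_sys_peak, 0)
    vd <- vapply(ms, function(m) m$vmax_dia_peak, 0)
    expect_identical(max(vs) - min(vs), 0)   # jitter never moves Vmax peaks
    expect_identical(max(vd) - min(vd), 0)
    vmax_all <- rbind(vmax_all, c(vs[1], vd[1]))
    vmean_spread[s] <- diff(range(vapply(ms, function(m) m$vmean_avg, 0)))
  }
  # the maximal-|v| pixel sits at the lumen center: all strategies agree
  expect_identical(max(vmax_all[, 1]) - min(vmax_all[, 1]), 0)
  expect_identical(max(vmax_all[, 2]) - min(vmax_all[, 2]), 0)
  # while average Vmean does move for the border-click strategy
  expect_gt(vmean_spread["BORDER_THRESHOLD"], 0)
})
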