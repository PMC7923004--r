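#!/usr/bin/env Rscript
# Step 3 — intra-rater repeatability and the ROI-size mechanism.
#
# Ten synthetic subjects are processed twice per software strategy, the
# second pass with operator click positions jittered by one pixel (the
# re-processing-after-two-weeks protocol). ICC(A,1) is computed per measure
# and strategy. A second experiment dilates/erodes the true ROI on a
# noise-free phantom to expose why Vmean-derived measures lose
# repeatability while Vmax keeps it.

library(aqueflow)
dir.create("results", showWarnings = FALSE)

## repeat-processing ICC ----------------------------------------------------
tab <- simulate_cohort(cohort_spec(n_ms = 5L, n_nc = 5L, seed = 33L),
                       n_repeats = 2L)
icc_rows <- list()
for (sw in c("A", "B", "C")) for (m in c("csa_avg", "vmean_sys_peak",
                                         "vmean_dia_peak", "vmean_avg",
                                         "vmax_sys_peak", "vmax_dia_peak",
                                         "fr_avg", "caudal_volume",
                                         "cranial_volume", "net_volume")) {
  sub <- tab[tab$software == sw, ]
  x <- matrix(sub[[m]][order(sub$repeat_id, sub$subject_id)], ncol = 2)
  r <- tryCatch(icc_repeatability(x),
                error = function(e) list(icc = NA, p_value = NA,
                                         grade = "degenerate"))
  icc_rows[[length(icc_rows) + 1L]] <-
    data.frame(software = sw, measure = m, icc = r$icc, p = r$p_value,
               grade = r$grade)
}
icc_tab <- do.call(rbind, icc_rows)
write.csv(icc_tab, "results/03_icc.csv", row.names = FALSE)
cat("Repeat-processing ICC by software and measure:\n")
print(icc_tab, digits = 3)

cat("\nVmax peaks keep ICC = 1 under click jitter with every strategy;",
    "\nclick variability surfaces only in the ROI-size-sensitive measures",
    "\n(CSA and the Vmean-derived quantities) of the click-initialized",
    "\nstrategies.\n\n")

## ROI-size sensitivity -----------------------------------------------------
ph <- render_cine(lumen_geometry(), waveform_spec(),
                  acquisition_spec(snr = Inf))
vm <- background_correct(phase_to_velocity(ph$series),
                         propose_nfa(ph$truth$true_mask))
tmask <- ph$truth$true_mask
edits <- list(erode1 = roi_mask(mask_erode(tmask, 1)), true = tmask,
              dilate1 = roi_mask(mask_dilate(tmask, 1)),
              dilate2 = roi_mask(mask_dilate(tmask, 2)),
              dilate3 = roi_mask(mask_dilate(tmask, 3)))
sens <- do.call(rbind, lapply(names(edits), function(nm) {
  m <- summarize_measures(compute_timecourses(vm, edits[[nm]]))
  data.frame(roi = nm, csa = m$csa_avg, vmean_sys = m$vmean_sys_peak,
             vmean_dia = m$vmean_dia_peak, vmax_sys = m$vmax_sys_peak,
             vmax_dia = m$vmax_dia_peak)
}))
write.csv(sens, "results/03_roi_sensitivity.csv", row.names = FALSE)
cat("ROI-size sensitivity on the noise-free phantom:\n")
print(sens, digits = 3)
cat("\nGrowing the ROI dilutes Vmean monotonically; the Vmax peaks, taken",
    "\nat the lumen-center pixel of a laminar jet, do not move at all.\n")
cat("Tables written to results/03_icc.csv and",
    "results/03_roi_sensitivity.csv\n")
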