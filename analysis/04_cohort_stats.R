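#!/usr/bin/env Rscript
# Step 4 — synthetic-cohort reproducibility analysis.
#
# Simulates a 30 + 19 two-group cohort (MS-like subjects carry a larger
# cranial diastolic centerline amplitude), quantifies every subject with the
# three strategies, and runs the statistical battery: pooled GLM per measure
# (age + sex + software + group, treatment coding, references female / NC /
# software C), one-way RM-ANOVA across software with Bonferroni paired post
# hocs, and per-software group GLMs.

library(aqueflow)
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(seed = 101L)
tab <- simulate_cohort(spec)
write_measures(tab, "results/04_cohort_measures.csv")

d <- describe_cohort(tab)
cat(sprintf("Cohort: %d MS-like, %d control subjects | age t-test p = %.3f",
            spec$n_ms, spec$n_nc, d$age_ttest$p.value))
cat(sprintf(" | sex chi-square p = %.3f\n\n", d$sex_chisq$p.value))

measures <- c("csa_avg", "vmean_sys_peak", "vmean_dia_peak", "vmean_avg",
              "vmax_sys_peak", "vmax_dia_peak", "fr_sys_peak",
              "fr_dia_peak", "fr_avg", "caudal_volume", "cranial_volume",
              "net_volume")

## pooled GLMs (software + group, covarying age and sex) --------------------
glm_tab <- do.call(rbind, lapply(measures, function(m) {
  co <- fit_glm(tab, m)$coefficients
  cbind(data.frame(measure = m), co[co$term != "(Intercept)", ])
}))
write.csv(glm_tab, "results/04_glm_pooled.csv", row.names = FALSE)

## RM-ANOVA across software + Bonferroni post hocs --------------------------
rm_tab <- do.call(rbind, lapply(measures, function(m) {
  r <- rm_anova(tab, m)
  data.frame(measure = m, F = r$F, p = r$p,
             p_AB = r$posthoc$p_adj[1], p_AC = r$posthoc$p_adj[2],
             p_BC = r$posthoc$p_adj[3])
}))
write.csv(rm_tab, "results/04_rm_anova.csv", row.names = FALSE)

## per-software group comparisons -------------------------------------------
grp_tab <- do.call(rbind, lapply(measures, function(m) {
  do.call(rbind, lapply(c("A", "B", "C"), function(sw) {
    co <- fit_glm(tab[tab$software == sw, ], m,
                  terms = c("age", "sex", "group"))$coefficients
    g <- co[co$term == "groupMS", ]
    data.frame(measure = m, software = sw, B = g$B, p = g$p)
  }))
}))
write.csv(grp_tab, "results/04_group_per_software.csv", row.names = FALSE)

cat("Software effects (pooled GLM) on the diastolic Vmax peak:\n")
print(subset(glm_tab, measure == "vmax_dia_peak"), digits = 3)
cat("\nGroup effect per software (diastolic Vmax peak):\n")
print(subset(grp_tab, measure == "vmax_dia_peak"), digits = 3)
cat("\nRM-ANOVA across software:\n")
print(rm_tab, digits = 3)

sig <- subset(grp_tab, measure == "vmax_dia_peak")$p
cat("\nHeadline: the diastolic Vmax peak separates the groups with every\n")
cat(sprintf(
  "strategy (all group p <= %.4f) while no software term is significant\n",
  max(sig)))
cat("for that measure — ROI-size-insensitive Vmax carries the group\n")
cat("difference regardless of the segmentation style.\n")
cat("Tables written under results/04_*.csv\n")
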