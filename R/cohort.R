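# Synthetic-cohort reproducibility framework: per-subject phantoms quantified
# by all three segmentation strategies, then GLM / RM-ANOVA / post-hoc
# analyses of software and group effects.

SOFTWARE_LEVELS <- c(A = "BORDER_THRESHOLD", B = "CONTOUR_REFINE",
                     C = "REGION_GROW")

#' Synthetic cohort specification
#'
#' Defines the generative model for a two-group (MS-like vs control) cohort:
#' demographics, subject-level waveform/geometry parameters with
#' between-subject spread, group/age/sex effects on those parameters,
#' optional additive per-software measure biases, and operator click jitter
#' for repeat measurements. Defaults emulate a cohort of 30 people with
#' multiple sclerosis and 19 controls with age/sex distributions and measure
#' ranges typical of aqueductal CSF flow studies; the group effect is an
#' increase of the diastolic (cranial) centerline amplitude in the MS-like
#' group.
#'
#' @param n_ms,n_nc group sizes.
#' @param age_ms,age_nc \code{c(mean, sd)} of age, years.
#' @param p_female_ms,p_female_nc probability of female sex.
#' @param baseline named list of population-mean phantom parameters:
#'   \code{sys_amp}, \code{dia_amp} (centerline amplitudes, cm/s),
#'   \code{net_offset} (cm/s), \code{radius} (lumen radius, mm),
#'   \code{systolic_fraction}, \code{rr_interval} (s).
#' @param param_sd named list of between-subject SDs for \code{sys_amp},
#'   \code{dia_amp}, \code{net_offset}, \code{radius}, plus \code{center}
#'   (half-width, mm, of the uniform in-plane lumen position spread).
#' @param group_effects named list of MS-minus-control shifts of
#'   \code{sys_amp}, \code{dia_amp}, \code{radius}.
#' @param age_slopes per-year (age centered at 50) slopes of \code{sys_amp}
#'   and \code{dia_amp}.
#' @param sex_effects male-minus-female shifts of \code{sys_amp} and
#'   \code{dia_amp}.
#' @param software_bias named list (by software label A/B/C) of named
#'   additive offsets applied to specific measures, emulating systematic
#'   software differences; e.g. \code{list(A = c(csa_avg = 0.3))}.
#' @param snr phantom magnitude SNR.
#' @param matrix_size phantom image side, pixels.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_ms = 30L, n_nc = 19L,
                        age_ms = c(51.8, 8.8), age_nc = c(48.4, 12.5),
                        p_female_ms = 17 / 30, p_female_nc = 14 / 19,
                        baseline = list(sys_amp = 9.5, dia_amp = 6.2,
                                        net_offset = 0.4, radius = 1.0,
                                        systolic_fraction = 0.45,
                                        rr_interval = 0.9),
                        param_sd = list(sys_amp = 2.5, dia_amp = 1.8,
                                        net_offset = 0.25, radius = 0.12,
                                        center = 0.4),
                        group_effects = list(sys_amp = 1.0, dia_amp = 2.0,
                                             radius = 0.10),
                        age_slopes = list(sys_amp = -0.03, dia_amp = -0.02),
                        sex_effects = list(sys_amp = 0.8, dia_amp = 0.5),
                        software_bias = list(),
                        snr = 30, matrix_size = 64L, seed = 1L) {
  structure(list(n_ms = as.integer(n_ms), n_nc = as.integer(n_nc),
                 age_ms = age_ms, age_nc = age_nc,
                 p_female_ms = p_female_ms, p_female_nc = p_female_nc,
                 baseline = baseline, param_sd = param_sd,
                 group_effects = group_effects, age_slopes = age_slopes,
                 sex_effects = sex_effects, software_bias = software_bias,
                 snr = snr, matrix_size = as.integer(matrix_size),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a quantified synthetic cohort
#'
#' For every synthetic subject a phantom is rendered from subject-level
#' waveform and geometry parameters (group-, age- and sex-dependent) and
#' quantified with each segmentation strategy; repeats re-run the operator
#' interaction with jittered seed clicks on the same rendered series (the
#' repeat-processing protocol). Ground truth is retained.
#'
#' @param spec a [cohort_spec()].
#' @param strategies named character vector mapping software labels to
#'   strategy names (default \code{A} = border thresholding, \code{B} =
#'   contour refinement, \code{C} = region growing).
#' @param n_repeats processing repeats per subject and software.
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{age}, \code{sex}, \code{software}, \code{repeat_id} and the twelve
#'   measures; attribute \code{truth} holds per-subject [flow_measures()]
#'   ground truth, attribute \code{spec} the generating spec.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            strategies = SOFTWARE_LEVELS, n_repeats = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_ms + spec$n_nc
  group <- rep(c("MS", "NC"), c(spec$n_ms, spec$n_nc))
  b <- spec$baseline; sdv <- spec$param_sd
  ge <- spec$group_effects; as_ <- spec$age_slopes; se <- spec$sex_effects

  sub <- withr::with_seed(spec$seed, {
    age <- ifelse(group == "MS",
                  stats::rnorm(n, spec$age_ms[1], spec$age_ms[2]),
                  stats::rnorm(n, spec$age_nc[1], spec$age_nc[2]))
    sex <- ifelse(stats::runif(n) < ifelse(group == "MS", spec$p_female_ms,
                                           spec$p_female_nc), "F", "M")
    is_ms <- group == "MS"; is_m <- sex == "M"; dage <- age - 50
    sys_amp <- clamp(b$sys_amp + (sdv$sys_amp %||% 0) * stats::rnorm(n) +
                       is_ms * (ge$sys_amp %||% 0) +
                       dage * (as_$sys_amp %||% 0) +
                       is_m * (se$sys_amp %||% 0), 2, 18)
    dia_amp <- clamp(b$dia_amp + (sdv$dia_amp %||% 0) * stats::rnorm(n) +
                       is_ms * (ge$dia_amp %||% 0) +
                       dage * (as_$dia_amp %||% 0) +
                       is_m * (se$dia_amp %||% 0), 1, 18)
    net_offset <- b$net_offset + (sdv$net_offset %||% 0) * stats::rnorm(n)
    radius <- clamp(b$radius + (sdv$radius %||% 0) * stats::rnorm(n) +
                      is_ms * (ge$radius %||% 0), 0.8, 1.6)
    cw <- sdv$center %||% 0
    center_y <- cw * stats::runif(n, -1, 1)
    center_x <- cw * stats::runif(n, -1, 1)
    seeds <- sample.int(2^30, n)
    jitters <- lapply(seq_len(max(1L, n_repeats - 1L) * n), function(i)
      sample(c(-1L, 0L, 1L), 2L, replace = TRUE))
    list(age = age, sex = sex, sys_amp = sys_amp, dia_amp = dia_amp,
         net_offset = net_offset, radius = radius, center_y = center_y,
         center_x = center_x, seeds = seeds, jitters = jitters)
  })

  rows <- list(); truth_list <- vector("list", n)
  ji <- 0L
  for (i in seq_len(n)) {
    wf <- waveform_spec(systolic_amplitude = sub$sys_amp[i],
                        diastolic_amplitude = sub$dia_amp[i],
                        net_offset = sub$net_offset[i],
                        systolic_fraction = b$systolic_fraction,
                        rr_interval = b$rr_interval)
    geo <- lumen_geometry(center = c(sub$center_y[i], sub$center_x[i]),
                          semi_axes = rep(sub$radius[i], 2))
    acq <- acquisition_spec(snr = spec$snr, matrix_size = spec$matrix_size,
                            seed = sub$seeds[i])
    ph <- render_cine(geo, wf, acq)
    truth_list[[i]] <- ph$truth$true_measures
    vm <- background_correct(phase_to_velocity(ph$series),
                             propose_nfa(ph$truth$true_mask))
    window <- mask_dilate(ph$truth$true_mask, 2L)
    k <- select_reference_frame(vm, window)
    for (r in seq_len(n_repeats)) {
      jit <- if (r == 1L) c(0L, 0L) else {
        ji <- ji + 1L
        sub$jitters[[ji]]
      }
      for (sw in names(strategies)) {
        seg <- segment_strategy(vm, strategies[[sw]], ref_frame = k,
                                window = window, seed_jitter = jit)
        m <- summarize_measures(compute_timecourses(vm, propagate_mask(seg, vm)))
        vals <- unlist(unclass(m)[MEASURE_NAMES])
        bias <- spec$software_bias[[sw]]
        if (!is.null(bias)) vals[names(bias)] <- vals[names(bias)] + bias
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%03d", i), group = group[i],
          age = sub$age[i], sex = sub$sex[i], software = sw, repeat_id = r,
          as.list(vals))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth_list
  attr(out, "spec") <- spec
  out
}

#' Fit the pooled general linear model for one measure
#'
#' Ordinary least squares with treatment (reference-level) coding, the
#' standard reproducibility model: measure ~ age + sex + software + group.
#' Reports per-coefficient B, standard error, t, 95% confidence interval,
#' partial eta squared (t^2 / (t^2 + df_residual), the parameter-level form
#' of SS_term / (SS_term + SS_error)) and p. Default references: female sex,
#' software C (region growing), control group.
#'
#' @param table a cohort table (see [simulate_cohort()]).
#' @param response measure column name.
#' @param terms model terms among \code{age}, \code{sex}, \code{software},
#'   \code{group}.
#' @param ref named list of reference levels for the factor terms.
#' @return object of class \code{glm_result}: \code{coefficients}
#'   data.frame, underlying \code{fit}, response and references.
#' @export
fit_glm <- function(table, response, terms = c("age", "sex", "software",
                                               "group"),
                    ref = list(sex = "F", software = "C", group = "NC")) {
  stopifnot(response %in% names(table))
  df <- table
  if ("repeat_id" %in% names(df)) df <- df[df$repeat_id == 1L, ]
  df$y <- df[[response]]
  for (f in intersect(c("sex", "software", "group"), terms)) {
    if (length(unique(df[[f]])) < 2L)
      stop(sprintf("term '%s' is constant (aliased with the intercept)", f),
           call. = FALSE)
    df[[f]] <- stats::relevel(factor(df[[f]]), ref = ref[[f]])
  }
  fml <- stats::reformulate(terms, response = "y")
  fit <- stats::lm(fml, data = df)
  if (anyNA(coef(fit)))
    stop(sprintf("rank-deficient design; aliased: %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
         call. = FALSE)
  s <- summary(fit)
  cm <- s$coefficients
  dfres <- fit$df.residual
  ci <- stats::confint(fit, level = 0.95)
  out <- data.frame(term = rownames(cm), B = cm[, 1], std_error = cm[, 2],
                    t = cm[, 3], ci_lo = ci[, 1], ci_hi = ci[, 2],
                    partial_eta_sq = cm[, 3]^2 / (cm[, 3]^2 + dfres),
                    p = cm[, 4], row.names = NULL)
  structure(list(coefficients = out, fit = fit, response = response,
                 ref = ref, df_residual = dfres),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("GLM for %s (df residual = %d):\n", x$response, x$df_residual))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' All level pairs of a factor, compared by (by default paired) t-tests on
#' subject-matched values, with p-values multiplied by the number of pairs
#' and capped at 1. Pairs with exactly identical values yield p = 1.
#'
#' @param table cohort table.
#' @param response measure column name.
#' @param factor_name factor column (default software).
#' @param subject subject id column used for pairing.
#' @param paired use paired tests (within-subject comparison).
#' @return data.frame with one row per pair: mean difference, t, raw and
#'   Bonferroni-adjusted p.
#' @export
pairwise_posthoc <- function(table, response, factor_name = "software",
                             subject = "subject_id", paired = TRUE) {
  df <- table
  if ("repeat_id" %in% names(df)) df <- df[df$repeat_id == 1L, ]
  levs <- sort(unique(as.character(df[[factor_name]])))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  res <- lapply(pairs, function(pr) {
    a <- df[df[[factor_name]] == pr[1], ]
    b <- df[df[[factor_name]] == pr[2], ]
    if (paired) {
      b <- b[match(a[[subject]], b[[subject]]), ]
      d <- a[[response]] - b[[response]]
      if (all(abs(d - mean(d)) < 1e-15)) {
        tt <- list(statistic = if (abs(mean(d)) < 1e-15) 0 else Inf,
                   p.value = if (abs(mean(d)) < 1e-15) 1 else 0)
      } else tt <- stats::t.test(d)
    } else tt <- stats::t.test(a[[response]], b[[response]])
    data.frame(level1 = pr[1], level2 = pr[2],
               mean_diff = mean(a[[response]]) - mean(b[[response]]),
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_adj = min(1, m * tt$p.value))
  })
  do.call(rbind, res)
}

#' One-way repeated-measures ANOVA across software
#'
#' Tests whether the software factor shifts a measure within subjects
#' (complete balanced design; each subject measured once per software).
#' The subject effect is blocked out via \code{aov(y ~ software +
#' Error(subject))}; Bonferroni-corrected paired post-hoc comparisons are
#' attached.
#'
#' @param table cohort table.
#' @param response measure column name.
#' @param within within-subject factor column.
#' @param subject subject id column.
#' @return list: \code{F}, \code{df}, \code{p}, \code{posthoc} data.frame.
#' @export
rm_anova <- function(table, response, within = "software",
                     subject = "subject_id") {
  df <- table
  if ("repeat_id" %in% names(df)) df <- df[df$repeat_id == 1L, ]
  counts <- base::table(df[[subject]], df[[within]])
  if (any(counts != 1L))
    stop("incomplete within-subject design (missing cells)", call. = FALSE)
  df$y <- df[[response]]
  df$.subj <- factor(df[[subject]]); df$.win <- factor(df[[within]])
  fit <- stats::aov(y ~ .win + Error(.subj), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_eff <- tab[".win", "Sum Sq"]; df1 <- tab[".win", "Df"]
  ss_res <- tab["Residuals", "Sum Sq"]; df2 <- tab["Residuals", "Df"]
  ms_eff <- ss_eff / df1; ms_res <- ss_res / df2
  if (ms_res <= 1e-24) {
    if (ms_eff <= 1e-24) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
  } else {
    f <- ms_eff / ms_res
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, df = c(df1, df2), p = p,
       posthoc = pairwise_posthoc(df, response, factor_name = within,
                                  subject = subject, paired = TRUE))
}

#' Demographic comparison and normality screen of a cohort table
#'
#' Student's t-test for age, chi-squared for sex composition, and a
#' Kolmogorov-Smirnov normality diagnostic per measure (reported only; never
#' gates the pipeline).
#'
#' @param table cohort table.
#' @return list: \code{age_ttest}, \code{sex_chisq}, \code{normality}
#'   data.frame of per-measure KS statistics.
#' @export
describe_cohort <- function(table) {
  df <- table
  if ("repeat_id" %in% names(df)) df <- df[df$repeat_id == 1L, ]
  subj <- df[!duplicated(df$subject_id), c("subject_id", "group", "age",
                                           "sex")]
  age_t <- stats::t.test(age ~ group, data = subj)
  sex_x <- suppressWarnings(stats::chisq.test(base::table(subj$group,
                                                          subj$sex)))
  ks <- do.call(rbind, lapply(MEASURE_NAMES, function(m) {
    x <- df[[m]]
    k <- suppressWarnings(stats::ks.test((x - mean(x)) / stats::sd(x),
                                         "pnorm"))
    data.frame(measure = m, ks_stat = unname(k$statistic),
               ks_p = k$p.value)
  }))
  list(age_ttest = age_t, sex_chisq = sex_x, normality = ks)
}
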