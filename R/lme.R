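#' Random-intercept mixed model of AFD on strain
#'
#' Fits `mean_afd ~ group * oss_center + (1 | subject_id)` to a binned AFD
#' table, with the OSS bin center treated as a continuous predictor centered
#' at its grand mean (so the group main effect is the group difference at
#' mean strain). Estimation is REML via `lme4`, with Satterthwaite p-values
#' from `lmerTest` and Wald 95% confidence intervals.
#'
#' Because the response is a within-bin mean over `n_voxels` voxels, rows are
#' weighted by `n_voxels` by default, which makes the residual variance
#' structure of the model match the voxel-level generative process
#' (`weights = FALSE` gives the unweighted fit).
#'
#' Reported quantities follow the convention in which the interaction is the
#' control-minus-mTBI slope difference (positive when AFD rises more steeply
#' with strain in controls than in mTBI).
#'
#' @param table Binned AFD table: columns subject_id, group (control/mtbi),
#'   bin_center, mean_afd, n_voxels.
#' @param weight_by_voxels Weight rows by `n_voxels` (default TRUE).
#' @param reml Fit by REML (default) or ML.
#' @return Object of class `lme_result` with elements `slope_control`,
#'   `slope_mtbi`, `interaction` (each a list: estimate, conf.low, conf.high,
#'   p.value), `group_effect` (mTBI minus control at mean OSS), `intercept`,
#'   `random_intercept_sd`, `sigma`, `singular`, `n_subjects`, `n_obs`,
#'   `model` (the lmerMod fit).
#' @export
fit_lme <- function(table, weight_by_voxels = TRUE, reml = TRUE) {
  need <- c("subject_id", "group", "bin_center", "mean_afd")
  stopifnot(all(need %in% names(table)))
  d <- as.data.frame(table)
  d$group <- factor(d$group, levels = c("control", "mtbi"))
  if (any(is.na(d$group))) {
    stop("`group` must contain only 'control' and 'mtbi'.", call. = FALSE)
  }
  if (length(unique(d$bin_center)) < 3) {
    stop("Need at least 3 distinct strain bins to fit the model.",
         call. = FALSE)
  }
  counts <- table(unique(d[c("subject_id", "group")])$group)
  if (any(counts < 2)) {
    stop("Need at least 2 subjects per group.", call. = FALSE)
  }
  d$oss_c <- d$bin_center - mean(d$bin_center)
  w <- if (weight_by_voxels && "n_voxels" %in% names(d)) d$n_voxels else NULL
  # degenerate (noiseless) inputs trigger harmless convergence chatter
  fit <- suppressMessages(suppressWarnings(lmerTest::lmer(
    mean_afd ~ group * oss_c + (1 | subject_id),
    data = d, REML = reml, weights = w,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )))
  singular <- lme4::isSingular(fit)
  co <- summary(fit)$coefficients
  V <- as.matrix(stats::vcov(fit))
  est <- co[, "Estimate"]
  # linear combinations: control slope = oss_c; mtbi slope = oss_c + int;
  # reported interaction = control - mtbi slope = -int
  lin <- function(l, p.value = NA_real_) {
    e <- sum(l * est)
    se <- sqrt(drop(t(l) %*% V %*% l))
    list(estimate = e, conf.low = e - 1.96 * se, conf.high = e + 1.96 * se,
         se = se, p.value = p.value)
  }
  p_int <- co["groupmtbi:oss_c", "Pr(>|t|)"]
  p_oss <- co["oss_c", "Pr(>|t|)"]
  p_grp <- co["groupmtbi", "Pr(>|t|)"]
  structure(
    list(
      slope_control = lin(c(0, 0, 1, 0), p_oss),
      slope_mtbi = lin(c(0, 0, 1, 1)),
      interaction = lin(c(0, 0, 0, -1), p_int),
      group_effect = lin(c(0, 1, 0, 0), p_grp),
      intercept = lin(c(1, 0, 0, 0)),
      random_intercept_sd = sqrt(unname(
        lme4::VarCorr(fit)$subject_id["(Intercept)", "(Intercept)"])),
      sigma = stats::sigma(fit),
      singular = singular,
      method = if (reml) "REML" else "ML",
      weighted = !is.null(w),
      n_subjects = length(unique(d$subject_id)),
      n_obs = nrow(d),
      model = fit
    ),
    class = "lme_result"
  )
}

#' @export
print.lme_result <- function(x, ...) {
  cat("<lme_result> AFD ~ group * OSS + (1 | subject), ", x$method,
      if (x$singular) " [singular fit]", "\n", sep = "")
  cat(sprintf("  control slope     %.4f [%.4f, %.4f]\n",
              x$slope_control$estimate, x$slope_control$conf.low,
              x$slope_control$conf.high))
  cat(sprintf("  mTBI slope        %.4f [%.4f, %.4f]\n",
              x$slope_mtbi$estimate, x$slope_mtbi$conf.low,
              x$slope_mtbi$conf.high))
  cat(sprintf("  interaction (c-m) %.4f [%.4f, %.4f], p = %.3g\n",
              x$interaction$estimate, x$interaction$conf.low,
              x$interaction$conf.high, x$interaction$p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an AFD-strain mixed-model fit
#'
#' @param x An [fit_lme()] result.
#' @param ... Unused.
#' @return Tibble: term, estimate, conf.low, conf.high, p.value.
#' @export
tidy.lme_result <- function(x, ...) {
  terms <- c("intercept", "group_effect", "slope_control", "slope_mtbi",
             "interaction")
  purrr::list_rbind(purrr::map(terms, function(tm) {
    e <- x[[tm]]
    tibble::tibble(term = tm, estimate = e$estimate, std.error = e$se,
                   conf.low = e$conf.low, conf.high = e$conf.high,
                   p.value = e$p.value)
  }))
}

#' One-row summary of an AFD-strain mixed-model fit
#'
#' @param x An [fit_lme()] result.
#' @param ... Unused.
#' @return Tibble: nobs, n_subjects, sigma, random_intercept_sd, singular,
#'   method.
#' @export
glance.lme_result <- function(x, ...) {
  tibble::tibble(
    nobs = x$n_obs, n_subjects = x$n_subjects, sigma = x$sigma,
    random_intercept_sd = x$random_intercept_sd,
    singular = x$singular, method = x$method
  )
}

#' Mixed-design 2x2 ANOVA on region AFD
#'
#' Group (mTBI vs control, between subjects) by region (high vs low strain,
#' within subjects) analysis of variance on per-subject regional AFD means.
#' Sums of squares are the textbook mixed-design decomposition: the group
#' effect is tested against between-subject variation within groups, and the
#' region and region-by-group effects against the region-by-subject residual.
#'
#' @param summary A [roi_afd_summary()] tibble (columns group, afd_hs,
#'   afd_ls).
#' @return Tibble of class `anova_2x2`: effect, df1, df2, F, p.
#' @export
mixed_anova_2x2 <- function(summary) {
  stopifnot(all(c("group", "afd_hs", "afd_ls") %in% names(summary)))
  g <- factor(summary$group, levels = c("control", "mtbi"))
  if (any(table(g) < 2)) {
    stop("Need at least 2 subjects per group.", call. = FALSE)
  }
  hs <- summary$afd_hs; ls <- summary$afd_ls
  n_g <- as.vector(table(g))
  n <- length(hs)
  subj_mean <- (hs + ls) / 2
  grand <- mean(c(hs, ls))
  # between-subjects stratum (2 region observations per subject)
  group_means <- tapply(subj_mean, g, mean)
  ss_group <- 2 * sum(n_g * (group_means - grand)^2)
  ss_subj_within <- 2 * sum((subj_mean - group_means[g])^2)
  df_group <- 1
  df_subj <- n - 2
  # within-subjects stratum
  region_eff <- (hs - ls) / 2  # signed half-difference per subject
  reg_group_means <- tapply(region_eff, g, mean)
  reg_grand <- mean(region_eff)
  ss_region <- 2 * n * reg_grand^2
  ss_interaction <- 2 * sum(n_g * (reg_group_means - reg_grand)^2)
  ss_resid <- 2 * sum((region_eff - reg_group_means[g])^2)
  df_resid <- n - 2
  if (ss_subj_within <= 0 || ss_resid <= 0) {
    stop("Degenerate variance: ANOVA error terms are zero.", call. = FALSE)
  }
  ms <- function(ss, df) ss / df
  fstat <- c(
    group = ms(ss_group, df_group) / ms(ss_subj_within, df_subj),
    region = ms(ss_region, 1) / ms(ss_resid, df_resid),
    `group:region` = ms(ss_interaction, 1) / ms(ss_resid, df_resid)
  )
  df2 <- c(df_subj, df_resid, df_resid)
  out <- tibble::tibble(
    effect = names(fstat),
    df1 = c(df_group, 1, 1),
    df2 = df2,
    F = unname(fstat),
    p = stats::pf(unname(fstat), c(df_group, 1, 1), df2, lower.tail = FALSE)
  )
  class(out) <- c("anova_2x2", class(out))
  out
}
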