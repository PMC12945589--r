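test_that("bin edges anchor at width multiples with a closed top edge", {
  m <- tiny_map(array(c(0.10, 0.30, 0.49, 0.50), c(4, 1, 1)), kind = "oss_z")
  b <- build_bins(m, width = 0.25)
  expect_equal(b$scheme$lower[1], 0)
  # value 0.10 -> bin [0, 0.25), center 0.125
  expect_equal(b$scheme$center[b$assignment[1, 1, 1]], 0.125)
  # max value on the top edge goes into the last bin (closed top)
  expect_equal(b$assignment[4, 1, 1], b$assignment[3, 1, 1])
  # negative anchor
  m2 <- tiny_map(array(c(-0.9, 1.1), c(2, 1, 1)))
  b2 <- build_bins(m2, width = 0.25)
  expect_equal(b2$scheme$lower[1], -1)
  # range [-1, 4] with width 0.25 covers 20 bins
  m3 <- tiny_map(array(seq(-1, 4 - 1e-9, length.out = 100), c(100, 1, 1)))
  expect_equal(nrow(build_bins(m3, width = 0.25)$scheme), 20)
})

test_that("bin occupancy conserves the in-mask voxel count", {
  spec <- small_spec(seed = 31)
  z <- zscore_within_subject(
    scalar_map(spec$grid, spec$normative_oss_mean, spec$mask, "oss"))
  b <- build_bins(z)
  expect_equal(sum(b$scheme$n_voxels), sum(spec$mask))
  expect_true(all(diff(b$scheme$lower) - b$width < 1e-12))
})

test_that("subject bin means average correctly and honor the voxel floor", {
  vals <- array(0, c(20, 1, 1))
  z <- array(0, c(20, 1, 1))
  z[1:10] <- 0.1; z[11:13] <- 0.6; z[14:20] <- 1.1
  vals[1:10] <- c(0.4, 0.6)[rep(1:2, 5)]
  vals[11:13] <- 9
  vals[14:20] <- 0.7
  zm <- tiny_map(z, kind = "oss_z")
  bins <- build_bins(zm)
  afd <- tiny_map(vals, kind = "afd")
  rows <- subject_bin_means(afd, bins, list(subject_id = "s1",
                                            group = "control"),
                            min_voxels = 5)
  # the 3-voxel bin is dropped; remaining means are exact
  expect_equal(nrow(rows), 2)
  expect_equal(rows$mean_afd, c(0.5, 0.7))
  expect_equal(rows$n_voxels, c(10, 7))
  # uniform AFD: every surviving bin mean equals the constant
  uni <- subject_bin_means(tiny_map(array(0.3, c(20, 1, 1))), bins,
                           list(subject_id = "s1", group = "control"),
                           min_voxels = 1)
  expect_equal(uni$mean_afd, rep(0.3, nrow(uni)))
  expect_error(subject_bin_means(afd, bins,
                                 list(subject_id = "s", group = "control"),
                                 min_voxels = 50),
               "No bin")
})

test_that("delta-AFD curve equals hand-computed group differences", {
  tab <- tibble::tibble(
    subject_id = c("c1", "c2", "m1", "m2"),
    group = c("control", "control", "mtbi", "mtbi"),
    sex = "F",
    bin_center = 0.125,
    mean_afd = c(0.5, 0.6, 0.4, 0.5),
    n_voxels = 100
  )
  cv <- delta_afd_curve(tab)
  expect_equal(cv$delta, 0.1)
  # pooled-variance two-sample interval with df 2
  sp <- sqrt((stats::var(c(0.5, 0.6)) + stats::var(c(0.4, 0.5))) / 2)
  hw <- stats::qt(0.975, 2) * sp * sqrt(1 / 2 + 1 / 2)
  expect_equal(cv$conf.high - cv$delta, hw)
  # identical groups: zero difference, CI covers 0
  tab2 <- tab
  tab2$mean_afd <- c(0.5, 0.6, 0.5, 0.6)
  cv2 <- delta_afd_curve(tab2)
  expect_equal(cv2$delta, 0)
  expect_true(cv2$conf.low <= 0 && cv2$conf.high >= 0)
  # single-group bins are omitted with a warning
  tab3 <- dplyr::bind_rows(tab, tibble::tibble(
    subject_id = c("c1", "c2"), group = "control", sex = "F",
    bin_center = 0.375, mean_afd = c(1, 1.1), n_voxels = 50))
  expect_warning(cv3 <- delta_afd_curve(tab3), "omitted")
  expect_equal(nrow(cv3), 1)
})

test_that("the mixed model recovers exact generative lines", {
  # noiseless table built directly from the generative equation
  subjects <- sprintf("s%02d", 1:8)
  group <- rep(c("control", "mtbi"), each = 4)
  b <- c(0.03, -0.02, 0.01, 0.04, -0.01, 0.02, -0.03, 0.00)
  centers <- seq(-0.875, 3.625, by = 0.25)
  tab <- purrr::list_rbind(purrr::map(1:8, function(i) {
    tibble::tibble(
      subject_id = subjects[i], group = group[i], sex = "F",
      bin_center = centers,
      mean_afd = 0.5 + ifelse(group[i] == "control", 0.041, 0.029) * centers +
        b[i],
      n_voxels = 500
    )
  }))
  fit <- fit_lme(tab)
  expect_equal(fit$slope_control$estimate, 0.041, tolerance = 1e-8)
  expect_equal(fit$slope_mtbi$estimate, 0.029, tolerance = 1e-8)
  expect_equal(fit$interaction$estimate, 0.041 - 0.029, tolerance = 1e-8)
  # p-values on exactly noiseless data are dominated by degenerate df;
  # only require clear significance
  expect_lt(fit$interaction$p.value, 0.05)
  td <- tidy(fit)
  expect_setequal(td$term, c("intercept", "group_effect", "slope_control",
                             "slope_mtbi", "interaction"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_equal(glance(fit)$nobs, nrow(tab))
  expect_error(fit_lme(tab[tab$group == "control", ]), "2 subjects per group")
})

test_that("balanced fixed effects equal ordinary least squares", {
  set.seed(14)
  subjects <- sprintf("s%02d", 1:4)
  group <- rep(c("control", "mtbi"), each = 2)
  centers <- seq(0.125, 2.125, by = 0.25)
  tab <- purrr::list_rbind(purrr::map(1:4, function(i) {
    tibble::tibble(
      subject_id = subjects[i], group = group[i], sex = "M",
      bin_center = centers,
      mean_afd = 0.5 + 0.04 * centers + stats::rnorm(length(centers), 0, 0.01),
      n_voxels = 100
    )
  }))
  fit <- fit_lme(tab, weight_by_voxels = FALSE)
  d <- as.data.frame(tab)
  d$group <- factor(d$group, levels = c("control", "mtbi"))
  d$oss_c <- d$bin_center - mean(d$bin_center)
  ols <- stats::lm(mean_afd ~ group * oss_c, data = d)
  expect_equal(fit$slope_control$estimate, unname(stats::coef(ols)["oss_c"]),
               tolerance = 1e-6)
  expect_equal(fit$interaction$estimate,
               -unname(stats::coef(ols)["groupmtbi:oss_c"]), tolerance = 1e-6)
})

test_that("ROI AFD summaries and ratios behave under rescaling", {
  g <- voxel_grid(c(10, 1, 1))
  brain <- array(TRUE, c(10, 1, 1))
  roi <- strain_roi_mask(array(1:10 <= 4, c(10, 1, 1)), brain, g)
  mk <- function(hs_val, ls_val) {
    v <- array(ls_val, c(10, 1, 1)); v[1:4] <- hs_val
    tiny_map(v, kind = "afd")
  }
  maps <- list(a = mk(0.45, 0.50), b = mk(0.5, 0.5), c = mk(0.55, 0.50),
               d = mk(0.60, 0.50))
  meta <- tibble::tibble(subject_id = letters[1:4],
                         group = c("mtbi", "mtbi", "control", "control"),
                         sex = c("F", "M", "F", "M"))
  rs <- roi_afd_summary(maps, roi, meta)
  expect_equal(rs$ratio[1], 0.9)
  expect_equal(rs$ratio[2], 1)
  # global rescaling leaves ratios unchanged
  maps2 <- lapply(maps, function(m) tiny_map(m$values * 3.7, kind = "afd"))
  rs2 <- roi_afd_summary(maps2, roi, meta)
  expect_equal(rs2$ratio, rs$ratio, tolerance = 1e-12)
})

test_that("ratio test reproduces hand-computed Welch arithmetic", {
  rs <- tibble::tibble(
    subject_id = letters[1:4],
    group = c("control", "control", "mtbi", "mtbi"),
    sex = "F",
    afd_hs = 1, afd_ls = 1,
    ratio = c(1.00, 1.02, 0.90, 0.92)
  )
  rt <- ratio_ttest(rs)
  x <- c(1.00, 1.02); y <- c(0.90, 0.92)
  se <- sqrt(stats::var(x) / 2 + stats::var(y) / 2)
  expect_equal(rt$t, (mean(x) - mean(y)) / se, tolerance = 1e-12)
  expect_lt(rt$p, 0.05)
  # direction flip gives the complementary p
  rt2 <- ratio_ttest(rs, direction = "mtbi_higher")
  expect_equal(rt2$p, 1 - rt$p, tolerance = 1e-12)
  # identical groups: t = 0, p = 0.5
  rs3 <- rs; rs3$ratio <- c(1, 1.1, 1, 1.1)
  rt3 <- ratio_ttest(rs3)
  expect_equal(rt3$t, 0)
  expect_equal(rt3$p, 0.5)
})

test_that("mixed 2x2 ANOVA matches the textbook decomposition and aov", {
  # balanced 2-per-cell toy with hand-computable sums of squares
  rs <- tibble::tibble(
    subject_id = letters[1:4],
    group = c("control", "control", "mtbi", "mtbi"),
    sex = "F",
    afd_hs = c(0.52, 0.54, 0.40, 0.44),
    afd_ls = c(0.50, 0.52, 0.48, 0.50),
    ratio = 1
  )
  an <- mixed_anova_2x2(rs)
  # oracle: base aov with an Error(subject) stratum on long data
  long <- data.frame(
    y = c(rs$afd_hs, rs$afd_ls),
    region = rep(c("hs", "ls"), each = 4),
    group = rep(rs$group, 2),
    subject = rep(rs$subject_id, 2)
  )
  av <- summary(stats::aov(y ~ group * region + Error(subject / region),
                           data = long))
  f_group <- av[["Error: subject"]][[1]]["group", "F value"]
  f_within <- av[["Error: subject:region"]][[1]]
  expect_equal(an$F[an$effect == "group"], f_group, tolerance = 1e-10)
  expect_equal(an$F[an$effect == "region"], f_within["region", "F value"],
               tolerance = 1e-10)
  expect_equal(an$F[an$effect == "group:region"],
               f_within["group:region", "F value"], tolerance = 1e-10)
  # purely additive group and region shifts: interaction F vanishes
  rs2 <- rs
  reg_noise <- c(-0.001, 0.001, -0.001, 0.001)  # balanced across groups
  rs2$afd_hs <- c(0.50, 0.50, 0.45, 0.45)
  rs2$afd_ls <- rs2$afd_hs + 0.02 + reg_noise
  an2 <- mixed_anova_2x2(rs2)
  expect_lt(an2$F[an2$effect == "group:region"], 1e-20)
  expect_error(mixed_anova_2x2(rs[c(1, 3), ]), "2 subjects per group")
})

test_that("unbalanced groups agree with the aov oracle", {
  set.seed(5)
  n <- c(control = 7, mtbi = 4)
  rs <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:11),
    group = rep(names(n), n),
    sex = "M",
    afd_hs = stats::rnorm(11, 0.5, 0.03),
    afd_ls = stats::rnorm(11, 0.5, 0.03),
    ratio = 1
  )
  an <- mixed_anova_2x2(rs)
  long <- data.frame(
    y = c(rs$afd_hs, rs$afd_ls),
    region = rep(c("hs", "ls"), each = 11),
    group = rep(rs$group, 2),
    subject = rep(rs$subject_id, 2)
  )
  av <- summary(stats::aov(y ~ group * region + Error(subject / region),
                           data = long))
  f_within <- av[["Error: subject:region"]][[1]]
  expect_equal(an$F[an$effect == "group:region"],
               f_within["group:region", "F value"], tolerance = 1e-8)
})

test_that("stratified contrasts split, skip and match the pooled test", {
  rs <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:9),
    group = c(rep("control", 4), rep("mtbi", 5)),
    sex = c("F", "F", "F", "F", "F", "F", "F", "F", "M"),
    afd_hs = 1, afd_ls = 1,
    ratio = c(1.00, 1.01, 1.02, 1.03, 0.90, 0.91, 0.92, 0.93, 0.89)
  )
  expect_warning(st <- stratified_contrast(rs), "skipped")
  expect_equal(nrow(st), 1)
  expect_equal(st$stratum, "F")
  # single-sex data reproduces the unstratified test
  rsF <- rs[rs$sex == "F", ]
  pooled <- ratio_ttest(rsF)
  expect_equal(st$t, pooled$t)
  expect_equal(st$p, pooled$p)
})
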