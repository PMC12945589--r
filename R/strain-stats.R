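#' Discretize a normative strain map into z-score bins
#'
#' Bins the in-mask values of the normative OSS z map into uniform-width
#' intervals whose edges are anchored at integer multiples of the width
#' (edges `floor(min / width) * width`, upward until the maximum is covered).
#' Intervals are half-open `[edge, edge + width)` except the top edge, which
#' is closed so the maximum voxel is binned. Each in-mask voxel is assigned
#' exactly one bin; the assignment volume is the fixed spatial regressor for
#' all strain-stratified statistics.
#'
#' @param normative A [scalar_map()] (typically the normative OSS z map).
#' @param width Bin width in z units (default 0.25).
#' @return An object of class `bin_scheme`: `scheme` (tibble: bin, lower,
#'   upper, center, n_voxels), `assignment` (integer 3-D array, NA outside
#'   mask), `width`, `mask`.
#' @export
build_bins <- function(normative, width = 0.25) {
  stopifnot(inherits(normative, "scalar_map"), width > 0)
  v <- normative$values[normative$mask]
  if (length(v) == 0) stop("Empty mask: nothing to bin.", call. = FALSE)
  lo <- floor(min(v) / width) * width
  n_bins <- max(ceiling((max(v) - lo) / width), 1L)
  edges <- lo + width * (0:n_bins)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  assignment <- array(NA_integer_, dim = dim(normative$values))
  assignment[normative$mask] <- idx
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(
      scheme = tibble::tibble(
        bin = seq_len(n_bins),
        lower = edges[-length(edges)],
        upper = edges[-1],
        center = (edges[-length(edges)] + edges[-1]) / 2,
        n_voxels = counts
      ),
      assignment = assignment,
      width = width,
      mask = normative$mask
    ),
    class = "bin_scheme"
  )
}

#' @export
print.bin_scheme <- function(x, ...) {
  occ <- x$scheme$n_voxels > 0
  cat(sprintf("<bin_scheme> %d bins of width %g over [%g, %g], %d occupied\n",
              nrow(x$scheme), x$width, min(x$scheme$lower),
              max(x$scheme$upper), sum(occ)))
  invisible(x)
}

#' Per-subject mean AFD within each strain bin
#'
#' Averages one subject's AFD map within each bin of the normative strain
#' binning; bins with fewer than `min_voxels` in-mask voxels are dropped.
#' The subject (not the voxel) becomes the unit of analysis downstream.
#'
#' @param afd A [scalar_map()] of AFD values on the binning's grid/mask.
#' @param bins A [build_bins()] result.
#' @param meta Named list or one-row data frame with at least `subject_id`
#'   and `group`; `sex` and `phase` are carried through if present.
#' @param min_voxels Minimum voxels per reported bin (default 10).
#' @return Tibble rows: subject_id, group, sex, bin_center, mean_afd,
#'   n_voxels.
#' @export
subject_bin_means <- function(afd, bins, meta, min_voxels = 10) {
  stopifnot(inherits(afd, "scalar_map"), inherits(bins, "bin_scheme"))
  if (!identical(afd$mask, bins$mask)) {
    stop("AFD map and bin assignment must share one mask.", call. = FALSE)
  }
  meta <- as.list(meta)
  stopifnot(!is.null(meta$subject_id), !is.null(meta$group))
  idx <- bins$assignment[afd$mask]
  vals <- afd$values[afd$mask]
  sums <- rowsum(vals, idx)
  counts <- as.vector(table(factor(idx, levels = rownames(sums))))
  keep <- counts >= min_voxels
  if (!any(keep)) {
    stop("No bin has at least ", min_voxels, " voxels for subject ",
         meta$subject_id, ".", call. = FALSE)
  }
  bin_ids <- as.integer(rownames(sums))[keep]
  tibble::tibble(
    subject_id = meta$subject_id,
    group = meta$group,
    sex = if (is.null(meta$sex)) NA_character_ else meta$sex,
    bin_center = bins$scheme$center[bin_ids],
    mean_afd = as.vector(sums[keep, 1]) / counts[keep],
    n_voxels = counts[keep]
  )
}

#' Bin a whole simulated AFD cohort
#'
#' Convenience wrapper: builds the bin scheme from the cohort's normative
#' strain z map and stacks [subject_bin_means()] over all subjects.
#'
#' @param cohort An [simulate_afd_cohort()] result.
#' @param width Bin width in z units.
#' @param min_voxels Minimum voxels per reported bin.
#' @return A tibble of subject-by-bin mean AFD rows (the binned AFD table).
#' @export
bin_afd_cohort <- function(cohort, width = 0.25, min_voxels = 10) {
  stopifnot(inherits(cohort, "afd_cohort"))
  bins <- build_bins(cohort$oss_z, width = width)
  purrr::list_rbind(purrr::map(seq_len(nrow(cohort$cohort)), function(i) {
    subject_bin_means(cohort$afd[[i]], bins,
                      meta = cohort$cohort[i, ], min_voxels = min_voxels)
  }))
}

#' Group-difference AFD curve across strain bins
#'
#' Per bin: mean AFD difference (control minus mTBI) with the pooled-variance
#' two-sample 95% confidence interval across subjects. Bins observed in only
#' one group are omitted with a warning.
#'
#' @param table A binned AFD table ([subject_bin_means()] rows).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble of class `delta_afd_curve`: bin_center, delta (control -
#'   mTBI), conf.low, conf.high, n_control, n_mtbi.
#' @export
delta_afd_curve <- function(table, conf_level = 0.95) {
  stopifnot(all(c("group", "bin_center", "mean_afd") %in% names(table)))
  split_bins <- split(table, table$bin_center)
  rows <- lapply(split_bins, function(d) {
    x <- d$mean_afd[d$group == "control"]
    y <- d$mean_afd[d$group == "mtbi"]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    delta <- mean(x) - mean(y)
    df <- length(x) + length(y) - 2
    sp2 <- ((length(x) - 1) * stats::var(x) +
              (length(y) - 1) * stats::var(y)) / df
    se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    tq <- stats::qt(1 - (1 - conf_level) / 2, df)
    tibble::tibble(
      bin_center = d$bin_center[1], delta = delta,
      conf.low = delta - tq * se, conf.high = delta + tq * se,
      n_control = length(x), n_mtbi = length(y)
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " bin(s) omitted: fewer than 2 subjects in a group.",
            call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$bin_center), ]
  class(out) <- c("delta_afd_curve", class(out))
  out
}

#' Per-subject high-strain / low-strain AFD summary
#'
#' Averages each subject's AFD map inside the high-strain and low-strain
#' regions and forms the within-subject ratio `afd_hs / afd_ls`. Subjects
#' with non-positive LS mean are given `NA` ratio (excluded from ratio
#' analyses) with a message.
#'
#' @param afd_maps Named list of per-subject AFD [scalar_map()]s, or an
#'   `afd_cohort`.
#' @param roi A [strain_roi_mask()].
#' @param meta Data frame with `subject_id`, `group` and optionally `sex`
#'   (ignored when `afd_maps` is an `afd_cohort`, which carries its own).
#' @return Tibble of class `roi_summary`: subject_id, group, sex, afd_hs,
#'   afd_ls, ratio.
#' @export
roi_afd_summary <- function(afd_maps, roi, meta = NULL) {
  stopifnot(inherits(roi, "strain_roi_mask"))
  if (inherits(afd_maps, "afd_cohort")) {
    meta <- afd_maps$cohort
    afd_maps <- afd_maps$afd
  }
  stopifnot(is.list(afd_maps), !is.null(meta))
  if (!any(roi$hs) || !any(roi$ls)) {
    stop("High-strain and low-strain regions must both be non-empty.",
         call. = FALSE)
  }
  hs <- unname(vapply(afd_maps, function(m) mean(m$values[roi$hs]),
                      numeric(1)))
  ls <- unname(vapply(afd_maps, function(m) mean(m$values[roi$ls]),
                      numeric(1)))
  ratio <- ifelse(ls > 0, hs / ls, NA_real_)
  if (anyNA(ratio)) {
    message(sum(is.na(ratio)),
            " subject(s) with non-positive LS mean excluded from ratios.")
  }
  out <- tibble::tibble(
    subject_id = meta$subject_id,
    group = meta$group,
    sex = if ("sex" %in% names(meta)) meta$sex else NA_character_,
    afd_hs = hs, afd_ls = ls, ratio = ratio
  )
  class(out) <- c("roi_summary", class(out))
  out
}

#' Directed test on the high/low-strain AFD ratio
#'
#' Two-sample t-test (Welch by default) on the per-subject `afd_hs / afd_ls`
#' ratios, one-sided in the stated direction. `"mtbi_lower"` tests whether
#' mTBI ratios are lower than control ratios (t computed as control minus
#' mTBI, upper-tail p).
#'
#' @param summary A [roi_afd_summary()] tibble (or any tibble with `group`
#'   and `ratio`).
#' @param direction `"mtbi_lower"` (default) or `"mtbi_higher"`.
#' @param welch Use the Welch (unequal-variance) statistic (default TRUE).
#' @return A list of class `ratio_test`: `t`, `df`, `p` (one-sided),
#'   `mean_control`, `mean_mtbi`, `direction`, `n`.
#' @export
ratio_ttest <- function(summary, direction = c("mtbi_lower", "mtbi_higher"),
                        welch = TRUE) {
  direction <- match.arg(direction)
  d <- summary[!is.na(summary$ratio), ]
  x <- d$ratio[d$group == "control"]
  y <- d$ratio[d$group == "mtbi"]
  if (length(x) < 2 || length(y) < 2) {
    stop("Need at least 2 subjects with ratios per group.", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      # identical degenerate groups: no evidence either way
      return(structure(list(t = 0, df = length(x) + length(y) - 2, p = 0.5,
                            mean_control = mean(x), mean_mtbi = mean(y),
                            direction = direction,
                            n = c(control = length(x), mtbi = length(y))),
                       class = "ratio_test"))
    }
    stop("Degenerate ratio variance in both groups.", call. = FALSE)
  }
  alt <- if (direction == "mtbi_lower") "greater" else "less"
  ht <- stats::t.test(x, y, alternative = alt, var.equal = !welch)
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
         mean_control = mean(x), mean_mtbi = mean(y), direction = direction,
         n = c(control = length(x), mtbi = length(y))),
    class = "ratio_test"
  )
}

#' @export
print.ratio_test <- function(x, ...) {
  cat(sprintf(
    "<ratio_test> t = %.3f (df = %.1f), one-sided p = %.3g (%s)\n",
    x$t, x$df, x$p, x$direction))
  invisible(x)
}

#' Stratified ratio tests
#'
#' Repeats [ratio_ttest()] within each stratum of a grouping column
#' (default sex). Strata with fewer than 2 subjects per group are skipped
#' with a warning.
#'
#' @param summary A [roi_afd_summary()] tibble.
#' @param stratify_by Column name to stratify on.
#' @param ... Passed to [ratio_ttest()].
#' @return Tibble: stratum, n_control, n_mtbi, t, df, p.
#' @export
stratified_contrast <- function(summary, stratify_by = "sex", ...) {
  stopifnot(stratify_by %in% names(summary))
  strata <- split(summary, summary[[stratify_by]])
  rows <- lapply(names(strata), function(s) {
    d <- strata[[s]]
    nc <- sum(d$group == "control" & !is.na(d$ratio))
    nm <- sum(d$group == "mtbi" & !is.na(d$ratio))
    if (nc < 2 || nm < 2) {
      warning("Stratum '", s, "' skipped: fewer than 2 subjects per group.",
              call. = FALSE)
      return(NULL)
    }
    rt <- ratio_ttest(d, ...)
    tibble::tibble(stratum = s, n_control = nc, n_mtbi = nm,
                   t = rt$t, df = rt$df, p = rt$p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop("No stratum has at least 2 subjects per group.", call. = FALSE)
  }
  out
}
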