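#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired signed-rank test with Wilcoxon's original zero-handling: zero
#' differences are dropped and n reduced. The p-value is exact for n <= 25
#' (after zero-drop, ties permitting) and uses the normal approximation with
#' continuity correction above.
#'
#' @param x,y Numeric vectors of equal length (paired observations).
#' @return A list with `statistic` (signed-rank V), `p` (two-sided),
#'   `n` (pairs used after zero-drop), `method`.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("All paired differences are zero: signed-rank test undefined.",
         call. = FALSE)
  }
  exact <- n <= 25
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value, n = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Leave-one-out cross-validation of the high-strain mask
#'
#' For each subject in turn, rebuilds the voxelwise one-sample t statistics
#' and the joint FDR/t-thresholded high-strain mask from the remaining n - 1
#' subjects, then records the held-out subject's mean OSS z inside that
#' fold's HS and LS regions. Generalizable strain concentration shows up as
#' held-out HS means exceeding LS means across folds, tested with the
#' Wilcoxon matched-pairs signed-rank test.
#'
#' @param zmaps List of per-subject OSS z [scalar_map()]s (n >= 4).
#' @param q_thr,t_thr Thresholds passed to [define_hs_mask()].
#' @param subject_ids Optional character vector of ids (defaults to `s1..sn`).
#' @return An object of class `loo_result`: tibble `folds` (subject_id,
#'   hs_mean, ls_mean, hs_n_voxels), `wilcoxon` (statistic, p), and
#'   `n_excluded` folds whose HS mask was empty.
#' @export
loo_cross_validation <- function(zmaps, q_thr = 0.05, t_thr = 4,
                                 subject_ids = NULL) {
  n <- length(zmaps)
  if (n < 4) {
    stop("Leave-one-out cross-validation needs at least 4 subjects.",
         call. = FALSE)
  }
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  stopifnot(length(subject_ids) == n)
  rows <- vector("list", n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    stats_i <- voxelwise_one_sample_t(zmaps[-i])
    mask_i <- tryCatch(
      define_hs_mask(stats_i, zmaps[[i]]$mask, q_thr = q_thr, t_thr = t_thr),
      error = function(e) NULL
    )
    if (is.null(mask_i)) {
      excluded <- c(excluded, subject_ids[i])
      next
    }
    held <- zmaps[[i]]$values
    rows[[i]] <- tibble::tibble(
      subject_id = subject_ids[i],
      hs_mean = mean(held[mask_i$hs]),
      ls_mean = mean(held[mask_i$ls]),
      hs_n_voxels = sum(mask_i$hs)
    )
  }
  folds <- dplyr::bind_rows(rows)
  if (length(excluded)) {
    warning(length(excluded), " fold(s) excluded for empty HS mask: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  if (nrow(folds) < 2) {
    stop("Too few usable folds for the signed-rank test.", call. = FALSE)
  }
  wt <- wilcoxon_paired(folds$hs_mean, folds$ls_mean)
  structure(
    list(folds = folds, wilcoxon = wt, n_excluded = length(excluded),
         thresholds = c(q_thr = q_thr, t_thr = t_thr)),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(
    "<loo_result> %d folds (%d excluded); HS > LS in %d/%d; Wilcoxon V = %g, p = %.3g\n",
    nrow(x$folds), x$n_excluded, sum(x$folds$hs_mean > x$folds$ls_mean),
    nrow(x$folds), x$wilcoxon$statistic, x$wilcoxon$p))
  invisible(x)
}
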