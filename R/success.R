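# Cross-subject decoding of regulatory success: one contrast pattern per
# subject over an ROI, leave-one-subject-out nu-SVR prediction of the
# subject's success score, and permutation inference on the resulting
# prediction accuracy.

#' Subject-level contrast features over an ROI
#'
#' For each subject, combines the condition-mean trial patterns with
#' zero-sum contrast weights (e.g. `c(HC = 1, NC = -0.5, TC = -0.5)`),
#' voxel by voxel, over the ROI.
#'
#' @param patterns List over subjects of `pattern_dataset`s.
#' @param roi Integer columns of the pattern matrices to use.
#' @param contrast Named numeric contrast over conditions, summing to 0.
#' @return Subjects x ROI-voxels feature matrix.
#' @export
make_contrast_features <- function(patterns, roi, contrast) {
  if (abs(sum(contrast)) > 1e-12) stop("contrast weights must sum to 0")
  out <- t(vapply(patterns, function(p) {
    miss <- setdiff(names(contrast), unique(p$meta$condition))
    if (length(miss)) stop("condition(s) absent for a subject: ",
                           paste(miss, collapse = ", "))
    f <- numeric(length(roi))
    for (cc in names(contrast)) {
      rows <- p$meta$condition == cc
      f <- f + contrast[[cc]] * colMeans(p$X[rows, roi, drop = FALSE])
    }
    f
  }, numeric(length(roi))))
  out
}

#' Leave-one-subject-out prediction of regulatory success
#'
#' For each subject, a linear nu-SVR (cost 0.01) is trained on all other
#' subjects' ROI features and success scores and predicts the held-out
#' subject's score; accuracy is the Pearson correlation between predicted
#' and observed scores across subjects.  Features are standardized per
#' voxel using the training subjects only.
#'
#' @param X Subjects x voxels feature matrix.
#' @param y Per-subject success scores.
#' @param cost,nu SVR hyperparameters.
#' @param standardize Standardize features within each training fold?
#' @return List with `predicted` (per-subject LOSO predictions) and `r`
#'   (prediction accuracy).
#' @export
loso_predict_success <- function(X, y, cost = 0.01, nu = 0.5,
                                 standardize = TRUE) {
  n <- nrow(X)
  if (n < 8) stop("need at least 8 subjects")
  if (sd(y) == 0) stop("constant success scores")
  pred <- vapply(seq_len(n), function(s) {
    svr_decode_fold(X[-s, , drop = FALSE], y[-s], X[s, , drop = FALSE],
                    cost = cost, nu = nu, scale = standardize)
  }, numeric(1))
  list(predicted = pred, r = if (sd(pred) == 0) 0 else cor(pred, y))
}

#' Permutation test for cross-subject decoding accuracy
#'
#' Re-runs the full leave-one-subject-out decoding with the pairing of
#' subjects' patterns and scores permuted, building an empirical null for
#' the prediction accuracy.  The p-value uses the add-one counting rule;
#' accuracies above the null's 95th percentile are flagged significant.
#'
#' @param X,y As in [loso_predict_success()].
#' @param observed_r Observed accuracy; computed from `X`, `y` when `NULL`.
#' @param n_perm Number of permutations.
#' @param cutoff_prob Null quantile used as the significance cutoff.
#' @param ... Passed to [loso_predict_success()].
#' @return List with `p`, `cutoff` (null quantile), `significant`,
#'   `observed_r` and the `null` accuracies.
#' @export
permutation_pvalue <- function(X, y, observed_r = NULL, n_perm = 1000,
                               cutoff_prob = 0.95, ...) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse permutation p")
  if (is.null(observed_r)) observed_r <- loso_predict_success(X, y, ...)$r
  null <- vapply(seq_len(n_perm), function(i)
    loso_predict_success(X, sample(y), ...)$r, numeric(1))
  cutoff <- quantile(null, cutoff_prob, names = FALSE)
  list(p = (1 + sum(null >= observed_r)) / (n_perm + 1),
       cutoff = cutoff, significant = observed_r > cutoff,
       observed_r = observed_r, null = null)
}
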