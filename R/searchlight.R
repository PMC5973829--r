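# Searchlight SVR decoding.  For every in-mask voxel a sphere of
# neighbouring voxels provides the features of a linear nu-SVR that
# predicts trial-wise attribute values; accuracy is the run-wise
# cross-validated Fisher-z correlation between predicted and actual values,
# assigned to the sphere's center.

#' Fisher z transform of a correlation
#' @param r Correlation(s); clipped to `+/- clip` before `atanh` so maps
#'   stay finite.
#' @param clip Clipping bound.
#' @return `atanh` of the clipped correlation.
#' @export
fisher_z <- function(r, clip = 0.999) atanh(pmin(pmax(r, -clip), clip))

#' Build searchlight spheres over a mask
#'
#' One searchlight per in-mask voxel, containing all in-mask voxels within
#' a Euclidean radius of the center.  Spheres are truncated at the mask
#' boundary; centers with fewer than `min_voxels` members are dropped
#' (marked missing).
#'
#' @param mask 3-D logical array.
#' @param radius Sphere radius in voxels (>= 0; a radius-4 sphere has 257
#'   members in the volume interior).
#' @param min_voxels Minimum member count for a usable searchlight.
#' @return List with `members` (list over in-mask voxels: integer indices
#'   into the in-mask voxel set, or `NULL` when below `min_voxels`),
#'   `center` (linear volume index per searchlight) and `dim`.
#' @export
build_searchlights <- function(mask, radius = 4, min_voxels = 10) {
  if (radius < 0) stop("radius must be >= 0")
  dims <- dim(mask)
  if (!any(mask)) stop("empty mask")
  r <- floor(radius)
  off <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  off <- as.matrix(off[off$x^2 + off$y^2 + off$z^2 <= radius^2, , drop = FALSE])
  centers <- which(mask)
  col_of <- match(seq_len(prod(dims)), centers)  # volume index -> X column
  cz <- (centers - 1) %/% (dims[1] * dims[2])
  rem <- (centers - 1) %% (dims[1] * dims[2])
  cy <- rem %/% dims[1]
  cx <- rem %% dims[1]
  n <- length(centers)
  memb <- vector("list", n)
  acc_center <- integer(0); acc_member <- integer(0)
  for (m in seq_len(nrow(off))) {
    tx <- cx + off[m, 1]; ty <- cy + off[m, 2]; tz <- cz + off[m, 3]
    ok <- tx >= 0 & tx < dims[1] & ty >= 0 & ty < dims[2] &
      tz >= 0 & tz < dims[3]
    tv <- tx[ok] + dims[1] * (ty[ok] + dims[2] * tz[ok]) + 1L
    cc <- col_of[tv]
    keep <- !is.na(cc)
    acc_center <- c(acc_center, which(ok)[keep])
    acc_member <- c(acc_member, cc[keep])
  }
  sp <- split(acc_member, acc_center)
  memb[as.integer(names(sp))] <- lapply(sp, sort)
  short <- lengths(memb) < min_voxels
  memb[short] <- list(NULL)
  list(members = memb, center = centers, dim = dims)
}

#' Fit a linear nu-SVR on one training fold and predict the test fold
#'
#' A linear-kernel nu support vector regression with fixed cost
#' `c = 0.01` (and `nu = 0.5`), fit on the training patterns without
#' feature scaling.
#'
#' @param train_X,train_y Training patterns (trials x voxels) and labels.
#' @param test_X Test patterns.
#' @param cost,nu SVR hyperparameters.
#' @param scale Standardize features on the training set first?
#' @return Numeric predictions for the rows of `test_X`.
#' @export
svr_decode_fold <- function(train_X, train_y, test_X, cost = 0.01, nu = 0.5,
                            scale = FALSE) {
  if (length(unique(train_y)) < 2L)
    stop("constant training labels; SVR decoding is degenerate")
  if (scale) {
    mu <- colMeans(train_X)
    sg <- apply(train_X, 2, sd)
    sg[sg == 0] <- 1
    train_X <- sweep(sweep(train_X, 2, mu), 2, sg, "/")
    test_X <- sweep(sweep(test_X, 2, mu), 2, sg, "/")
  }
  fit <- e1071::svm(train_X, train_y, type = "nu-regression",
                    kernel = "linear", cost = cost, nu = nu, scale = FALSE)
  as.numeric(predict(fit, test_X))
}

#' Leave-one-run-out cross-validated decoding accuracy
#'
#' For each fold (run), trains the SVR on all other runs and correlates
#' predictions with the held-out run's labels; the accuracy is the mean
#' Fisher-z-transformed correlation across folds.  Folds with undefined
#' correlations (constant predictions or labels) score 0.
#'
#' @param X Trials x voxels pattern matrix.
#' @param y Trial labels.
#' @param fold_id Fold (run) label per trial.
#' @param cost,nu,scale Passed to [svr_decode_fold()].
#' @param clip Correlation clipping bound before the z transform.
#' @return Mean Fisher-z accuracy (chance level 0).
#' @export
crossval_accuracy <- function(X, y, fold_id, cost = 0.01, nu = 0.5,
                              scale = FALSE, clip = 0.999) {
  folds <- unique(fold_id)
  usable <- vapply(folds, function(f) sum(fold_id == f) >= 2, TRUE)
  if (sum(usable) < 2L) stop("fewer than 2 usable folds")
  z <- vapply(folds[usable], function(f) {
    te <- fold_id == f
    pred <- svr_decode_fold(X[!te, , drop = FALSE], y[!te],
                            X[te, , drop = FALSE], cost = cost, nu = nu,
                            scale = scale)
    if (sd(pred) == 0 || sd(y[te]) == 0) return(0)
    fisher_z(cor(pred, y[te]), clip)
  }, numeric(1))
  mean(z)
}

#' Whole-volume searchlight decoding of an attribute
#'
#' Runs [crossval_accuracy()] in every searchlight of one condition's
#' trials and writes the accuracy to the sphere's center voxel.
#'
#' @param data A `pattern_dataset` ([gen_patterns()]).
#' @param labels Attribute name (a column of `data$meta`) or a numeric
#'   vector with one label per selected trial.
#' @param condition Condition whose trials to decode.
#' @param radius Searchlight radius in voxels.
#' @param searchlights Optional precomputed [build_searchlights()] result
#'   (reused across attributes/conditions).
#' @param cost,nu,scale Passed to the SVR.
#' @return An `accuracy_map`: list with `values` (3-D array, `NA` outside
#'   the mask and at missing centers), `dim`, `voxel_mm`, `mask` and tags
#'   `attribute`/`condition`.
#' @export
run_searchlight <- function(data, labels, condition, radius = 4,
                            searchlights = NULL, cost = 0.01, nu = 0.5,
                            scale = FALSE) {
  sel <- data$meta$condition == condition
  if (!any(sel)) stop("condition not present: ", condition)
  lab_name <- NULL
  if (is.character(labels) && length(labels) == 1L) {
    lab_name <- labels
    labels <- data$meta[[labels]][sel]
  }
  X <- data$X[sel, , drop = FALSE]
  folds <- data$meta$run[sel]
  if (is.null(searchlights))
    searchlights <- build_searchlights(data$mask, radius)
  vals <- rep(NA_real_, length(searchlights$center))
  for (i in seq_along(searchlights$center)) {
    mb <- searchlights$members[[i]]
    if (is.null(mb)) next
    vals[i] <- crossval_accuracy(X[, mb, drop = FALSE], labels, folds,
                                 cost = cost, nu = nu, scale = scale)
  }
  arr <- array(NA_real_, data$dim)
  arr[searchlights$center] <- vals
  structure(list(values = arr, dim = data$dim, voxel_mm = data$voxel_mm,
                 mask = data$mask, attribute = lab_name,
                 condition = condition),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("accuracy map (%s%s): %d voxels, mean z = %.4f, max z = %.4f\n",
              if (is.null(x$attribute)) "" else paste0(x$attribute, ", "),
              if (is.null(x$condition)) "" else x$condition,
              length(v), mean(v), max(v)))
  invisible(x)
}

# separable Gaussian filter along one array axis (unnormalized weights)
axis_filter <- function(a, K, axis) {
  pa <- aperm(a, c(axis, setdiff(1:3, axis)))
  d <- dim(pa)
  m <- K %*% matrix(pa, d[1])
  out <- array(m, d)
  aperm(out, order(c(axis, setdiff(1:3, axis))))
}

#' Smooth an accuracy map within its mask
#'
#' Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 log 2))` mm, applied
#' only to in-mask, non-missing voxels with renormalization at mask edges
#' (so a constant map is unchanged).
#'
#' @param map An `accuracy_map`, or a 3-D array.
#' @param fwhm Full width at half maximum of the kernel, mm.
#' @param voxel_mm Voxel size (taken from the map when available).
#' @return Smoothed object of the same type.
#' @export
smooth_map <- function(map, fwhm = 6, voxel_mm = NULL) {
  is_map <- inherits(map, "accuracy_map")
  arr <- if (is_map) map$values else map
  if (fwhm <= 0) return(map)
  if (is.null(voxel_mm)) voxel_mm <- if (is_map) map$voxel_mm else 1
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(3 * sigma))
  d <- dim(arr)
  Ks <- lapply(d, function(n) {
    i <- seq_len(n)
    K <- exp(-outer(i, i, `-`)^2 / (2 * sigma^2))
    K[abs(outer(i, i, `-`)) > r] <- 0
    K
  })
  w <- !is.na(arr)
  a0 <- arr; a0[!w] <- 0
  num <- a0; den <- array(as.numeric(w), d)
  for (ax in 1:3) {
    num <- axis_filter(num, Ks[[ax]], ax)
    den <- axis_filter(den, Ks[[ax]], ax)
  }
  out <- num / den
  out[!w] <- NA_real_
  if (is_map) { map$values <- out; map } else out
}

#' Cross-condition and cross-attribute decoding matrix over an ROI
#'
#' Tests whether the neural code for one attribute in one condition
#' generalizes to another attribute/condition.  Cells pair
#' (attribute, condition) combinations: when the two cells use disjoint
#' trials (different conditions), the SVR is trained on all trials of one
#' cell and tested on all trials of the other, and vice versa (2-fold);
#' cells sharing trials (same condition, including the diagonal) use a
#' split-half approach on odd/even runs.  Each cell's accuracy is the mean
#' Fisher-z of its two directions.  Per-cell significance is assessed
#' against a label-permutation null (the full cell statistic recomputed
#' with trial labels permuted); values above the null's 95th percentile
#' are flagged.
#'
#' @param data A `pattern_dataset`.
#' @param roi Integer columns of `data$X` to use as features (an ROI).
#' @param attributes Attribute names (columns of `data$meta`).
#' @param conditions Conditions to cross (default: all in the metadata).
#' @param n_perm Label permutations per cell.
#' @param cutoff_prob Quantile of the null used as significance cutoff.
#' @param cost,nu Passed to the SVR.
#' @return List of class `cross_condition_matrix` with matrices `z`,
#'   `cutoff`, `significant` (cells as rows/columns, named
#'   `attribute.condition`).
#' @export
cross_condition_matrix <- function(data, roi, attributes,
                                   conditions = NULL, n_perm = 1000,
                                   cutoff_prob = 0.95, cost = 0.01,
                                   nu = 0.5) {
  if (is.null(conditions)) conditions <- unique(data$meta$condition)
  cells <- expand.grid(attribute = attributes, condition = conditions,
                       stringsAsFactors = FALSE)
  nm <- paste(cells$attribute, cells$condition, sep = ".")
  nc <- nrow(cells)
  Xr <- data$X[, roi, drop = FALSE]

  cell_data <- lapply(seq_len(nc), function(i) {
    sel <- which(data$meta$condition == cells$condition[i])
    list(rows = sel, y = data$meta[[cells$attribute[i]]][sel],
         run = data$meta$run[sel])
  })
  pair_z <- function(ci, cj, yi, yj) {
    shared <- length(intersect(ci$rows, cj$rows)) > 0
    if (shared && !identical(ci$rows, cj$rows))
      stop("cells with partially overlapping trials are not supported")
    dir_z <- function(tr_rows, tr_y, te_rows, te_y) {
      pred <- svr_decode_fold(Xr[tr_rows, , drop = FALSE], tr_y,
                              Xr[te_rows, , drop = FALSE],
                              cost = cost, nu = nu)
      if (sd(pred) == 0 || sd(te_y) == 0) return(0)
      fisher_z(cor(pred, te_y))
    }
    if (!shared) {
      (dir_z(ci$rows, yi, cj$rows, yj) +
         dir_z(cj$rows, yj, ci$rows, yi)) / 2
    } else {
      h1 <- ci$run %% 2 == 1
      (dir_z(ci$rows[h1], yi[h1], cj$rows[!h1], yj[!h1]) +
         dir_z(ci$rows[!h1], yi[!h1], cj$rows[h1], yj[h1])) / 2
    }
  }

  z <- cut_m <- matrix(NA_real_, nc, nc, dimnames = list(nm, nm))
  sig <- matrix(NA, nc, nc, dimnames = list(nm, nm))
  for (i in seq_len(nc)) for (j in i:nc) {
    ci <- cell_data[[i]]; cj <- cell_data[[j]]
    obs <- pair_z(ci, cj, ci$y, cj$y)
    null <- vapply(seq_len(n_perm), function(p)
      pair_z(ci, cj, sample(ci$y), sample(cj$y)), numeric(1))
    cut <- quantile(null, cutoff_prob, names = FALSE)
    z[i, j] <- z[j, i] <- obs
    cut_m[i, j] <- cut_m[j, i] <- cut
    sig[i, j] <- sig[j, i] <- obs > cut
  }
  structure(list(z = z, cutoff = cut_m, significant = sig, cells = cells,
                 n_perm = n_perm),
            class = "cross_condition_matrix")
}

#' @export
print.cross_condition_matrix <- function(x, ...) {
  cat("Cross-condition decoding matrix (Fisher z; * above the",
      "permutation cutoff)\n")
  m <- matrix(sprintf("%6.3f%s", x$z, ifelse(x$significant, "*", " ")),
              nrow(x$z), dimnames = dimnames(x$z))
  print(m, quote = FALSE)
  invisible(x)
}
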