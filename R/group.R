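# Group-level inference over subjects' accuracy maps: one-sample t maps
# against chance, within-subject condition ANOVAs and directed contrasts,
# permutation-based cluster-level family-wise error correction, and
# minimum-statistic conjunctions.

# stack a list of accuracy maps (or arrays) into voxels x maps matrix
stack_maps <- function(maps) {
  arrs <- lapply(maps, function(m) if (inherits(m, "accuracy_map")) m$values else m)
  d <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d)) stop("map geometry mismatch")
  list(mat = vapply(arrs, as.vector, numeric(prod(d))), dim = d)
}

new_stat_map <- function(stat, p, df, type, dim, subject_values = NULL,
                         subject_cond_values = NULL, tail = "two") {
  structure(list(stat = array(stat, dim), p = array(p, dim), df = df,
                 type = type, dim = dim, subject_values = subject_values,
                 subject_cond_values = subject_cond_values, tail = tail),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  ok <- !is.na(x$stat)
  cat(sprintf("%s map (df = %s): %d voxels, max %s = %.3f, min p = %.2g\n",
              x$type, paste(round(x$df, 1), collapse = ", "), sum(ok),
              x$type, max(x$stat[ok]), min(x$p[ok])))
  invisible(x)
}

#' Group main-effect map: decoding accuracy against chance
#'
#' Averages each subject's condition-specific accuracy maps and tests the
#' average against chance (0 for Fisher-z accuracies) with a voxelwise
#' one-sample t-test.
#'
#' @param subject_maps List over subjects; each element either a single
#'   `accuracy_map` (already condition-averaged) or a list of condition
#'   maps to be averaged.
#' @return A `stat_map` with the voxelwise t statistic and one-tailed p
#'   (accuracy above chance).
#' @export
main_effect_map <- function(subject_maps) {
  if (length(subject_maps) < 3) stop("need at least 3 subjects")
  avg <- lapply(subject_maps, function(s) {
    if (inherits(s, "accuracy_map") || is.array(s)) return(s)
    st <- stack_maps(s)
    array(rowMeans(st$mat), st$dim)
  })
  st <- stack_maps(avg)
  n <- ncol(st$mat)
  mu <- rowMeans(st$mat)
  se <- apply(st$mat, 1, sd) / sqrt(n)
  tv <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, NA))
  p <- pt(tv, n - 1, lower.tail = FALSE)
  new_stat_map(tv, p, n - 1, "t", st$dim, subject_values = st$mat,
               tail = "one")
}

#' Condition effects on decoding accuracy: RM-ANOVA and directed contrasts
#'
#' With `contrast = NULL`, computes the voxelwise one-way within-subject
#' ANOVA omnibus F across conditions (the voxelwise analogue of
#' [rm_anova()]).  With a named, zero-sum contrast (e.g.
#' `c(HC = 1, NC = -0.5, TC = -0.5)`), computes the per-subject contrast
#' combination and its voxelwise one-sample t, one-tailed in the stated
#' direction.
#'
#' @param subject_cond_maps List over subjects of named lists of
#'   `accuracy_map`s per condition (complete grid).
#' @param contrast Optional named numeric contrast over conditions.
#' @return A `stat_map` (type `"F"` or `"t"`).
#' @export
condition_anova_map <- function(subject_cond_maps, contrast = NULL) {
  conds <- names(subject_cond_maps[[1]])
  n <- length(subject_cond_maps)
  k <- length(conds)
  mats <- lapply(subject_cond_maps, function(s) {
    if (!identical(sort(names(s)), sort(conds))) stop("incomplete condition grid")
    stack_maps(s[conds])$mat
  })
  d <- if (inherits(subject_cond_maps[[1]][[1]], "accuracy_map"))
    subject_cond_maps[[1]][[1]]$dim else dim(subject_cond_maps[[1]][[1]])
  # voxels x subjects x conditions
  arr <- array(unlist(mats), c(prod(d), k, n))
  arr <- aperm(arr, c(1, 3, 2))
  if (!is.null(contrast)) {
    if (abs(sum(contrast)) > 1e-12) stop("contrast weights must sum to 0")
    cvals <- matrix(0, prod(d), n)
    for (j in seq_along(contrast))
      cvals <- cvals + contrast[j] * arr[, , match(names(contrast)[j], conds)]
    mu <- rowMeans(cvals)
    se <- apply(cvals, 1, sd) / sqrt(n)
    tv <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, NA))
    p <- pt(tv, n - 1, lower.tail = FALSE)
    return(new_stat_map(tv, p, n - 1, "t", d, subject_values = cvals,
                        tail = "one"))
  }
  grand <- rowMeans(arr, dims = 1)
  cond_m <- apply(arr, c(1, 3), mean)
  subj_m <- apply(arr, c(1, 2), mean)
  ss_cond <- n * rowSums((cond_m - grand)^2)
  ss_subj <- k * rowSums((subj_m - grand)^2)
  ss_tot <- apply((arr - array(grand, dim(arr)))^2, 1, sum)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_err <- (ss_tot - ss_cond - ss_subj) / df2
  Fv <- ifelse(ms_err > 0, (ss_cond / df1) / ms_err, ifelse(ss_cond == 0, 0, Inf))
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  new_stat_map(Fv, p, c(df1, df2), "F", d, subject_cond_values = arr)
}

# cluster sizes and peaks of a supra-threshold logical array
cluster_table <- function(above, stat, dims) {
  lab <- cpp_label_components(above, dims, 26L)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ids)) return(data.frame())
  do.call(rbind, lapply(ids, function(i) {
    vox <- which(lab == i)
    pk <- vox[which.max(stat[vox])]
    co <- arrayInd(pk, dims)
    data.frame(cluster = i, size = length(vox), peak_stat = max(stat[vox]),
               peak_x = co[1], peak_y = co[2], peak_z = co[3])
  }))
}

#' Cluster-level family-wise error correction by permutation
#'
#' Thresholds the statistic map at voxelwise `p < height_p`, finds
#' 26-connected supra-threshold clusters, and compares each cluster's size
#' with the permutation distribution of the maximum cluster size under the
#' null: sign-flipping of per-subject values for t maps, within-subject
#' condition-label permutation for F maps.  Clusters with permutation
#' `p < alpha` survive.
#'
#' @param stat A `stat_map` from [main_effect_map()] or
#'   [condition_anova_map()] (carrying its subject-level values).
#' @param height_p Voxelwise height threshold.
#' @param alpha Cluster-level family-wise alpha.
#' @param n_perm Number of permutations.
#' @return A `cluster_result`: list with `clusters` (size, peak, cluster-p
#'   per cluster), `mask` (logical array of surviving voxels),
#'   `height_threshold`, `method`.
#' @export
cluster_correct <- function(stat, height_p = 0.001, alpha = 0.05,
                            n_perm = 1000) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse cluster-level p")
  dims <- stat$dim
  if (stat$type == "t") {
    sv <- stat$subject_values
    if (is.null(sv)) stop("stat map lacks subject-level values")
    n <- ncol(sv)
    thr <- qt(1 - height_p, stat$df)
    tmap <- function(m) {
      mu <- rowMeans(m)
      se <- sqrt((rowMeans(m^2) - mu^2) * n / (n - 1)) / sqrt(n)
      ifelse(se > 0, mu / se, 0)
    }
    observed <- tmap(sv)
    null_max <- vapply(seq_len(n_perm), function(i) {
      flip <- sample(c(-1, 1), n, replace = TRUE)
      tm <- tmap(sweep(sv, 2, flip, `*`))
      ab <- !is.na(tm) & tm > thr
      if (!any(ab)) return(0L)
      lab <- cpp_label_components(array(ab, dims), dims, 26L)
      max(tabulate(lab[lab > 0L]))
    }, integer(1))
    method <- "sign-flip permutation of subject values"
  } else {
    arr <- stat$subject_cond_values
    if (is.null(arr)) stop("stat map lacks subject x condition values")
    n <- dim(arr)[2]; k <- dim(arr)[3]
    thr <- qf(1 - height_p, stat$df[1], stat$df[2])
    fmap <- function(a) {
      grand <- rowMeans(a, dims = 1)
      cond_m <- apply(a, c(1, 3), mean)
      subj_m <- apply(a, c(1, 2), mean)
      ss_cond <- n * rowSums((cond_m - grand)^2)
      ss_subj <- k * rowSums((subj_m - grand)^2)
      ss_tot <- apply((a - array(grand, dim(a)))^2, 1, sum)
      ms_err <- (ss_tot - ss_cond - ss_subj) / ((k - 1) * (n - 1))
      ifelse(ms_err > 0, (ss_cond / (k - 1)) / ms_err, 0)
    }
    observed <- fmap(arr)
    null_max <- vapply(seq_len(n_perm), function(i) {
      perm <- arr
      for (s in seq_len(n)) perm[, s, ] <- perm[, s, sample(k)]
      fm <- fmap(perm)
      ab <- !is.na(fm) & fm > thr
      if (!any(ab)) return(0L)
      lab <- cpp_label_components(array(ab, dims), dims, 26L)
      max(tabulate(lab[lab > 0L]))
    }, integer(1))
    method <- "within-subject condition-label permutation"
  }
  above <- !is.na(observed) & observed > thr
  tab <- cluster_table(array(above, dims), array(observed, dims), dims)
  keep_mask <- array(FALSE, dims)
  if (nrow(tab)) {
    tab$cluster_p <- vapply(tab$size, function(s)
      (1 + sum(null_max >= s)) / (n_perm + 1), numeric(1))
    tab$significant <- tab$cluster_p < alpha
    lab <- cpp_label_components(array(above, dims), dims, 26L)
    for (i in which(tab$significant)) keep_mask[lab == tab$cluster[i]] <- TRUE
  }
  structure(list(clusters = tab, mask = keep_mask, height_threshold = thr,
                 height_p = height_p, alpha = alpha, n_perm = n_perm,
                 method = method),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster correction (%s; height p < %g, alpha = %g, %d perms)\n",
              x$method, x$height_p, x$alpha, x$n_perm))
  if (!nrow(x$clusters)) cat("no supra-threshold clusters\n") else
    print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Conjunction of thresholded significance masks
#'
#' Voxelwise intersection of independently corrected significance masks
#' (minimum-statistic conjunction logic).
#'
#' @param masks List of logical arrays (or `cluster_result`s) of identical
#'   geometry.
#' @return Logical array: voxels significant in every input.
#' @export
conjunction <- function(masks) {
  if (!length(masks)) stop("empty mask list")
  masks <- lapply(masks, function(m) if (inherits(m, "cluster_result")) m$mask else m)
  out <- masks[[1]]
  for (m in masks[-1]) {
    if (!identical(dim(m), dim(out))) stop("mask geometry mismatch")
    out <- out & m
  }
  out
}
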