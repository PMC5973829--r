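# Synthetic study generator.  Emulates the two-task regulation study the
# analysis stack expects: 5-point food ratings recoded to -2..+2 around a
# neutral default, $0-40 trade-off proposals around a ($20, $20) default,
# three regulatory conditions of 90 trials in 9 runs of 10, condition-wise
# cohort-mean attribute weights, and trial-wise voxel patterns that encode
# attribute values linearly with condition-dependent gain.

#' Cohort-mean attribute weights per regulatory condition
#'
#' The generator's default drift weights: group means (and between-subject
#' SDs) of the fitted attribute weights under each regulatory goal, on the
#' per-step drift scale.  These are the magnitudes the synthetic cohort
#' emulates; conditions are NC/HC/TC (natural, focus-on-health,
#' focus-on-taste) for the food task and NC/PC/EC (natural,
#' focus-on-partner, focus-on-ethics) for the altruism task.
#'
#' @param task `"food"` or `"altruism"`.
#' @return Data frame with columns `condition`, `attribute`, `mean`, `sd`.
#' @export
#' @examples
#' cohort_weights("food")
cohort_weights <- function(task = c("food", "altruism")) {
  task <- match.arg(task)
  if (task == "food") {
    data.frame(
      condition = rep(c("NC", "HC", "TC"), each = 2),
      attribute = rep(c("taste", "health"), 3),
      mean = c(0.0163, -0.0003, 0.0044, 0.0121, 0.0167, -0.0019),
      sd   = c(0.0054,  0.0040, 0.0064, 0.0074, 0.0051,  0.0037))
  } else {
    data.frame(
      condition = rep(c("NC", "PC", "EC"), each = 3),
      attribute = rep(c("self", "other", "fairness"), 3),
      mean = c(0.0082, 0.0010, 0.0018,
               0.0037, 0.0059, 0.0029,
               0.0070, 0.0047, 0.0062),
      sd   = c(0.0038, 0.0039, 0.0034,
               0.0057, 0.0040, 0.0035,
               0.0050, 0.0049, 0.0056))
  }
}

#' Condition labels of a task
#' @param task `"food"` or `"altruism"`.
#' @return Character vector of the three condition labels.
#' @export
task_conditions <- function(task = c("food", "altruism")) {
  if (match.arg(task) == "food") c("NC", "HC", "TC") else c("NC", "PC", "EC")
}

#' DDM parameters at the cohort means (or sampled around them)
#'
#' @param task `"food"` or `"altruism"`.
#' @param condition One of the task's conditions.
#' @param heterogeneous If `TRUE`, draw the weights from a normal
#'   distribution with the cohort means and SDs (one subject's parameters);
#'   if `FALSE`, use the means exactly.
#' @param ... Passed on to [ddm_params()] (e.g. `ndt`, `bound0`, `decay`).
#' @return A [ddm_params()] object.
#' @export
cohort_params <- function(task, condition, heterogeneous = FALSE, ...) {
  cw <- cohort_weights(task)
  cw <- cw[cw$condition == condition, ]
  if (!nrow(cw)) stop("unknown condition: ", condition)
  w <- setNames(cw$mean, cw$attribute)
  if (heterogeneous) w <- setNames(rnorm(nrow(cw), cw$mean, cw$sd), cw$attribute)
  ddm_params(w[task_attributes(task)], ...)
}

#' Generate a stimulus set
#'
#' Food: 90 items covering the 5 x 5 grid of (taste, health) ratings,
#' recoded to -2..+2 around the neutral default, in a roughly uniform
#' manner (three full grids plus 15 cells sampled without replacement).
#' Altruism: proposals with integer payoffs in $0-40 that always trade off
#' self against other around the ($20, $20) default -- one party's payoff
#' exceeds its default share while the other's is at most the default, so
#' no proposal weakly dominates (or is dominated by) the default.
#'
#' @param task `"food"` or `"altruism"`.
#' @param n_items Number of stimuli.
#' @return Data frame of stimuli with the task's attribute columns (and
#'   `fairness` for the altruism task); attribute `"task"` records the task.
#' @export
gen_stimuli <- function(task = c("food", "altruism"), n_items = 90) {
  task <- match.arg(task)
  if (task == "food") {
    grid <- expand.grid(taste = -2:2, health = -2:2)
    full <- n_items %/% nrow(grid)
    extra <- n_items - full * nrow(grid)
    idx <- c(rep(seq_len(nrow(grid)), full),
             sample(nrow(grid), extra))
    out <- grid[sample(idx), , drop = FALSE]
  } else {
    n_gen <- n_items %/% 2
    gen <- data.frame(self = sample(0:20, n_gen, replace = TRUE),
                      other = sample(21:40, n_gen, replace = TRUE))
    slf <- data.frame(self = sample(21:40, n_items - n_gen, replace = TRUE),
                      other = sample(0:20, n_items - n_gen, replace = TRUE))
    out <- rbind(gen, slf)[sample(n_items), , drop = FALSE]
    out$fairness <- fairness(out$self, out$other)
  }
  rownames(out) <- NULL
  attr(out, "task") <- task
  out
}

#' Select altruism proposals from natural-condition choices
#'
#' Fits the two-weight logistic choice rule
#' `P(accept) = logit^-1(w_self * self + w_other * other)` to
#' natural-condition choices, then assembles a stimulus set from the
#' candidates: the 30% most likely to elicit a generous response, the 30%
#' most likely to elicit a selfish response, and the remaining 40% drawn
#' uniformly from the full candidate space (the two 30% groups are floored;
#' the remainder goes to the random group).  A generous response accepts a
#' generous proposal or rejects a selfish one.
#'
#' @param nc_choices Natural-condition choice data (columns `self`, `other`,
#'   `choice`).
#' @param candidates Candidate proposal data frame (e.g. [gen_stimuli()]
#'   with a large `n_items`).
#' @param n Number of proposals to select.
#' @return Data frame of `n` proposals with a `selection` column
#'   (`"generous_likely"`, `"selfish_likely"`, `"random"`), plus the fitted
#'   logistic weights as attribute `"logistic_weights"`.
#' @export
select_altruism_trials <- function(nc_choices, candidates, n = 90) {
  resp <- nc_choices[nc_choices$choice != "missed", , drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(glm((choice == "yes") ~ self + other - 1,
                         family = binomial(), data = resp)),
    error = function(e) NULL)
  # linear predictors beyond ~15 logits mean the fit is saturated at 0/1
  # probabilities for every proposal: (quasi-)separated choices
  sep <- is.null(fit) || !fit$converged ||
    max(abs(predict(fit))) > 15 || any(!is.finite(coef(fit)))
  if (sep) {
    warning("logistic fit separated or failed; selecting all proposals at random")
    out <- candidates[sample(nrow(candidates), n, replace = nrow(candidates) < n), ]
    out$selection <- "random"
    rownames(out) <- NULL
    return(out)
  }
  p_acc <- predict(fit, newdata = candidates, type = "response")
  generous_prop <- candidates$other > 20
  p_generous <- ifelse(generous_prop, p_acc, 1 - p_acc)
  n30 <- floor(0.3 * n)
  ord <- order(p_generous, decreasing = TRUE)
  gen_idx <- ord[seq_len(n30)]
  slf_idx <- rev(ord)[seq_len(n30)]
  rest <- setdiff(seq_len(nrow(candidates)), c(gen_idx, slf_idx))
  rnd_idx <- sample(rest, n - 2 * n30)
  out <- candidates[c(gen_idx, slf_idx, rnd_idx), ]
  out$selection <- rep(c("generous_likely", "selfish_likely", "random"),
                       c(n30, n30, n - 2 * n30))
  rownames(out) <- NULL
  attr(out, "logistic_weights") <- coef(fit)
  attr(out, "task") <- "altruism"
  out
}

#' Simulate a subject's choice dataset
#'
#' Simulates every trial of every condition with the accumulator
#' ([simulate_trials()]), presenting each stimulus once per condition in
#' randomized order, tagged with the 9-runs-of-10 block structure.
#'
#' @param params Named list of [ddm_params()], one per condition.
#' @param stimuli Stimulus data frame ([gen_stimuli()]); its row count must
#'   be divisible by 9.
#' @param subject Subject identifier.
#' @param task `"food"` or `"altruism"`.
#' @param payoff_reference Default payoff subtracted from altruism payoffs
#'   when they enter the drift ([recode_attributes()]); the returned table
#'   keeps raw dollars.
#' @return Choice data frame with columns `subject`, `task`, `condition`,
#'   `run`, `trial`, the attribute columns, `choice` and `rt_s`.
#' @export
gen_behavior <- function(params, stimuli, subject = 1,
                         task = c("food", "altruism"),
                         payoff_reference = 20) {
  task <- match.arg(task)
  if (task == "altruism" && is.null(stimuli$fairness))
    stimuli$fairness <- fairness(stimuli$self, stimuli$other)
  n <- nrow(stimuli)
  if (n %% 9L != 0L) stop("number of stimuli must be divisible by 9 runs")
  per_run <- n %/% 9L
  out <- lapply(names(params), function(cond) {
    ord <- sample(n)
    st <- stimuli[ord, task_attributes(task), drop = FALSE]
    sim <- simulate_trials(params[[cond]],
                           recode_attributes(st, task, payoff_reference))
    data.frame(subject = subject, task = task, condition = cond,
               run = rep(1:9, each = per_run), trial = seq_len(n),
               st, choice = sim$choice, rt_s = sim$rt,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Simulate a full behavioral cohort
#'
#' @param n_subjects Cohort size (the food-task sample was 36; configurable
#'   up to larger samples).
#' @param task `"food"` or `"altruism"`.
#' @param heterogeneous Draw per-subject weights around the cohort means
#'   ([cohort_params()])?
#' @param n_items Stimuli per condition.
#' @param ... Passed to [ddm_params()] via [cohort_params()].
#' @return Choice data frame for all subjects (rbind of [gen_behavior()]),
#'   with the per-subject generating weights attached as attribute
#'   `"generating_weights"`.
#' @export
gen_cohort <- function(n_subjects = 36, task = c("food", "altruism"),
                       heterogeneous = TRUE, n_items = 90, ...) {
  task <- match.arg(task)
  conds <- task_conditions(task)
  gw <- list()
  out <- lapply(seq_len(n_subjects), function(s) {
    stim <- gen_stimuli(task, n_items)
    pars <- lapply(setNames(conds, conds), function(cc)
      cohort_params(task, cc, heterogeneous = heterogeneous, ...))
    gw[[s]] <<- lapply(pars, `[[`, "weights")
    gen_behavior(pars, stim, subject = s, task = task)
  })
  structure(do.call(rbind, out), generating_weights = gw)
}

#' Encoding specification for synthetic voxel patterns
#'
#' Describes how trial patterns encode attribute values: a volume geometry,
#' a set of spherical regions each carrying one independent unit-norm code
#' vector per attribute, per-condition non-negative gains, additive
#' Gaussian voxel noise, and optionally a success-coding ROI whose common
#' direction carries subject-level regulatory-success scores.  The planted
#' signal-to-noise ratio of an attribute in a region is
#' `gain * sd(attribute values) / noise_sd` per voxel-pattern norm unit.
#'
#' @param dim Volume dimensions in voxels.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param regions List of regions, each a list with `center` (voxel
#'   coordinates), `radius` (voxels) and `gain`: a named list/matrix mapping
#'   attribute to a named vector of per-condition gains (>= 0).
#' @param noise_sd SD of the additive voxel noise.
#' @param success Optional list with `center`, `radius` and `beta` for the
#'   success-coding ROI.
#' @param mask Optional logical array; default all voxels in the volume.
#' @return An object of class `encoding_spec`.  Code vectors are drawn (from
#'   the current RNG stream) once per spec, so every dataset generated from
#'   the same spec shares the same attribute codes.
#' @export
encoding_spec <- function(dim = c(20, 20, 20), voxel_mm = 3,
                          regions = list(), noise_sd = 1,
                          success = NULL, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim)
  stopifnot(all(dim(mask) == dim))
  regions <- lapply(regions, function(r) {
    r$voxels <- sphere_voxels(r$center, r$radius, dim)
    if (!all(mask[r$voxels]))
      stop("region extends outside the mask")
    gains <- r$gain
    attrs <- names(gains)
    r$code <- lapply(setNames(attrs, attrs), function(a) {
      u <- rnorm(length(r$voxels))
      u / sqrt(sum(u^2))
    })
    if (any(unlist(gains) < 0)) stop("gains must be non-negative")
    r
  })
  if (!is.null(success)) {
    success$voxels <- sphere_voxels(success$center, success$radius, dim)
    u <- rnorm(length(success$voxels))
    success$direction <- u / sqrt(sum(u^2))
  }
  structure(list(dim = dim, voxel_mm = voxel_mm, regions = regions,
                 noise_sd = noise_sd, success = success, mask = mask),
            class = "encoding_spec")
}

# linear indices of in-volume voxels within Euclidean radius of center
sphere_voxels <- function(center, radius, dim) {
  r <- floor(radius)
  off <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  off <- off[off$x^2 + off$y^2 + off$z^2 <= radius^2, ]
  vx <- sweep(as.matrix(off), 2, center, `+`)
  keep <- vx[, 1] >= 1 & vx[, 1] <= dim[1] &
    vx[, 2] >= 1 & vx[, 2] <= dim[2] &
    vx[, 3] >= 1 & vx[, 3] <= dim[3]
  vx <- vx[keep, , drop = FALSE]
  sort(vx[, 1] + dim[1] * (vx[, 2] - 1) + dim[1] * dim[2] * (vx[, 3] - 1))
}

#' Generate trial-wise voxel patterns for a behavioral dataset
#'
#' Each trial's pattern is the sum, over regions and attributes, of the
#' region's attribute code vector scaled by the condition's gain and the
#' trial's attribute value, plus isotropic Gaussian noise; voxels outside
#' every region carry pure noise.
#'
#' @param behavior Choice data frame ([gen_behavior()]) for one subject.
#' @param spec An [encoding_spec()].
#' @return An object of class `pattern_dataset`: list with `X` (trials x
#'   in-mask voxels), `meta` (the behavior table), `dim`, `voxel_mm`,
#'   `mask`, and `mask_index` (linear volume index of each column of `X`).
#' @export
gen_patterns <- function(behavior, spec) {
  mask_index <- which(spec$mask)
  n_vox <- length(mask_index)
  n_tr <- nrow(behavior)
  X <- matrix(rnorm(n_tr * n_vox, sd = spec$noise_sd), n_tr, n_vox)
  col_of <- match(seq_len(prod(spec$dim)), mask_index)
  for (r in spec$regions) {
    cols <- col_of[r$voxels]
    for (a in names(r$gain)) {
      g <- r$gain[[a]][behavior$condition]
      if (any(is.na(g)))
        stop("region gain for attribute '", a,
             "' lacks condition(s) present in the behavior table")
      X[, cols] <- X[, cols] + (g * behavior[[a]]) %o% r$code[[a]]
    }
  }
  structure(list(X = X, meta = behavior, dim = spec$dim,
                 voxel_mm = spec$voxel_mm, mask = spec$mask,
                 mask_index = mask_index),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("pattern dataset: %d trials x %d voxels (volume %s, %g mm)\n",
              nrow(x$X), ncol(x$X), paste(x$dim, collapse = "x"),
              x$voxel_mm))
  invisible(x)
}

#' Generate subject-level contrast patterns encoding success scores
#'
#' One pattern per subject: within the spec's success ROI the pattern is
#' `beta * score * v` for a common unit direction `v`, plus noise; all
#' other voxels are pure noise.
#'
#' @param scores Numeric vector of per-subject regulatory-success scores.
#' @param spec An [encoding_spec()] with a `success` component.
#' @return Subjects x in-mask-voxels matrix with attribute `"roi_cols"`
#'   giving the columns of the success ROI.
#' @export
gen_success_patterns <- function(scores, spec) {
  if (is.null(spec$success)) stop("encoding spec has no success ROI")
  mask_index <- which(spec$mask)
  n_vox <- length(mask_index)
  X <- matrix(rnorm(length(scores) * n_vox, sd = spec$noise_sd),
              length(scores), n_vox)
  cols <- match(spec$success$voxels, mask_index)
  X[, cols] <- X[, cols] +
    (spec$success$beta * scores) %o% spec$success$direction
  attr(X, "roi_cols") <- cols
  X
}
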