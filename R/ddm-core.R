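# Multi-attribute drift diffusion model with exponentially collapsing bounds.
#
# The accumulator starts at 0 after the non-decision time and takes discrete
# Euler steps of dt seconds.  Each step adds the drift increment (a weighted
# sum of the trial's attribute values) plus Gaussian noise; a "yes" response
# is emitted when the relative decision value (RDV) reaches the upper bound,
# "no" at the lower bound.  Both bounds collapse exponentially toward zero as
# the response deadline approaches, so late evidence needs less support.

#' Attribute sets for the two choice tasks
#'
#' The food task describes each on-screen item by its tastiness and
#' healthiness, rated on 5-point scales and recoded to -2..+2 around the
#' neutral default food.  The altruism task describes each monetary proposal
#' by the payoff to the chooser (`self`), the payoff to the anonymous partner
#' (`other`), both in dollars 0-40, and the derived `fairness` attribute
#' `-|self - other|`.
#'
#' @param task `"food"` or `"altruism"`.
#' @return Character vector of attribute names, in canonical order.
#' @export
#' @examples
#' task_attributes("food")
task_attributes <- function(task = c("food", "altruism")) {
  task <- match.arg(task)
  if (task == "food") c("taste", "health") else c("self", "other", "fairness")
}

#' Fairness of a proposed payoff split
#'
#' Fairness is the negative absolute gap between the two payoffs,
#' `-|self - other|`, so an equal split scores 0 and every unequal split is
#' negative.
#'
#' @param self_payoff,other_payoff Payoffs in dollars.
#' @return Fairness in (negative) dollars.
#' @export
#' @examples
#' fairness(20, 20)  # 0
#' fairness(40, 0)   # -40
fairness <- function(self_payoff, other_payoff) {
  stopifnot(is.finite(self_payoff), is.finite(other_payoff))
  -abs(self_payoff - other_payoff)
}

#' Drift diffusion model parameters
#'
#' Bundles the free parameters of the accumulator (attribute weights,
#' non-decision time, initial bound height, bound decay rate) with the fixed
#' simulation constants (per-step noise, step size, response deadline).
#'
#' @param weights Named numeric vector of attribute weights (drift units per
#'   attribute unit per step).  Names must exactly match the task's
#'   attribute set (see [task_attributes()]).
#' @param ndt Non-decision time in seconds (perceptual/motor latency).
#' @param bound0 Initial bound height (> 0).  The RDV starts at 0; bounds sit
#'   at +/- `bound0` at the end of the non-decision time.
#' @param decay Exponential decay rate of the bound toward zero, per second
#'   (>= 0; 0 means constant bounds).
#' @param noise_sd Standard deviation of the per-step Gaussian noise (fixed
#'   convention, not fitted).
#' @param dt Step size in seconds.
#' @param deadline Response deadline in seconds; accumulation past the
#'   deadline is a missed trial.
#' @return An object of class `ddm_params`.
#' @export
#' @examples
#' ddm_params(c(taste = 0.0163, health = -0.0003), ndt = 0.4,
#'            bound0 = 1, decay = 0.5)
ddm_params <- function(weights, ndt = 0.4, bound0 = 1.0, decay = 0.5,
                       noise_sd = 0.1, dt = 0.008, deadline = 4.0) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("'weights' must be a fully named numeric vector")
  stopifnot(is.numeric(weights), all(is.finite(weights)),
            is.finite(ndt), ndt >= 0, bound0 > 0, decay >= 0,
            noise_sd > 0, dt > 0, deadline > 0)
  if (ndt >= deadline) stop("'ndt' must be smaller than 'deadline'")
  structure(list(weights = weights, ndt = ndt, bound0 = bound0,
                 decay = decay, noise_sd = noise_sd, dt = dt,
                 deadline = deadline),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Multi-attribute DDM parameters\n")
  cat("  weights: ",
      paste(sprintf("%s = %.4g", names(x$weights), x$weights),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  ndt = %.3f s, bound0 = %.3f, decay = %.3f /s\n",
              x$ndt, x$bound0, x$decay))
  cat(sprintf("  constants: noise_sd = %.3g/step, dt = %.3g s, deadline = %g s\n",
              x$noise_sd, x$dt, x$deadline))
  invisible(x)
}

#' Recode task attributes to the model's default-relative scale
#'
#' The accumulator models the choice between the on-screen option and the
#' default, so attribute values enter the drift relative to the default:
#' food ratings are already coded -2..+2 around the neutral default food,
#' while altruism payoffs are recoded as `self - reference` and
#' `other - reference` around the $20/$20 default allocation (fairness is 0
#' at the default and needs no shift).  Missing `fairness` columns are
#' derived from the raw payoffs first.  Dataset files keep raw $0-40
#' payoffs; this recoding is applied at model entry.
#'
#' @param data Data frame with the task's attribute columns.
#' @param task `"food"` or `"altruism"`.
#' @param payoff_reference Default payoff in dollars subtracted from `self`
#'   and `other`.
#' @return The data frame with recoded attribute columns.
#' @export
recode_attributes <- function(data, task, payoff_reference = 20) {
  if (task == "altruism") {
    if (is.null(data$fairness)) data$fairness <- fairness(data$self, data$other)
    data$self <- data$self - payoff_reference
    data$other <- data$other - payoff_reference
  }
  data
}

# Attribute values of one or many trials as a numeric matrix whose columns
# match the weight names; errors on schema mismatch.
attr_matrix <- function(attrs, weights) {
  nm <- names(weights)
  if (is.data.frame(attrs)) attrs <- as.matrix(attrs[, intersect(colnames(attrs), nm), drop = FALSE])
  if (is.null(dim(attrs))) attrs <- matrix(attrs, nrow = 1,
                                           dimnames = list(NULL, names(attrs)))
  missing <- setdiff(nm, colnames(attrs))
  if (length(missing))
    stop("attribute value(s) missing for weight(s): ",
         paste(missing, collapse = ", "))
  attrs[, nm, drop = FALSE]
}

#' Deterministic drift increment of a trial
#'
#' The per-step drift is the weighted sum of the trial's attribute values;
#' per-step noise is added on top of this by the accumulator.
#'
#' @param params A [ddm_params()] object.
#' @param attrs Named numeric vector, or a data frame/matrix with one row per
#'   trial, holding attribute values.  Names must cover the weight names.
#' @return Numeric vector of drift increments (per step), one per trial.
#' @export
#' @examples
#' p <- ddm_params(c(taste = 0.0163, health = -0.0003))
#' drift_increment(p, c(taste = 2, health = 0))
drift_increment <- function(params, attrs) {
  a <- attr_matrix(attrs, params$weights)
  drop(a %*% params$weights)
}

#' Decision bound height at a time point
#'
#' Bounds are constant at `bound0` during the non-decision time and then
#' collapse exponentially toward zero: `bound0 * exp(-decay * (t - ndt))`.
#' Bounds are symmetric at plus/minus this value.
#'
#' @param params A [ddm_params()] object.
#' @param t Time from stimulus onset, seconds (vectorized).
#' @return Bound height(s), strictly positive.
#' @export
bound_at <- function(params, t) {
  stopifnot(all(t >= 0))
  ifelse(t < params$ndt, params$bound0,
         params$bound0 * exp(-params$decay * (t - params$ndt)))
}

#' Simulate choices and response times from the accumulator
#'
#' Draws one stochastic accumulation path per trial.  Uses R's random number
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param params A [ddm_params()] object.
#' @param attrs Attribute values, as in [drift_increment()]; one row (or one
#'   vector) per trial.
#' @param n Number of replicate simulations when `attrs` is a single trial.
#' @return Data frame with columns `choice` (`"yes"`, `"no"`, `"missed"`) and
#'   `rt` (seconds; `NA` for missed trials).
#' @export
#' @examples
#' set.seed(1)
#' p <- ddm_params(c(taste = 0.02, health = 0))
#' table(simulate_trials(p, c(taste = 1, health = 0), n = 100)$choice)
simulate_trials <- function(params, attrs, n = NULL) {
  v <- drift_increment(params, attrs)
  if (!is.null(n)) {
    if (length(v) != 1L) stop("'n' is only meaningful for a single trial")
    v <- rep(v, n)
  }
  sim <- cpp_simulate_trials(v, params$bound0, params$decay, params$ndt,
                             params$noise_sd, params$dt, params$deadline)
  data.frame(choice = c("no", "missed", "yes")[sim$choice + 2L],
             rt = sim$rt, stringsAsFactors = FALSE)
}

#' Joint choice/response-time distribution of the accumulator
#'
#' Propagates the full probability distribution of the RDV forward in time
#' over a discrete grid with absorbing, collapsing bounds, yielding the joint
#' probability of each (choice, RT bin) plus the probability of missing the
#' deadline.  This deterministic density is the kernel of the model's
#' likelihood.
#'
#' @param params A [ddm_params()] object.
#' @param attrs Attribute values for one or more trials; one density per
#'   distinct drift value is computed.
#' @param rt_bin RT bin width in seconds.
#' @param n_grid Number of RDV grid points (odd).
#' @param span Half-width of the RDV grid in units of `bound0`.
#' @return For a single trial, an object of class `choice_rt_density`: a list
#'   with `rt_bin_edges`, `p_yes`, `p_no` (per-bin probabilities) and
#'   `p_missed`.  For several trials, a list of such objects (one per trial,
#'   shared between trials with equal drift).
#' @export
#' @examples
#' p <- ddm_params(c(taste = 0.02, health = 0))
#' d <- choice_rt_density(p, c(taste = 1, health = 0))
#' sum(d$p_yes) + sum(d$p_no) + d$p_missed  # 1
choice_rt_density <- function(params, attrs, rt_bin = 0.05, n_grid = 201,
                              span = 1.2) {
  v <- drift_increment(params, attrs)
  uv <- unique(v)
  dens <- cpp_fpt_density(uv, params$bound0, params$decay, params$ndt,
                          params$noise_sd, params$dt, params$deadline,
                          rt_bin, n_grid, span)
  edges <- seq(0, by = rt_bin, length.out = dens$n_bins + 1L)
  one <- function(j) {
    structure(list(rt_bin_edges = edges,
                   p_yes = dens$p_yes[, j],
                   p_no = dens$p_no[, j],
                   p_missed = dens$p_missed[j],
                   drift = uv[j]),
              class = "choice_rt_density")
  }
  if (length(v) == 1L) return(one(1L))
  lapply(match(v, uv), one)
}

#' @export
print.choice_rt_density <- function(x, ...) {
  cat(sprintf(paste0("choice/RT density: P(yes) = %.4f, P(no) = %.4f, ",
                     "P(missed) = %.4f (%d RT bins)\n"),
              sum(x$p_yes), sum(x$p_no), x$p_missed,
              length(x$p_yes)))
  invisible(x)
}

# RT bin index (1-based) for observed RTs; must mirror the C++ assignment.
rt_bin_of <- function(rt, rt_bin, n_bins) {
  pmin(pmax(floor(rt / rt_bin + 1e-9), 0) + 1L, n_bins)
}

#' Log-likelihood of a choice dataset under DDM parameters
#'
#' Sums, over trials, the log joint density of the observed (choice, RT bin);
#' missed trials contribute the log probability of reaching the deadline.
#' Densities are computed once per distinct drift value.  Zero densities are
#' floored at `floor_lik` so the optimizer never sees `-Inf`.
#'
#' @param params A [ddm_params()] object.
#' @param data Choice data frame for a single subject and condition, with a
#'   `choice` column (`"yes"`/`"no"`/`"missed"`), an `rt` (or `rt_s`) column
#'   in seconds, and one column per model attribute.
#' @param rt_bin,n_grid,span Density resolution, as in [choice_rt_density()].
#' @param floor_lik Lower floor applied to per-trial densities.
#' @param contaminant Mixture weight of a uniform contaminant distribution
#'   over the outcome space (choice x RT bin, plus missed).  A small value
#'   makes the likelihood robust to outlier responses and removes the
#'   cliffs that near-deterministic trials otherwise carve into the
#'   surface; 0 gives the pure process likelihood.
#' @return The summed log-likelihood (scalar).
#' @export
log_likelihood <- function(params, data, rt_bin = 0.05, n_grid = 201,
                           span = 1.2, floor_lik = 1e-10,
                           contaminant = 0) {
  if (!nrow(data)) stop("empty dataset")
  rt <- if ("rt" %in% names(data)) data$rt else data$rt_s
  v <- drift_increment(params, data)
  uv <- unique(v)
  dens <- cpp_fpt_density(uv, params$bound0, params$decay, params$ndt,
                          params$noise_sd, params$dt, params$deadline,
                          rt_bin, n_grid, span)
  j <- match(v, uv)
  n_bins <- dens$n_bins
  lik <- numeric(nrow(data))
  missed <- data$choice == "missed"
  lik[missed] <- dens$p_missed[j[missed]]
  if (any(!missed)) {
    b <- rt_bin_of(rt[!missed], rt_bin, n_bins)
    idx <- cbind(b, j[!missed])
    yes <- data$choice[!missed] == "yes"
    lik[!missed][yes] <- dens$p_yes[idx[yes, , drop = FALSE]]
    lik[!missed][!yes] <- dens$p_no[idx[!yes, , drop = FALSE]]
  }
  if (contaminant > 0)
    lik <- (1 - contaminant) * lik + contaminant / (2 * n_bins + 1)
  sum(log(pmax(lik, floor_lik)))
}
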