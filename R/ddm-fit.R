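# Maximum-likelihood fitting of the multi-attribute DDM, one subject and
# condition at a time.  The likelihood is the deterministic grid density of
# ddm-core.R; optimization is multi-start derivative-free trust-region
# search (BOBYQA) inside box constraints, on rescaled parameters so all
# coordinates move on comparable scales.

#' Control settings for [fit_ddm()]
#'
#' @param weight_box,ndt_box,bound0_box,decay_box Lower/upper box bounds for
#'   the attribute weights (shared across attributes), non-decision time (s),
#'   initial bound height and bound decay rate (1/s).
#' @param n_starts Number of Latin-hypercube starting points screened by one
#'   likelihood evaluation each.
#' @param n_refine Cap on additional full refinements granted to
#'   Latin-hypercube starts whose screened value beats the informed route's
#'   optimum.
#' @param maxit,reltol Function-evaluation cap and final trust-region radius
#'   (on the rescaled parameter scale) of each refinement run.
#' @param rt_bin,n_grid,span Likelihood resolution (see
#'   [choice_rt_density()]).
#' @param floor_lik Per-trial density floor.
#' @param contaminant Uniform-contaminant mixture weight in the fitted
#'   likelihood (see [log_likelihood()]); a small value smooths the
#'   cliffs that near-deterministic trials create.
#' @param missed_warn Warn when the fraction of missed trials exceeds this.
#' @return A list of class `ddm_fit_control`.
#' @export
ddm_fit_control <- function(weight_box = c(-0.05, 0.05),
                            ndt_box = c(0.1, 1.5),
                            bound0_box = c(0.2, 3),
                            decay_box = c(0, 2),
                            n_starts = 10, n_refine = 1,
                            maxit = 250, reltol = 1e-5,
                            rt_bin = 0.05, n_grid = 121, span = 1.2,
                            floor_lik = 1e-10, contaminant = 0.005,
                            missed_warn = 0.2) {
  structure(as.list(environment()), class = "ddm_fit_control")
}


#' Fit the multi-attribute DDM to one subject and condition
#'
#' Maximizes the grid-density likelihood over the attribute weights,
#' non-decision time, initial bound height and bound decay rate (5 free
#' parameters for the food task, 6 for the altruism task; per-step noise is
#' a fixed scaling convention).  Optimization is staged derivative-free
#' (BOBYQA) search within box constraints: the weights are first optimized
#' alone at candidate non-decision times anchored just below the fastest
#' response (starting from a logistic-regression-informed weight vector and
#' from zero), the winner seeds a full-vector refinement, Latin-hypercube
#' starts act as a screened safety net, and coordinate cycles plus a short
#' polish conclude when the refinement has not converged.
#'
#' @param data Choice data for a single subject x condition: columns
#'   `choice` (`"yes"`/`"no"`/`"missed"`), `rt_s` (or `rt`) in seconds, and
#'   one column per task attribute.
#' @param task `"food"` or `"altruism"`; determines the attribute set.
#' @param constants A [ddm_params()]-style list giving the fixed simulation
#'   constants `noise_sd`, `dt`, `deadline`.
#' @param control A [ddm_fit_control()] list.
#' @param payoff_reference Default payoff subtracted from altruism payoffs
#'   before they enter the drift (see [recode_attributes()]).
#' @return An object of class `ddm_fit` with components `params`
#'   ([ddm_params()]), `loglik`, `n_trials`, `converged`,
#'   `n_restarts_used`, `task` and `data`.
#' @seealso [posterior_predictive_check()], [coef.ddm_fit()],
#'   [simulate.ddm_fit()]
#' @export
#' @examples
#' set.seed(42)
#' p <- ddm_params(c(taste = 0.0163, health = -0.0003))
#' stim <- gen_stimuli("food")
#' beh <- gen_behavior(list(NC = p), stim, subject = 1, task = "food")
#' fit <- fit_ddm(beh, task = "food",
#'                control = ddm_fit_control(n_starts = 4, maxit = 150))
#' coef(fit)
fit_ddm <- function(data, task = c("food", "altruism"),
                    constants = list(noise_sd = 0.1, dt = 0.008, deadline = 4),
                    control = ddm_fit_control(), payoff_reference = 20) {
  task <- match.arg(task)
  attrs <- task_attributes(task)
  if (!nrow(data)) stop("empty dataset")
  data <- recode_attributes(data, task, payoff_reference)
  if (!all(attrs %in% names(data)))
    stop("data lacks attribute column(s): ",
         paste(setdiff(attrs, names(data)), collapse = ", "))
  if (is.null(data$rt_s) && !is.null(data$rt)) data$rt_s <- data$rt
  miss_rate <- mean(data$choice == "missed")
  if (miss_rate > control$missed_warn)
    warning(sprintf("%.0f%% of trials are missed responses", 100 * miss_rate))

  k <- length(attrs)
  lo <- c(rep(control$weight_box[1], k), control$ndt_box[1],
          control$bound0_box[1], control$decay_box[1])
  hi <- c(rep(control$weight_box[2], k), control$ndt_box[2],
          control$bound0_box[2], control$decay_box[2])
  par_names <- c(attrs, "ndt", "bound0", "decay")

  mk_params <- function(theta) {
    theta <- unname(theta)
    ddm_params(setNames(theta[seq_len(k)], attrs),
               ndt = theta[k + 1], bound0 = theta[k + 2], decay = theta[k + 3],
               noise_sd = constants$noise_sd, dt = constants$dt,
               deadline = constants$deadline)
  }
  # comparable coordinate scales for the trust-region search
  scales <- c(rep(0.01, k), 0.3, 0.7, 0.5)
  # lean objective: attribute matrix, responses and bins precomputed once
  A <- attr_matrix(data, setNames(numeric(k), attrs))
  n_bins <- as.integer(ceiling(constants$deadline / control$rt_bin - 1e-9))
  missed <- data$choice == "missed"
  is_yes <- data$choice == "yes" & !missed
  rtb <- integer(nrow(data))
  rtb[!missed] <- rt_bin_of(data$rt_s[!missed], control$rt_bin, n_bins)
  unif <- 1 / (2 * n_bins + 1)
  negll <- function(x) {
    th <- x * scales
    v <- drop(A %*% th[seq_len(k)])
    uv <- unique(v)
    dens <- cpp_fpt_density(uv, th[k + 2], th[k + 3], th[k + 1],
                            constants$noise_sd, constants$dt,
                            constants$deadline, control$rt_bin,
                            control$n_grid, control$span)
    j <- match(v, uv)
    lik <- numeric(length(v))
    lik[missed] <- dens$p_missed[j[missed]]
    lik[is_yes] <- dens$p_yes[cbind(rtb[is_yes], j[is_yes])]
    no <- !missed & !is_yes
    lik[no] <- dens$p_no[cbind(rtb[no], j[no])]
    if (control$contaminant > 0)
      lik <- (1 - control$contaminant) * lik + control$contaminant * unif
    val <- -sum(log(pmax(lik, control$floor_lik)))
    if (!is.finite(val)) val <- 1e10
    val
  }

  xlo <- lo / scales; xhi <- hi / scales
  wi <- seq_len(k); si <- k + 1:3
  # minqa warns whenever maxfun is modest relative to dimension; the
  # staged budgets are deliberate, so silence that advisory
  bobyqa_q <- function(...) suppressWarnings(minqa::bobyqa(...))
  sub_opt <- function(x, idx, rhobeg, maxfun, rhoend = control$reltol) {
    f <- function(xs) { x[idx] <- xs; negll(x) }
    opt <- bobyqa_q(x[idx], f, lower = xlo[idx], upper = xhi[idx],
                         control = list(rhobeg = rhobeg, rhoend = rhoend,
                                        maxfun = maxfun))
    x[idx] <- opt$par
    list(par = x, fval = opt$fval)
  }

  # Latin-hypercube starts kept away from the box edges (screened only;
  # refined if they beat the informed route)
  u <- lhs::randomLHS(control$n_starts, k + 3)
  lhs_starts <- t(apply(u, 1, function(r) lo + (0.1 + 0.8 * r) * (hi - lo)))

  # informed weight start: logistic choice weights rescaled to drift units
  # by the random-walk absorption relation beta ~= 2 b w / noise_sd^2 at
  # b = 1; under separation the ratios are kept but the magnitude capped
  resp <- data[data$choice != "missed", , drop = FALSE]
  w_heur <- rep(0, k)
  if (nrow(resp) > k && length(unique(resp$choice)) == 2L) {
    X <- attr_matrix(resp, setNames(numeric(k), attrs))
    g <- tryCatch(suppressWarnings(
      glm((resp$choice == "yes") ~ X - 1, family = binomial())),
      error = function(e) NULL)
    if (!is.null(g) && all(is.finite(coef(g)))) {
      w0 <- coef(g) * constants$noise_sd^2 / 2
      if (max(abs(w0)) > 0.015) w0 <- w0 * 0.015 / max(abs(w0))
      w_heur <- w0
    }
  }
  # candidate non-decision times anchored just below the fastest response:
  # the likelihood climbs steeply toward the first-RT cliff, so a start
  # near the cliff conditions the search far better than a generic one
  min_rt <- suppressWarnings(min(resp$rt_s, na.rm = TRUE))
  if (!is.finite(min_rt)) min_rt <- 0.5 * constants$deadline
  clamp_ndt <- function(x) min(max(x, control$ndt_box[1] + 0.01),
                               control$ndt_box[2] - 0.01)
  ndt_cands <- unique(c(clamp_ndt(min_rt - 0.03), clamp_ndt(min_rt - 0.15)))

  # Stage 1: weights-only search at each candidate ndt (bound 1, decay
  # 0.5); the k-dimensional subproblem is well conditioned and cheap
  seeds <- c(lapply(ndt_cands, function(nd) c(w_heur, nd, 1, 0.5)),
             list(c(rep(0, k), ndt_cands[1], 1, 0.5)))
  w_best <- NULL
  for (s0 in seeds) {
    cand <- sub_opt(s0 / scales, wi, 0.5, 100, rhoend = 1e-3)
    if (is.null(w_best) || cand$fval < w_best$fval) w_best <- cand
  }

  # Stage 2: full-vector refinement from the seeded start
  opt <- bobyqa_q(w_best$par, negll, lower = xlo, upper = xhi,
                       control = list(rhobeg = 0.25,
                                      rhoend = control$reltol,
                                      maxfun = control$maxit))
  best <- list(par = opt$par, fval = opt$fval)
  conv <- opt$ierr == 0L
  n_runs <- 1L

  # safety net: a Latin-hypercube start earns a full refinement only when
  # its screened value already beats the refined optimum
  screen <- apply(sweep(lhs_starts, 2, scales, `/`), 1, negll)
  n_extra <- min(control$n_refine, sum(screen < best$fval))
  if (n_extra > 0) {
    for (i in order(screen)[seq_len(n_extra)]) {
      opt <- bobyqa_q(lhs_starts[i, ] / scales, negll,
                           lower = xlo, upper = xhi,
                           control = list(rhobeg = 0.25,
                                          rhoend = control$reltol,
                                          maxfun = control$maxit))
      n_runs <- n_runs + 1L
      if (opt$fval < best$fval) {
        best <- list(par = opt$par, fval = opt$fval)
        conv <- opt$ierr == 0L
      }
    }
  }

  # Stage 3: if refinement ran out of evaluations, coordinate cycles
  # (weights-only, then shape-only) walk the weight/bound ridge that can
  # stall a full-space run; a short full polish always concludes
  if (!conv) {
    for (cycle in 1:2) {
      f0 <- best$fval
      cand <- sub_opt(best$par, wi, 0.1, 100)
      if (cand$fval < best$fval) best <- cand
      cand <- sub_opt(best$par, si, 0.1, 100)
      if (cand$fval < best$fval) best <- cand
      if (best$fval > f0 - 1e-3) break
    }
  }
  # polish restarts until a fresh run from the optimum finds essentially
  # no further improvement (the practical stationarity declaration) or
  # reaches its trust-region tolerance
  for (round in 1:3) {
    f_before <- best$fval
    opt <- bobyqa_q(best$par, negll, lower = xlo, upper = xhi,
                    control = list(rhobeg = 0.05,
                                   rhoend = control$reltol,
                                   maxfun = 120))
    if (opt$fval < best$fval) best <- list(par = opt$par, fval = opt$fval)
    if (opt$ierr == 0L || (f_before - best$fval) < 1e-3) {
      conv <- TRUE
      break
    }
  }
  theta <- best$par * scales
  names(theta) <- par_names
  structure(list(params = mk_params(theta), loglik = -best$fval,
                 n_trials = nrow(data), n_missed = sum(data$choice == "missed"),
                 converged = conv, n_restarts_used = n_runs,
                 task = task, control = control, data = data,
                 payoff_reference = payoff_reference),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Multi-attribute DDM fit (%s task, %d trials, %d missed)\n",
              x$task, x$n_trials, x$n_missed))
  print(x$params)
  cat(sprintf("  log-likelihood: %.2f  (%d restarts, %s)\n", x$loglik,
              x$n_restarts_used,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.ddm_fit <- function(object, ...) {
  with(object$params,
       c(weights, ndt = unname(ndt), bound0 = unname(bound0),
         decay = unname(decay)))
}

#' @export
logLik.ddm_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$params$weights) + 3L,
            nobs = object$n_trials, class = "logLik")
}

#' @export
summary.ddm_fit <- function(object, ...) {
  out <- list(coef = coef(object), loglik = object$loglik,
              n_trials = object$n_trials, n_missed = object$n_missed,
              converged = object$converged, task = object$task,
              p_yes = mean(object$data$choice == "yes"),
              median_rt = median(object$data$rt_s, na.rm = TRUE))
  class(out) <- "summary.ddm_fit"
  out
}

#' @export
print.summary.ddm_fit <- function(x, ...) {
  cat(sprintf("DDM fit summary (%s task)\n", x$task))
  print(round(x$coef, 5))
  cat(sprintf("logLik %.2f on %d trials (%d missed); P(yes) = %.2f, median RT = %.2f s\n",
              x$loglik, x$n_trials, x$n_missed, x$p_yes, x$median_rt))
  invisible(x)
}

#' Simulate replicate datasets from a fitted DDM
#'
#' Re-simulates the fitted dataset's stimuli under the fitted parameters.
#'
#' @param object A `ddm_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed passed to `set.seed()`.
#' @param ... Unused.
#' @return A list of `nsim` data frames shaped like the fitted data.
#' @export
simulate.ddm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    out <- object$data
    sim <- simulate_trials(object$params, object$data)
    out$choice <- sim$choice
    out$rt_s <- sim$rt
    out
  })
}

#' Model predictions for trials
#'
#' Per-trial acceptance probability, probability of a missed response and
#' mean RT implied by the fitted (or supplied) parameters.
#'
#' @param object A `ddm_fit`.
#' @param newdata Optional data frame of trials (attribute columns); default
#'   the fitted data.
#' @param ... Unused.
#' @return Data frame with columns `p_yes`, `p_missed`, `mean_rt`.
#' @export
predict.ddm_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else
    recode_attributes(newdata, object$task, object$payoff_reference)
  dens <- choice_rt_density(object$params, data,
                            rt_bin = object$control$rt_bin,
                            n_grid = object$control$n_grid,
                            span = object$control$span)
  if (inherits(dens, "choice_rt_density")) dens <- list(dens)
  mids <- (head(dens[[1]]$rt_bin_edges, -1) + dens[[1]]$rt_bin_edges[-1]) / 2
  do.call(rbind, lapply(dens, function(d) {
    pr <- sum(d$p_yes) + sum(d$p_no)
    data.frame(p_yes = sum(d$p_yes),
               p_missed = d$p_missed,
               mean_rt = if (pr > 0) sum(mids * (d$p_yes + d$p_no)) / pr else NA_real_)
  }))
}

#' @export
residuals.ddm_fit <- function(object, ...) {
  pred <- predict(object)
  obs <- ifelse(object$data$choice == "missed", NA_real_,
                as.numeric(object$data$choice == "yes"))
  obs - pred$p_yes
}

#' @export
plot.ddm_fit <- function(x, ...) {
  plot(posterior_predictive_check(x), ...)
}
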