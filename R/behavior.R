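# Behavioral scoring: healthy/altruistic choice definitions, per-condition
# percentages, regulatory-success contrasts, and the small-sample statistics
# used to compare attribute weights across regulatory conditions.

#' Classify a food choice as healthy or unhealthy
#'
#' A healthy choice accepts the on-screen food when it is healthier than the
#' default food, or rejects it when it is less healthy.  Trials where the
#' two foods are equally healthy carry no health signal and are classified
#' `"undefined"`, as are missed responses; undefined trials are excluded
#' from percentage scores.
#'
#' @param choice `"yes"`, `"no"` or `"missed"` (vectorized).
#' @param onscreen_health Health rating of the on-screen food.
#' @param default_health Health rating of the default food (same scale).
#' @return Character vector: `"healthy"`, `"unhealthy"` or `"undefined"`.
#' @export
#' @examples
#' classify_healthy_choice("yes", 5, 3)   # healthy
#' classify_healthy_choice("yes", 2, 3)   # unhealthy
#' classify_healthy_choice("no", 3, 3)    # undefined (tie)
classify_healthy_choice <- function(choice, onscreen_health,
                                    default_health = 0) {
  out <- rep("undefined", length(choice))
  out[choice == "yes" & onscreen_health > default_health] <- "healthy"
  out[choice == "no" & onscreen_health < default_health] <- "healthy"
  out[choice == "yes" & onscreen_health < default_health] <- "unhealthy"
  out[choice == "no" & onscreen_health > default_health] <- "unhealthy"
  out
}

#' Classify an altruism-task choice as altruistic or selfish
#'
#' Every proposal trades off the chooser's payoff against the partner's
#' relative to the default allocation.  A choice is altruistic when it
#' accepts a proposal that benefits the partner at a cost to the self, or
#' rejects one that benefits the self at the partner's expense; the opposite
#' responses are selfish.  Missed responses are `"undefined"`.
#'
#' @param choice `"yes"`, `"no"` or `"missed"` (vectorized).
#' @param self_payoff,other_payoff Proposal payoffs in dollars.
#' @param default Default allocation `c(self, other)` in dollars.
#' @return Character vector: `"altruistic"`, `"selfish"` or `"undefined"`.
#' @export
#' @examples
#' classify_altruistic_choice("yes", 13, 27)  # altruistic
#' classify_altruistic_choice("no", 31, 9)    # altruistic
classify_altruistic_choice <- function(choice, self_payoff, other_payoff,
                                       default = c(20, 20)) {
  generous_prop <- other_payoff > default[2] & self_payoff <= default[1]
  selfish_prop <- self_payoff > default[1] & other_payoff <= default[2]
  if (any(!generous_prop & !selfish_prop))
    stop("proposal(s) violate the self/other trade-off structure")
  out <- rep("undefined", length(choice))
  out[choice == "yes" & generous_prop] <- "altruistic"
  out[choice == "no" & selfish_prop] <- "altruistic"
  out[choice == "yes" & selfish_prop] <- "selfish"
  out[choice == "no" & generous_prop] <- "selfish"
  out
}

#' Percentage of goal-consistent choices per condition
#'
#' Computes percent healthy (food task) or percent altruistic (altruism
#' task) choices over the defined trials of each condition.
#'
#' @param data Choice data for one subject with columns `condition`,
#'   `choice` and the task's attribute columns.
#' @param task `"food"` or `"altruism"`.
#' @param default Default option: health rating of the default food, or the
#'   `c(self, other)` default allocation.
#' @return Named numeric vector of percentages per condition.
#' @export
percent_goal_choices <- function(data, task = c("food", "altruism"),
                                 default = NULL) {
  task <- match.arg(task)
  cls <- if (task == "food") {
    classify_healthy_choice(data$choice, data$health,
                            if (is.null(default)) 0 else default)
  } else {
    classify_altruistic_choice(data$choice, data$self, data$other,
                               if (is.null(default)) c(20, 20) else default)
  }
  good <- if (task == "food") "healthy" else "altruistic"
  defined <- cls != "undefined"
  100 * tapply(cls[defined] == good, data$condition[defined], mean)
}

#' Regulatory-success contrast
#'
#' The goal-consistent change in a per-condition score between two
#' conditions, e.g. the increase in percent healthy choices under the
#' health goal relative to natural choice.
#'
#' @param pct_by_condition Named numeric vector of per-condition scores.
#' @param contrast Length-2 character vector `c(condA, condB)`; the score is
#'   `pct[condA] - pct[condB]`.
#' @return Difference in the score's units (percentage points for choice
#'   percentages).
#' @export
#' @examples
#' regulatory_success(c(HC = 78.83, NC = 44.31), c("HC", "NC"))  # 34.52
regulatory_success <- function(pct_by_condition, contrast) {
  stopifnot(length(contrast) == 2)
  if (!all(contrast %in% names(pct_by_condition)))
    stop("condition(s) missing from 'pct_by_condition': ",
         paste(setdiff(contrast, names(pct_by_condition)), collapse = ", "))
  unname(pct_by_condition[contrast[1]] - pct_by_condition[contrast[2]])
}

#' Per-subject regulatory-success scores
#'
#' Choice-based scores (differences in percent goal-consistent choices) and
#' weight-based scores (differences in fitted attribute weights) for the
#' standard condition contrasts of a task.
#'
#' @param data Choice data for one subject (all conditions).
#' @param fits Optional named list of `ddm_fit` objects, one per condition;
#'   when given, weight-based scores are included.
#' @param task `"food"` or `"altruism"`.
#' @param contrasts List of length-2 character vectors; defaults to the
#'   task's standard contrasts.
#' @return One-row data frame of scores named `d_choice_<A>_<B>` and
#'   `dw_<attribute>_<A>_<B>`.
#' @export
success_scores <- function(data, fits = NULL, task = c("food", "altruism"),
                           contrasts = NULL) {
  task <- match.arg(task)
  if (is.null(contrasts)) {
    contrasts <- if (task == "food") {
      list(c("HC", "NC"), c("HC", "TC"), c("NC", "TC"))
    } else {
      list(c("PC", "NC"), c("EC", "NC"), c("PC", "EC"))
    }
  }
  pct <- percent_goal_choices(data, task)
  out <- lapply(contrasts, function(ct) regulatory_success(pct, ct))
  names(out) <- vapply(contrasts, function(ct)
    paste0("d_choice_", ct[1], "_", ct[2]), "")
  if (!is.null(fits)) {
    for (ct in contrasts) {
      wa <- coef(fits[[ct[1]]])
      wb <- coef(fits[[ct[2]]])
      for (a in task_attributes(task))
        out[[paste0("dw_", a, "_", ct[1], "_", ct[2])]] <-
          unname(wa[a] - wb[a])
    }
  }
  as.data.frame(out)
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on `z`.
#'
#' @param x,y,z Numeric vectors of equal length (n >= 4).
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(x) == length(z), length(x) >= 4,
            all(is.finite(c(x, y, z))))
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero variance in residuals; partial correlation undefined")
  cor(rx, ry)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA with condition as the single factor:
#' `F = MS_condition / MS_(condition x subject)` with `k - 1` and
#' `(k - 1)(n - 1)` degrees of freedom.
#'
#' @param values Complete numeric matrix, subjects in rows, conditions in
#'   columns (>= 3 subjects, >= 2 conditions).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 3, ncol(values) >= 2, all(is.finite(values)))
  n <- nrow(values); k <- ncol(values)
  grand <- mean(values)
  cond_means <- colMeans(values)
  subj_means <- rowMeans(values)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  if (ms_err <= 0) {
    if (ms_cond == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    warning("zero error mean square; F reported as Inf")
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  Fv <- ms_cond / ms_err
  list(F = Fv, df1 = df1, df2 = df2, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

#' All pairwise paired t-tests with Bonferroni correction
#'
#' @param values Subject x condition matrix as in [rm_anova()].
#' @return Data frame with one row per condition pair: `t`, `df`, `p` and
#'   `p_corrected` (p multiplied by the number of pairs, capped at 1).
#' @export
paired_tests_bonferroni <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  pairs <- utils::combn(k, 2)
  nms <- colnames(values)
  if (is.null(nms)) nms <- paste0("C", seq_len(k))
  out <- apply(pairs, 2, function(ij) {
    d <- values[, ij[1]] - values[, ij[2]]
    if (sd(d) == 0) {
      c(t = 0, df = length(d) - 1, p = 1)
    } else {
      tt <- t.test(d)
      c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    }
  })
  res <- as.data.frame(t(out))
  res$p_corrected <- pmin(res$p * ncol(pairs), 1)
  data.frame(pair = paste(nms[pairs[1, ]], nms[pairs[2, ]], sep = "-"), res)
}

#' Posterior predictive check of a fitted DDM
#'
#' Re-simulates the fitted dataset's stimuli `n_rep` times under the fitted
#' parameters and compares observed to predicted acceptance rates per
#' attribute-value bin, and observed to predicted RT quantiles.
#'
#' @param fit A `ddm_fit`.
#' @param data Optional data to check against (default: the fitted data).
#' @param n_rep Number of simulated replicates.
#' @param n_bins Number of attribute-value bins for the acceptance curves.
#' @param probs RT quantiles to compare.
#' @return An object of class `ddm_ppc` with elements `p_yes` (per
#'   attribute: bin centers, observed and predicted acceptance rates) and
#'   `rt_quantiles` (observed vs predicted).
#' @export
posterior_predictive_check <- function(fit, data = NULL, n_rep = 100,
                                       n_bins = 5,
                                       probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (is.null(data)) data <- fit$data
  attrs <- task_attributes(fit$task)
  sims <- simulate(fit, nsim = n_rep)
  sim_yes <- vapply(sims, function(s) as.numeric(s$choice == "yes"),
                    numeric(nrow(data)))
  obs_yes <- as.numeric(data$choice == "yes")
  p_yes <- lapply(setNames(attrs, attrs), function(a) {
    x <- data[[a]]
    br <- if (length(unique(x)) <= n_bins) sort(unique(x)) else
      unique(quantile(x, seq(0, 1, length.out = n_bins + 1)))
    bin <- if (length(br) == length(unique(x))) factor(x) else
      cut(x, br, include.lowest = TRUE)
    data.frame(value = tapply(x, bin, mean),
               observed = tapply(obs_yes, bin, mean),
               predicted = tapply(rowMeans(sim_yes), bin, mean))
  })
  obs_rt <- data$rt_s[data$choice != "missed"]
  sim_rt <- unlist(lapply(sims, function(s) s$rt_s[s$choice != "missed"]))
  rtq <- data.frame(prob = probs,
                    observed = quantile(obs_rt, probs, na.rm = TRUE),
                    predicted = quantile(sim_rt, probs, na.rm = TRUE))
  structure(list(p_yes = p_yes, rt_quantiles = rtq, task = fit$task),
            class = "ddm_ppc")
}

#' @export
print.ddm_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$task, " task)\n", sep = "")
  for (a in names(x$p_yes)) {
    cat("P(yes) by", a, "bin:\n")
    print(round(x$p_yes[[a]], 3))
  }
  cat("RT quantiles (s):\n")
  print(round(x$rt_quantiles, 3))
  invisible(x)
}

#' @export
plot.ddm_ppc <- function(x, ...) {
  old <- par(mfrow = c(1, length(x$p_yes) + 1))
  on.exit(par(old))
  for (a in names(x$p_yes)) {
    d <- x$p_yes[[a]]
    plot(d$value, d$observed, ylim = c(0, 1), pch = 19,
         xlab = a, ylab = "P(yes)", main = paste("P(yes) by", a))
    lines(d$value, d$predicted, col = 2, lwd = 2)
    legend("topleft", c("observed", "predicted"), pch = c(19, NA),
           lty = c(NA, 1), col = c(1, 2), bty = "n")
  }
  plot(x$rt_quantiles$observed, x$rt_quantiles$predicted, pch = 19,
       xlab = "observed RT quantile (s)", ylab = "predicted RT quantile (s)",
       main = "RT quantiles")
  abline(0, 1, col = "grey")
  invisible(x)
}
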