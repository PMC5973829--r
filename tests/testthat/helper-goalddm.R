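# shared fixtures: small, fast configurations used across test files

fast_control <- function(...) {
  ddm_fit_control(n_starts = 4, n_refine = 1, maxit = 250, ...)
}

# cohort-mean parameters for one condition
mean_params <- function(task, condition, ...) {
  cohort_params(task, condition, heterogeneous = FALSE, ...)
}

# one simulated subject x condition dataset at the cohort means
sim_subject <- function(task = "food", condition = "NC", params = NULL,
                        subject = 1) {
  if (is.null(params)) params <- mean_params(task, condition)
  stim <- gen_stimuli(task)
  gen_behavior(setNames(list(params), condition), stim, subject, task)
}

# small encoding spec with one signal region per attribute
small_spec <- function(task = "food", dim = c(12, 12, 12), noise_sd = 1,
                       gain = 1, conditions = task_conditions(task)) {
  attrs <- task_attributes(task)
  centers <- list(c(4, 4, 6), c(9, 9, 6), c(6, 9, 4))
  regions <- lapply(seq_along(attrs), function(i) {
    g <- setNames(rep(gain, length(conditions)), conditions)
    list(center = centers[[i]], radius = 2,
         gain = setNames(list(g), attrs[i]))
  })
  encoding_spec(dim = dim, regions = regions, noise_sd = noise_sd,
                success = list(center = c(6, 6, 6), radius = 2,
                               beta = 1))
}
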