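# Synthetic study generators: stimuli, behavior, voxel patterns.

test_that("food stimuli cover the rating grid roughly uniformly", {
  set.seed(301)
  st <- gen_stimuli("food")
  expect_equal(nrow(st), 90)
  expect_true(all(st$taste %in% -2:2 & st$health %in% -2:2))
  counts <- table(factor(st$taste, -2:2), factor(st$health, -2:2))
  expect_true(all(abs(counts - 90 / 25) <= 3))
})

test_that("altruism proposals always trade off self against other", {
  set.seed(302)
  st <- gen_stimuli("altruism", n_items = 200)
  expect_true(all(st$self >= 0 & st$self <= 40 & st$other >= 0 &
                    st$other <= 40))
  gen <- st$self <= 20 & st$other > 20
  slf <- st$self > 20 & st$other <= 20
  expect_true(all(xor(gen, slf)))
  expect_equal(st$fairness, -abs(st$self - st$other))
})

test_that("generators are reproducible under a fixed seed", {
  make <- function() {
    set.seed(303)
    st <- gen_stimuli("food")
    beh <- gen_behavior(list(NC = mean_params("food", "NC")), st, 1, "food")
    pat <- gen_patterns(beh, small_spec("food", conditions = "NC"))
    list(st, beh, pat$X)
  }
  expect_identical(make(), make())
})

test_that("behavior tables have the 9x10 run structure per condition", {
  set.seed(304)
  pars <- lapply(setNames(nm = task_conditions("food")), function(cc)
    mean_params("food", cc))
  beh <- gen_behavior(pars, gen_stimuli("food"), 7, "food")
  expect_equal(nrow(beh), 270)
  expect_equal(as.integer(table(beh$condition)), rep(90L, 3))
  expect_true(all(table(beh$condition, beh$run) == 10))
  expect_true(validate_choice_data(beh)$ok)
})

test_that("zero weights give chance-level healthy choice; the health goal raises it", {
  set.seed(305)
  p0 <- ddm_params(c(taste = 0, health = 0))
  beh0 <- do.call(rbind, lapply(1:6, function(s)
    gen_behavior(list(NC = p0), gen_stimuli("food"), s, "food")))
  pct0 <- percent_goal_choices(beh0, "food")
  expect_equal(unname(pct0["NC"]), 50, tolerance = 5)
  pars <- list(NC = mean_params("food", "NC"), HC = mean_params("food", "HC"))
  behg <- do.call(rbind, lapply(1:6, function(s)
    gen_behavior(pars, gen_stimuli("food"), s, "food")))
  pctg <- percent_goal_choices(behg, "food")
  expect_gt(pctg["HC"], pctg["NC"] + 10)
})

test_that("trial selection splits 30/30/40 and targets generosity", {
  set.seed(306)
  # a strongly other-regarding simulated chooser
  p <- ddm_params(c(self = 0.002, other = 0.012, fairness = 0))
  nc <- gen_behavior(list(NC = p), gen_stimuli("altruism"), 1, "altruism")
  candidates <- gen_stimuli("altruism", n_items = 500)
  sel <- select_altruism_trials(nc, candidates, n = 90)
  expect_equal(as.integer(table(sel$selection)[c("generous_likely",
                                                 "selfish_likely", "random")]),
               c(27L, 27L, 36L))
  # logistic recovers the generating preference direction
  w <- attr(sel, "logistic_weights")
  expect_gt(w["other"], 0)
  expect_gt(w["other"], w["self"])
  gen_mean <- mean(sel$other[sel$selection == "generous_likely"])
  rnd_mean <- mean(sel$other[sel$selection == "random"])
  expect_gt(gen_mean, rnd_mean)
})

test_that("trial selection falls back to random sampling under separation", {
  nc <- data.frame(self = c(0, 40), other = c(40, 0),
                   choice = c("yes", "no"))
  nc <- nc[rep(1:2, 20), ]
  candidates <- gen_stimuli("altruism", n_items = 200)
  expect_warning(sel <- select_altruism_trials(nc, candidates, n = 90),
                 "random")
  expect_equal(nrow(sel), 90)
})

test_that("patterns carry the planted linear code and nothing else", {
  set.seed(307)
  spec <- small_spec("food", noise_sd = 0.5, gain = 1)
  beh <- gen_behavior(lapply(setNames(nm = task_conditions("food")),
                             function(cc) mean_params("food", cc)),
                      gen_stimuli("food"), 1, "food")
  pat <- gen_patterns(beh, spec)
  expect_equal(nrow(pat$X), 270)
  expect_equal(ncol(pat$X), sum(spec$mask))
  # in-region decoding works, off-region decoding does not
  roi <- match(spec$regions[[1]]$voxels, pat$mask_index)
  sel <- pat$meta$condition == "NC"
  z_in <- crossval_accuracy(pat$X[sel, roi], pat$meta$taste[sel],
                            pat$meta$run[sel])
  far <- setdiff(seq_len(ncol(pat$X)),
                 unlist(lapply(spec$regions, function(r)
                   match(r$voxels, pat$mask_index))))
  z_out <- crossval_accuracy(pat$X[sel, far[1:30]], pat$meta$taste[sel],
                             pat$meta$run[sel])
  expect_gt(z_in, 0.3)
  expect_lt(abs(z_out), 0.2)
})

test_that("pure-noise patterns give chance-level decoding", {
  set.seed(308)
  spec <- small_spec("food", gain = 0)
  beh <- gen_behavior(list(NC = mean_params("food", "NC")),
                      gen_stimuli("food"), 1, "food")
  # single-decode accuracies are noisy (SD ~0.1); average 5 regenerations
  z <- replicate(5, {
    pat <- gen_patterns(beh, spec)
    roi <- match(spec$regions[[1]]$voxels, pat$mask_index)
    crossval_accuracy(pat$X[, roi], pat$meta$taste, pat$meta$run)
  })
  expect_lt(abs(mean(z)), 0.15)
})

test_that("success patterns encode the scores at the planted ROI", {
  set.seed(309)
  spec <- small_spec("food", noise_sd = 0.3)
  scores <- rnorm(12)
  X <- gen_success_patterns(scores, spec)
  roi <- attr(X, "roi_cols")
  # projecting onto the ROI recovers score ordering
  proj <- X[, roi] %*% spec$success$direction
  expect_gt(cor(proj, scores), 0.8)
  # zero effect size leaves noise
  spec0 <- small_spec("food", noise_sd = 0.3)
  spec0$success$beta <- 0
  X0 <- gen_success_patterns(scores, spec0)
  expect_lt(abs(cor(X0[, attr(X0, "roi_cols")] %*% spec0$success$direction,
                    scores)), 0.6)
})

test_that("region outside the mask is rejected", {
  m <- array(TRUE, c(8, 8, 8)); m[1:2, , ] <- FALSE
  expect_error(
    encoding_spec(dim = c(8, 8, 8), mask = m,
                  regions = list(list(center = c(2, 4, 4), radius = 2,
                                      gain = list(taste = c(NC = 1))))),
    "mask")
})
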