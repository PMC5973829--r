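# Searchlight geometry, SVR decoding, accuracy maps, smoothing and the
# cross-condition generalization matrix.

test_that("searchlight membership counts follow sphere geometry", {
  mask <- array(TRUE, c(11, 11, 11))
  sl <- build_searchlights(mask, radius = 4)
  # interior voxel: all integer offsets with i^2+j^2+k^2 <= 16
  center <- which(sl$center == 6 + 11 * 5 + 121 * 5)
  expect_equal(length(sl$members[[center]]), 257)
  # corner voxel is truncated
  corner <- which(sl$center == 1)
  expect_lt(length(sl$members[[corner]]), 257)
  sl0 <- build_searchlights(mask, radius = 0, min_voxels = 1)
  expect_true(all(lengths(sl0$members) == 1))
  expect_error(build_searchlights(mask, radius = -1))
  expect_error(build_searchlights(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("searchlights below the member floor are marked missing", {
  mask <- array(FALSE, c(9, 9, 9))
  mask[5, 5, 5] <- TRUE; mask[5, 5, 6] <- TRUE
  sl <- build_searchlights(mask, radius = 4, min_voxels = 10)
  expect_true(all(vapply(sl$members, is.null, TRUE)))
})

test_that("SVR predicts a noiseless linear problem and rejects constants", {
  set.seed(401)
  y <- rep(seq(-2, 2), 8)
  X <- cbind(y)
  pred <- svr_decode_fold(X, y, matrix(c(-2, 0, 2), 3, 1))
  expect_gt(cor(pred, c(-2, 0, 2)), 0.99)
  expect_error(svr_decode_fold(X, rep(1, length(y)), X), "constant")
})

test_that("cross-validated accuracy reduces to its closed forms", {
  # two folds engineered so each fold correlation is exactly +/- known
  set.seed(402)
  y <- rep(c(-2, -1, 0, 1, 2), 4)
  X <- matrix(y + rnorm(20, sd = 1e-6), ncol = 1)
  fold <- rep(1:2, each = 10)
  z <- crossval_accuracy(X, y, fold)
  expect_equal(z, atanh(0.999), tolerance = 1e-3)  # clipped perfect r
  expect_error(crossval_accuracy(X, y, rep(1, 20)), "folds")
  # the average of Fisher z values, not of correlations
  expect_equal(mean(fisher_z(c(0.5, 0.5))), atanh(0.5), tolerance = 1e-12)
})

test_that("decoding of permuted labels is centred on chance", {
  set.seed(403)
  X <- matrix(rnorm(90 * 20), 90, 20)
  y <- rep(seq(-2, 2), each = 18)
  fold <- rep(1:9, each = 10)
  z <- replicate(40, crossval_accuracy(X, sample(y), fold))
  expect_lt(abs(mean(z)), 0.05)
})

test_that("searchlight maps localize a planted code and are deterministic", {
  set.seed(404)
  spec <- small_spec("food", dim = c(10, 10, 10), noise_sd = 0.5)
  beh <- gen_behavior(list(NC = mean_params("food", "NC")),
                      gen_stimuli("food"), 1, "food")
  pat <- gen_patterns(beh, spec)
  map <- run_searchlight(pat, "taste", "NC", radius = 2)
  expect_s3_class(map, "accuracy_map")
  sig_vox <- spec$regions[[1]]$voxels
  in_z <- map$values[sig_vox]
  out_vox <- setdiff(which(!is.na(map$values)),
                     unlist(lapply(spec$regions, `[[`, "voxels")))
  out_z <- map$values[out_vox]
  expect_gt(mean(in_z), mean(out_z) + 3 * sd(out_z))
  # re-running on the same inputs reproduces the map exactly
  map2 <- run_searchlight(pat, "taste", "NC", radius = 2)
  expect_identical(map$values, map2$values)
})

test_that("accuracy is invariant to voxel order", {
  set.seed(405)
  spec <- small_spec("food", dim = c(8, 8, 8), noise_sd = 1)
  beh <- gen_behavior(list(NC = mean_params("food", "NC")),
                      gen_stimuli("food"), 1, "food")
  pat <- gen_patterns(beh, spec)
  roi <- match(spec$regions[[1]]$voxels, pat$mask_index)
  z1 <- crossval_accuracy(pat$X[, roi], pat$meta$taste, pat$meta$run)
  perm <- sample(length(roi))
  z2 <- crossval_accuracy(pat$X[, roi[perm]], pat$meta$taste, pat$meta$run)
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("smoothing preserves constants and kernel mass, and fwhm = 0 is identity", {
  arr <- array(1, c(12, 12, 12))
  sm <- smooth_map(arr, fwhm = 6, voxel_mm = 3)
  expect_equal(sm, arr, tolerance = 1e-6)
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  smi <- smooth_map(imp, fwhm = 6, voxel_mm = 3)
  expect_equal(sum(smi), 1, tolerance = 1e-3)
  expect_identical(smooth_map(imp, fwhm = 0), imp)
  # NA voxels (outside mask) stay NA and do not bleed in
  arr2 <- array(1, c(10, 10, 10)); arr2[1:3, , ] <- NA
  sm2 <- smooth_map(arr2, fwhm = 6, voxel_mm = 3)
  expect_true(all(is.na(sm2[1:3, , ])))
  expect_equal(sm2[4:10, , ], arr2[4:10, , ], tolerance = 1e-6)
})

test_that("cross-condition matrix separates shared from independent codes", {
  set.seed(406)
  # same code for an attribute across conditions; independent across attrs
  spec <- small_spec("food", dim = c(8, 8, 8), noise_sd = 0.6,
                     conditions = c("NC", "HC"))
  spec$regions <- list(list(
    center = c(4, 4, 4), radius = 2,
    gain = list(taste = c(NC = 1, HC = 1), health = c(NC = 1, HC = 1))))
  spec <- encoding_spec(dim = spec$dim, regions = spec$regions,
                        noise_sd = 0.6)
  pars <- list(NC = mean_params("food", "NC"), HC = mean_params("food", "HC"))
  beh <- gen_behavior(pars, gen_stimuli("food"), 1, "food")
  pat <- gen_patterns(beh, spec)
  roi <- match(spec$regions[[1]]$voxels, pat$mask_index)
  m <- cross_condition_matrix(pat, roi, c("taste", "health"),
                              conditions = c("NC", "HC"), n_perm = 200)
  expect_true(isSymmetric(m$z))
  within <- m$z["taste.NC", "taste.HC"]
  across <- m$z["taste.NC", "health.HC"]
  expect_gt(within, across)
  expect_true(m$significant["taste.NC", "taste.HC"])
  expect_true(m$significant["health.NC", "health.HC"])
  expect_false(m$significant["taste.NC", "health.HC"])
  expect_false(m$significant["taste.HC", "health.NC"])
})
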