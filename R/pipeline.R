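# Orchestration and artifact I/O.  Choice tables travel as TSV, volumes as
# NIfTI-1; run_pipeline() chains the stages end-to-end under a single seed
# and writes a manifest of everything it produced.

#' Read / write choice datasets as tab-separated text
#'
#' @param path File path.
#' @param data Choice data frame.
#' @return `read_choice_data()` returns the data frame.
#' @export
read_choice_data <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_choice_data
#' @export
write_choice_data <- function(data, path) {
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a 3-D map as NIfTI-1
#'
#' @param x 3-D array, `accuracy_map` or `stat_map` (the statistic is
#'   written).
#' @param path Output path (`.nii`).
#' @param voxel_mm Isotropic voxel size.
#' @return `read_volume()` returns a plain 3-D array.
#' @export
write_volume <- function(x, path, voxel_mm = 3) {
  if (inherits(x, "accuracy_map")) { voxel_mm <- x$voxel_mm; x <- x$values }
  if (inherits(x, "stat_map")) x <- x$stat
  img <- RNifti::asNifti(x, pixdim = rep(voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}

#' Validate a choice dataset against the expected schema
#'
#' Checks column presence, vocabulary (conditions and choices of the
#' declared task), the 9-runs-of-10 structure and 90 trials per condition,
#' attribute ranges (ratings in -2..2, payoffs in 0..40), and the RT
#' deadline.
#'
#' @param data Choice data frame or path to a TSV file.
#' @param deadline Response deadline (s).
#' @return List of class `validation_report` with `ok`, `violations`
#'   (character vector) and `counts` (trials per subject x condition).
#' @export
validate_choice_data <- function(data, deadline = 4) {
  if (is.character(data)) data <- read_choice_data(data)
  v <- character(0)
  need <- c("subject", "task", "condition", "run", "trial", "choice", "rt_s")
  miss <- setdiff(need, names(data))
  if (length(miss)) v <- c(v, paste("missing column(s):",
                                    paste(miss, collapse = ", ")))
  if (!length(miss)) {
    task <- unique(data$task)
    for (tk in task) {
      d <- data[data$task == tk, ]
      if (!tk %in% c("food", "altruism")) {
        v <- c(v, paste("unknown task:", tk)); next
      }
      bad_attr <- setdiff(task_attributes(tk), names(data))
      if (length(bad_attr))
        v <- c(v, paste0(tk, ": missing attribute column(s): ",
                         paste(bad_attr, collapse = ", ")))
      bad_cond <- setdiff(unique(d$condition), task_conditions(tk))
      if (length(bad_cond))
        v <- c(v, paste0(tk, ": condition label(s) outside vocabulary: ",
                         paste(bad_cond, collapse = ", ")))
      if (tk == "food" && !length(bad_attr) &&
          !all(d$taste %in% -2:2 & d$health %in% -2:2))
        v <- c(v, "food: ratings outside -2..2")
      if (tk == "altruism" && !length(bad_attr) &&
          !all(d$self >= 0 & d$self <= 40 & d$other >= 0 & d$other <= 40))
        v <- c(v, "altruism: payoffs outside 0..40")
    }
    bad_choice <- setdiff(unique(data$choice), c("yes", "no", "missed"))
    if (length(bad_choice))
      v <- c(v, paste("choice label(s) outside vocabulary:",
                      paste(bad_choice, collapse = ", ")))
    rts <- data$rt_s[data$choice != "missed"]
    if (any(!is.finite(rts)) || any(rts > deadline))
      v <- c(v, sprintf("RTs missing or exceeding the %g s deadline", deadline))
    counts <- table(data$subject, data$task, data$condition)
    if (any(counts != 0 & counts != 90))
      v <- c(v, "trial counts per subject x condition differ from 90")
    runs <- table(data$subject, data$task, data$condition, data$run)
    if (any(runs != 0 & runs != 10))
      v <- c(v, "run structure differs from 9 runs of 10 trials")
  }
  counts <- if (!length(miss)) table(subject = data$subject,
                                     condition = data$condition) else NULL
  structure(list(ok = !length(v), violations = v, counts = counts),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("OK\n") else {
    cat("violations:\n")
    for (v in x$violations) cat(" -", v, "\n")
  }
  if (!is.null(x$counts)) print(x$counts)
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run.  `seed` is mandatory;
#' each stage derives its random stream from it (`seed + stage index`), so
#' a config reproduces bit-identically.
#'
#' @param seed Integer master seed.
#' @param tasks Tasks to simulate and analyze.
#' @param n_subjects Cohort size.
#' @param dim,voxel_mm,noise_sd Volume geometry and voxel noise of the
#'   synthetic patterns.
#' @param radius Searchlight radius (voxels).
#' @param fwhm Accuracy-map smoothing FWHM (mm).
#' @param cost,nu SVR hyperparameters.
#' @param height_p,alpha,n_perm Group-inference settings.
#' @param fit_control A [ddm_fit_control()].
#' @param constants DDM simulation constants.
#' @param heterogeneous Sample per-subject weights around the cohort means?
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, tasks = "food", n_subjects = 36,
                            dim = c(20, 20, 20), voxel_mm = 3,
                            noise_sd = 1, radius = 4, fwhm = 6,
                            cost = 0.01, nu = 0.5, height_p = 0.001,
                            alpha = 0.05, n_perm = 1000,
                            fit_control = ddm_fit_control(),
                            constants = list(noise_sd = 0.1, dt = 0.008,
                                             deadline = 4),
                            heterogeneous = TRUE) {
  if (missing(seed)) stop("pipeline config requires a 'seed'")
  cfg <- as.list(environment())
  stopifnot(all(tasks %in% c("food", "altruism")), n_subjects >= 1,
            radius >= 0, fwhm >= 0, cost > 0, nu > 0, nu <= 1,
            height_p > 0, height_p < 1, alpha > 0, alpha < 1, n_perm >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(args$dim)) args$dim <- as.integer(args$dim)
  do.call(pipeline_config, args)
}

#' Run the analysis pipeline end-to-end
#'
#' Stages: `behavior` (simulate the cohort), `fit` (per-subject DDM fits
#' and the weight table), `score` (success scores and condition-wise
#' weight statistics), `neural` (synthetic trial patterns), `searchlight`
#' (per-subject accuracy maps, smoothed), `group` (main effect and
#' condition contrast with cluster correction, conjunction), and
#' `success` (cross-subject LOSO decoding with permutation test).  All
#' artifacts are written under `out_dir` together with a JSON manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run (later stages need earlier ones in
#'   the same call).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("behavior", "fit", "score", "neural",
                                    "searchlight", "group", "success")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(packageVersion("goalddm")),
                   stages = list(), outputs = character(0))
  t_all <- proc.time()[3]
  note <- function(stage, t0, files) {
    manifest$stages[[stage]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    manifest$outputs <<- c(manifest$outputs, files)
  }
  behavior <- fits <- patterns <- scores <- NULL
  maps <- list()

  for (task in config$tasks) {
    conds <- task_conditions(task)
    attrs <- task_attributes(task)

    if ("behavior" %in% stages) {
      t0 <- proc.time()[3]; set.seed(config$seed + 1)
      behavior <- gen_cohort(config$n_subjects, task,
                             heterogeneous = config$heterogeneous)
      f <- file.path(out_dir, paste0("behavior_", task, ".tsv"))
      write_choice_data(behavior, f)
      note("behavior", t0, f)
    }
    if ("fit" %in% stages) {
      t0 <- proc.time()[3]; set.seed(config$seed + 2)
      fits <- lapply(split(behavior, behavior$subject), function(d)
        lapply(setNames(conds, conds), function(cc)
          fit_ddm(d[d$condition == cc, ], task = task,
                  constants = config$constants,
                  control = config$fit_control)))
      wt <- do.call(rbind, lapply(names(fits), function(s)
        do.call(rbind, lapply(conds, function(cc)
          data.frame(subject = s, condition = cc,
                     t(coef(fits[[s]][[cc]])))))))
      f <- file.path(out_dir, paste0("ddm_fits_", task, ".tsv"))
      write_choice_data(wt, f)
      # attribute x condition weight table (mean +/- SD over subjects)
      tab <- do.call(rbind, lapply(attrs, function(a)
        data.frame(attribute = a,
                   condition = conds,
                   mean = tapply(wt[[a]], wt$condition, mean)[conds],
                   sd = tapply(wt[[a]], wt$condition, sd)[conds])))
      f2 <- file.path(out_dir, paste0("weight_table_", task, ".tsv"))
      write_choice_data(tab, f2)
      note("fit", t0, c(f, f2))
    }
    if ("score" %in% stages) {
      t0 <- proc.time()[3]
      scores <- do.call(rbind, lapply(split(behavior, behavior$subject),
                                      function(d)
        cbind(subject = d$subject[1],
              success_scores(d, fits = if (is.null(fits)) NULL else
                fits[[as.character(d$subject[1])]], task = task))))
      f <- file.path(out_dir, paste0("success_scores_", task, ".tsv"))
      write_choice_data(scores, f)
      files <- f
      if (!is.null(fits) && length(fits) >= 3) {
        stats <- lapply(setNames(attrs, attrs), function(a) {
          m <- do.call(rbind, lapply(fits, function(fs)
            vapply(fs[conds], function(x) coef(x)[a], numeric(1))))
          list(anova = rm_anova(m), pairs = paired_tests_bonferroni(m))
        })
        f2 <- file.path(out_dir, paste0("weight_anova_", task, ".tsv"))
        write_choice_data(do.call(rbind, lapply(names(stats), function(a)
          data.frame(attribute = a, F = stats[[a]]$anova$F,
                     df1 = stats[[a]]$anova$df1, df2 = stats[[a]]$anova$df2,
                     p = stats[[a]]$anova$p))), f2)
        files <- c(files, f2)
      }
      note("score", t0, files)
    }
    if ("neural" %in% stages) {
      t0 <- proc.time()[3]; set.seed(config$seed + 3)
      spec <- default_encoding_spec(task, config)
      patterns <- lapply(split(behavior, behavior$subject),
                         gen_patterns, spec = spec)
      f <- file.path(out_dir, paste0("mask_", task, ".nii"))
      write_volume(array(as.numeric(spec$mask), config$dim), f,
                   config$voxel_mm)
      note("neural", t0, f)
      manifest$encoding <- list(regions = length(spec$regions),
                                noise_sd = spec$noise_sd)
    }
    if ("searchlight" %in% stages) {
      t0 <- proc.time()[3]; set.seed(config$seed + 4)
      sls <- build_searchlights(patterns[[1]]$mask, config$radius)
      files <- character(0)
      maps <- lapply(patterns, function(p)
        lapply(setNames(attrs, attrs), function(a)
          lapply(setNames(conds, conds), function(cc)
            smooth_map(run_searchlight(p, a, cc, searchlights = sls,
                                       cost = config$cost, nu = config$nu),
                       fwhm = config$fwhm))))
      for (a in attrs) for (cc in conds) {
        f <- file.path(out_dir, sprintf("accuracy_%s_%s_%s_subj1.nii",
                                        task, a, cc))
        write_volume(maps[[1]][[a]][[cc]], f)
        files <- c(files, f)
      }
      note("searchlight", t0, files)
    }
    if ("group" %in% stages) {
      t0 <- proc.time()[3]; set.seed(config$seed + 5)
      files <- character(0)
      corrected <- list()
      for (a in attrs) {
        subj_maps <- lapply(maps, `[[`, a)
        me <- main_effect_map(subj_maps)
        cl <- cluster_correct(me, height_p = config$height_p,
                              alpha = config$alpha, n_perm = config$n_perm)
        corrected[[a]] <- cl
        f <- file.path(out_dir, sprintf("group_t_%s_%s.nii", task, a))
        write_volume(me, f, config$voxel_mm)
        f2 <- file.path(out_dir, sprintf("clusters_%s_%s.tsv", task, a))
        if (nrow(cl$clusters)) write_choice_data(cl$clusters, f2) else
          writeLines("no clusters", f2)
        files <- c(files, f, f2)
      }
      conj <- conjunction(corrected)
      f <- file.path(out_dir, paste0("conjunction_", task, ".nii"))
      write_volume(array(as.numeric(conj), config$dim), f, config$voxel_mm)
      note("group", t0, c(files, f))
    }
    if ("success" %in% stages && config$n_subjects >= 8) {
      t0 <- proc.time()[3]; set.seed(config$seed + 6)
      contrast <- if (task == "food") c(HC = 1, NC = -0.5, TC = -0.5) else
        c(PC = 1, NC = -0.5, EC = -0.5)
      spec <- default_encoding_spec(task, config)
      roi <- match(spec$regions[[1]]$voxels, which(spec$mask))
      feat <- make_contrast_features(patterns, roi, contrast)
      y <- scores[[grep("^d_choice_", names(scores))[1]]]
      res <- loso_predict_success(feat, y, cost = config$cost, nu = config$nu)
      pt <- permutation_pvalue(feat, y, observed_r = res$r,
                               n_perm = config$n_perm,
                               cost = config$cost, nu = config$nu)
      f <- file.path(out_dir, paste0("success_decoding_", task, ".tsv"))
      write_choice_data(data.frame(score = names(scores)[grep("^d_choice_",
                                                              names(scores))[1]],
                                   r = res$r, p = pt$p,
                                   significant = pt$significant), f)
      note("success", t0, f)
    }
  }
  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  manifest$hashes <- as.list(tools::md5sum(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# default planted-signal layout used by run_pipeline: one region per
# attribute whose gain follows the task's cohort weight profile, normalized
# so each attribute's strongest condition has gain 1 on rating-scale units.
default_encoding_spec <- function(task, config) {
  attrs <- task_attributes(task)
  cw <- cohort_weights(task)
  d <- config$dim
  centers <- list(c(round(d[1] / 4), round(d[2] / 4), round(d[3] / 2)),
                  c(round(3 * d[1] / 4), round(d[2] / 2), round(d[3] / 2)),
                  c(round(d[1] / 2), round(3 * d[2] / 4), round(d[3] / 4)))
  sdev <- if (task == "food") 1.4 else 12  # typical attribute-value spread
  regions <- lapply(seq_along(attrs), function(i) {
    a <- attrs[i]
    wi <- cw[cw$attribute == a, ]
    g <- pmax(wi$mean, 0)
    g <- if (max(g) > 0) g / max(g) else g
    list(center = centers[[i]], radius = 2,
         gain = setNames(list(setNames(g / sdev, wi$condition)), a))
  })
  encoding_spec(dim = d, voxel_mm = config$voxel_mm, regions = regions,
                noise_sd = config$noise_sd,
                success = list(center = centers[[1]], radius = 2,
                               beta = 0.05))
}
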