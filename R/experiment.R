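#' End-to-end experiment configuration
#'
#' Bundles the sub-configurations of every pipeline stage. All randomness
#' derives from `seed`; two runs with the same configuration produce
#' identical numbers, and every numeric output file is stamped with the
#' configuration hash.
#'
#' @param cohort A [cohort_config()] (synthetic mode) or a directory path
#'   containing per-subject NIfTI volumes plus `participants.csv`.
#' @param n_repeats,n_outer,n_inner,val_frac Cross-validation layout.
#' @param cnn_spec An [architecture_spec()] used for training (tuning over
#'   the full grid is exposed via [tune_cnn()] and not rerun per fold here).
#' @param cnn_train A [train_config()].
#' @param svm_cfg An [svm_config()] for the volume-based SVM.
#' @param fusion_weights Weight grid for probability averaging.
#' @param saliency_method `"gradcampp"` (used for subtyping) or `"deepshap"`.
#' @param subtype List of arguments forwarded to [run_subtyping()], or
#'   `NULL` to skip subtyping.
#' @param downsample_factor Modal-pooling factor applied before scaling.
#' @param output_dir Output directory (`NULL` for no files).
#' @param seed Master seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              n_repeats = 3, n_outer = 3, n_inner = 2,
                              val_frac = 0.3,
                              cnn_spec = architecture_spec(1),
                              cnn_train = train_config(lr0 = 1e-3, epochs = 40,
                                                       patience = 40,
                                                       batch_size = 32),
                              svm_cfg = svm_config("linear", cost = 1),
                              fusion_weights = seq(0, 1, by = 0.01),
                              saliency_method = "gradcampp",
                              subtype = NULL,
                              downsample_factor = 1,
                              output_dir = NULL,
                              seed = 1L) {
  structure(list(cohort = cohort, n_repeats = n_repeats, n_outer = n_outer,
                 n_inner = n_inner, val_frac = val_frac, cnn_spec = cnn_spec,
                 cnn_train = cnn_train, svm_cfg = svm_cfg,
                 fusion_weights = fusion_weights,
                 saliency_method = saliency_method, subtype = subtype,
                 downsample_factor = downsample_factor,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @export
config_hash <- function(config) object_hash(unclass(config))

#' Run the full pipeline
#'
#' Synthesize (or load) the cohort, preprocess volumes (downsample, common
#' crop, scale), build the shared partition plan, train the CNN and the SVM
#' on identical partitions, concatenate outer-fold predictions into
#' per-repeat metrics, sweep the probability-averaging fusion, compute
#' saliency for the mean-performing CNN repeat, and (optionally) subtype
#' the severe-predicted saliency maps by consensus clustering. Stage
#' outputs are cached as RDS in `output_dir` keyed by the configuration
#' hash, so reruns resume from cached intermediates.
#'
#' @param config An [experiment_config()].
#' @return A results list (`cohort_table`, `plan_hash`, `metrics`,
#'   `fusion`, `saliency`, `subtyping`, `config_hash`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  cache_get <- function(name) {
    if (is.null(config$output_dir)) return(NULL)
    f <- file.path(config$output_dir, paste0(name, "-", hash, ".rds"))
    if (file.exists(f)) readRDS(f) else NULL
  }
  cache_put <- function(name, value) {
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(value, file.path(config$output_dir,
                               paste0(name, "-", hash, ".rds")))
    }
    value
  }

  # --- cohort ---------------------------------------------------------
  cohort <- cache_get("cohort")
  if (is.null(cohort)) {
    if (inherits(config$cohort, "cohort_config")) {
      cohort <- generate_cohort(config$cohort)
    } else stop("run_experiment: cohort must be a cohort_config")
    cache_put("cohort", cohort)
  }
  tab <- cohort_table(cohort)

  # --- preprocessing --------------------------------------------------
  vols <- lapply(cohort$subjects, function(s) s$volume)
  if (config$downsample_factor > 1)
    vols <- lapply(vols, downsample_mode, factor = config$downsample_factor)
  vols <- crop_common(vols)
  scaled <- lapply(vols, function(v) scale_minmax(v)$scaled)

  # --- partitions -----------------------------------------------------
  plan <- build_nested_partitions(tab$category4, config$n_repeats,
                                  config$n_outer, config$n_inner,
                                  config$val_frac, seed = config$seed)
  phash <- object_hash(plan)

  # --- models ---------------------------------------------------------
  models <- cache_get("models")
  if (is.null(models)) {
    flat <- flatten_volumes(scaled)
    n <- length(scaled)
    metrics <- list()
    repeat_preds <- list()
    cnn_fits <- list()
    for (r in seq_len(config$n_repeats)) {
      p_cnn <- numeric(n); p_svm <- numeric(n)
      fold_fits <- list()
      for (f in seq_len(config$n_outer)) {
        fo <- plan_fold(plan, r, f)
        cfg <- config$cnn_train
        cfg$seed <- as.integer(derive_seed(config$seed, r * 100 + f))
        fit <- train_cnn(config$cnn_spec,
                         scaled[fo$retrain_train_ids],
                         tab$label2[fo$retrain_train_ids], cfg,
                         scaled[fo$retrain_val_ids],
                         tab$label2[fo$retrain_val_ids])
        p_cnn[fo$test_ids] <-
          predict_proba(fit, scaled[fo$test_ids])[, "severe"]
        sfit <- train_svm(flat[fo$train_ids, , drop = FALSE],
                          tab$label2[fo$train_ids], config$svm_cfg)
        p_svm[fo$test_ids] <-
          predict_proba_svm(sfit, flat[fo$test_ids, , drop = FALSE])[, "severe"]
        fold_fits[[f]] <- fit
      }
      lab_cnn <- ifelse(p_cnn >= 0.5, "severe", "nonsevere")
      lab_svm <- ifelse(p_svm >= 0.5, "severe", "nonsevere")
      metrics[[r]] <- data.frame(
        repeat_ix = r,
        model = c("cnn", "svm"),
        rbind(as.data.frame(compute_metrics(tab$label2, lab_cnn)[1:5]),
              as.data.frame(compute_metrics(tab$label2, lab_svm)[1:5])))
      repeat_preds[[r]] <- list(p_cnn = p_cnn, p_svm = p_svm,
                                labels = tab$label2)
      cnn_fits[[r]] <- fold_fits
    }
    models <- cache_put("models", list(metrics = do.call(rbind, metrics),
                                       repeat_preds = repeat_preds,
                                       cnn_fits = cnn_fits))
  }

  # --- fusion ---------------------------------------------------------
  fusion <- fusion_sweep("weighted_average", config$fusion_weights,
                         models$repeat_preds, seed = config$seed)

  # --- saliency (mean-performing CNN repeat) --------------------------
  f1_cnn <- models$metrics$f1[models$metrics$model == "cnn"]
  rbest <- mean_performing_repeat(f1_cnn)
  preds <- models$repeat_preds[[rbest]]
  lab_cnn <- ifelse(preds$p_cnn >= 0.5, "severe", "nonsevere")
  correct <- which(lab_cnn == preds$labels)
  sal <- cache_get("saliency")
  if (is.null(sal)) {
    sal <- vector("list", length(scaled))
    for (i in correct) {
      f <- plan$outer[i, rbest]
      fit <- models$cnn_fits[[rbest]][[f]]
      m <- gradcampp(fit, scaled[[i]], target_class = lab_cnn[i])
      sal[[i]] <- rectify_and_normalize(m)
    }
    cache_put("saliency", sal)
  }

  # --- subtyping ------------------------------------------------------
  subtyping <- NULL
  if (!is.null(config$subtype)) {
    sev_ix <- correct[lab_cnn[correct] == "severe"]
    keep <- sev_ix[vapply(sal[sev_ix], function(m) m$normalized, logical(1))]
    maps <- t(vapply(sal[keep], function(m) as.vector(m$grid),
                     numeric(length(sal[[keep[1]]]$grid))))
    subtyping <- do.call(run_subtyping,
                         c(list(maps = maps, seed = config$seed),
                           config$subtype))
    subtyping$subject_ids <- tab$subject_id[keep]
  }

  results <- list(cohort_table = tab, plan = plan, plan_hash = phash,
                  metrics = models$metrics, fusion = fusion,
                  saliency = sal, mean_repeat = rbest,
                  subtyping = subtyping, config_hash = hash,
                  seed = config$seed)
  if (!is.null(config$output_dir)) {
    mt <- models$metrics
    mt$config_hash <- hash
    mt$seed <- config$seed
    write.csv(mt, file.path(config$output_dir, "metrics.csv"),
              row.names = FALSE)
  }
  results
}
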