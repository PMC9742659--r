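# Experiment orchestration: dataset splitting, the four-way strategy
# comparison, evaluation on the shared test studies, and report generation.

#' Split a centre's studies into train/validation/test
#'
#' Deterministic shuffled split. With the study-default fractions
#' (0.6, 0.2, 0.2) a 50-study centre yields 30/10/10 and six such centres
#' pool to 180/60 train/validation with 60 test studies.
#'
#' @param n_studies number of studies at the centre (or a `center_dataset`).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed split seed.
#' @return a `split_assignment`: disjoint index vectors `train`, `validation`,
#'   `test` covering `1:n_studies`.
#' @export
split_dataset <- function(n_studies, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (inherits(n_studies, "center_dataset"))
    n_studies <- length(n_studies$studies)
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9,
            n_studies >= 3)
  n_tr <- round(fractions[1] * n_studies)
  n_va <- round(fractions[2] * n_studies)
  n_te <- n_studies - n_tr - n_va
  if (min(n_tr, n_va, n_te) < 1)
    stop("fractions leave an empty split for ", n_studies, " studies")
  set.seed(seed)
  ord <- sample(n_studies)
  out <- list(train = sort(ord[seq_len(n_tr)]),
              validation = sort(ord[n_tr + seq_len(n_va)]),
              test = sort(ord[n_tr + n_va + seq_len(n_te)]))
  stopifnot(!anyDuplicated(unlist(out)), length(unlist(out)) == n_studies)
  structure(out, class = "split_assignment")
}

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run; all seeds are explicit and the
#' whole experiment is a pure function of this object.
#'
#' @param profiles list of [center_profile()]; default: the six heterogeneous
#'   built-in centres.
#' @param master_seed master seed for simulation, splitting and training.
#' @param strategies subset of `c("CB", "CZ", "FL_PL", "FL_SQ")`.
#' @param model_preset `"desk"` or `"full"`.
#' @param rounds,local_epochs,batch_size,optimizer,lr,weight_decay,aggregation_mode
#'   shared training schedule (see [strategy_config()]).
#' @param fractions train/validation/test split fractions.
#' @param target_size,target_spacing_mm common grid for training.
#' @param mask_tau evaluation mask threshold (normalized units).
#' @param hist_bins joint-histogram bins.
#' @param strategy_overrides named list of per-strategy overrides of the
#'   schedule fields (default `list(FL_PL = list(local_epochs = 2))`):
#'   parallel FL needs more local work per communication round than the
#'   sequential schedule to reach a comparable optimisation depth at a fixed
#'   round budget, because each round advances the global model by only one
#'   averaged local excursion.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(profiles = default_center_profiles(),
                              master_seed = 1L,
                              strategies = c("CB", "CZ", "FL_PL", "FL_SQ"),
                              model_preset = "desk", rounds = 20L,
                              local_epochs = 1L, batch_size = 5L,
                              optimizer = "adam", lr = 0.001,
                              weight_decay = 0.0001,
                              aggregation_mode = "parameter_average",
                              fractions = c(0.6, 0.2, 0.2),
                              target_size = 64L, target_spacing_mm = 3,
                              mask_tau = 0.01, hist_bins = 128L,
                              strategy_overrides = list(
                                FL_PL = list(local_epochs = 2L)),
                              out_dir = NULL) {
  stopifnot(length(profiles) >= 1,
            all(strategies %in% c("CB", "CZ", "FL_PL", "FL_SQ")))
  structure(list(profiles = profiles, master_seed = as.integer(master_seed),
                 strategies = strategies, model_preset = model_preset,
                 rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 batch_size = batch_size, optimizer = optimizer, lr = lr,
                 weight_decay = weight_decay,
                 aggregation_mode = aggregation_mode,
                 strategy_overrides = strategy_overrides,
                 fractions = fractions,
                 target_size = as.integer(target_size),
                 target_spacing_mm = target_spacing_mm, mask_tau = mask_tau,
                 hist_bins = as.integer(hist_bins), out_dir = out_dir),
            class = "experiment_config")
}

# Simulate + preprocess + split every centre. Returns per-centre lists of
# normalized slice pairs and the split assignment.
prepare_centers <- function(config) {
  tg <- grid_spec(spacing = rep(config$target_spacing_mm, 2),
                  size = rep(config$target_size, 2))
  lapply(config$profiles, function(pr) {
    ds <- generate_center_dataset(pr, config$master_seed)
    pp <- lapply(ds$studies, preprocess_study, target = tg)
    split <- split_dataset(length(pp), config$fractions,
                           seed = derive_seed(config$master_seed, "split",
                                              pr$center_id))
    list(profile = pr, prepped = pp, split = split,
         ids = vapply(ds$studies, function(s) s$study_id, ""))
  })
}

subset_xy <- function(center, idx) {
  list(X = lapply(center$prepped[idx], `[[`, "x"),
       Y = lapply(center$prepped[idx], `[[`, "y"),
       ids = center$ids[idx])
}

#' Run the full multi-centre comparison experiment
#'
#' Simulates (or reuses) the configured centres, preprocesses and splits
#' their studies, trains every requested strategy with the shared optimizer
#' recipe, evaluates each trained model on the shared test studies (CB models
#' additionally on all other centres' test sets, reported as `CB_cross`, to
#' quantify the generalizability loss), and assembles per-study metrics,
#' summary tables, pairwise statistics and joint-histogram analyses. Fully
#' reproducible from the config.
#'
#' The non-CB strategies are trained on the pooled training split and
#' evaluated on the pooled test studies; each CB model trains on one centre's
#' training split only. Model selection within a run takes the round with the
#' lowest pooled validation loss. Error metrics (ME, MAE, RE%, ARE%, PSNR)
#' are computed on SUV images with the body mask `reference > mask_tau`
#' (normalized units); SSIM is computed on the normalized 0-5 images with
#' dynamic range 5.
#'
#' @param config an [experiment_config()].
#' @return list with `metrics` (per study x strategy), `summary`,
#'   `stats_overall`, `stats_per_center`, `r2` (per-strategy joint-histogram
#'   analysis), `mean_are` (named vector incl. `CB_cross`), `history`,
#'   `config`.
#' @export
run_experiment <- function(config) {
  centers <- prepare_centers(config)
  asc_rule <- normalization_rule("ASC")
  mcfg <- u2net_config(config$model_preset)
  model <- u2net_model(mcfg)
  scfg <- function(strategy) {
    args <- list(strategy = strategy, rounds = config$rounds,
                 local_epochs = config$local_epochs,
                 batch_size = config$batch_size,
                 optimizer = config$optimizer, lr = config$lr,
                 weight_decay = config$weight_decay,
                 aggregation_mode = config$aggregation_mode)
    ov <- config$strategy_overrides[[strategy]]
    if (!is.null(ov)) args[names(ov)] <- ov
    do.call(strategy_config, args)
  }

  train_sets <- lapply(centers, function(ce) {
    xy <- subset_xy(ce, ce$split$train)
    local_dataset(ce$profile$center_id, xy$X, xy$Y)
  })
  val_pool <- list(
    X = do.call(c, lapply(centers, function(ce) subset_xy(ce, ce$split$validation)$X)),
    Y = do.call(c, lapply(centers, function(ce) subset_xy(ce, ce$split$validation)$Y)))
  tests <- lapply(centers, function(ce) subset_xy(ce, ce$split$test))
  names(tests) <- vapply(centers, function(ce) ce$profile$center_id, "")

  seed_tr <- derive_seed(config$master_seed, "train")
  states <- list()
  metrics <- list()
  history <- list()
  eval_model <- function(theta, test, strategy, center_lab) {
    preds <- model$predict(theta, test$X)
    rows <- lapply(seq_along(preds), function(i) {
      pred_n <- pmax(preds[[i]], 0)            # clip at inference export
      ref_n <- test$Y[[i]]
      pred_suv <- denormalize(pred_n, asc_rule)
      ref_suv <- denormalize(ref_n, asc_rule)
      r <- voxel_metrics(pred_suv, ref_suv,
                         mask = eval_mask(ref_n, config$mask_tau),
                         study_id = test$ids[i], strategy = strategy)
      r$SSIM <- ssim(pred_n, ref_n, L = 5)
      r$center_id <- center_lab[i]
      r$model_center <- NA_character_
      r
    })
    do.call(rbind, rows)
  }
  test_center_of <- function() unlist(lapply(names(tests), function(nm)
    rep(nm, length(tests[[nm]]$X))))
  pooled_test <- list(X = do.call(c, lapply(tests, `[[`, "X")),
                      Y = do.call(c, lapply(tests, `[[`, "Y")),
                      ids = do.call(c, lapply(tests, `[[`, "ids")))

  for (strat in intersect(config$strategies, c("CZ", "FL_PL", "FL_SQ"))) {
    st <- run_strategy(strat, train_sets, model, scfg(strat), seed = seed_tr,
                       validation = val_pool)
    states[[strat]] <- st
    history[[strat]] <- cbind(strategy = strat, st$history)
    metrics[[strat]] <- eval_model(st$best_theta, pooled_test, strat,
                                   test_center_of())
  }
  if ("CB" %in% config$strategies) {
    for (k in seq_along(centers)) {
      cid <- centers[[k]]$profile$center_id
      vxy <- subset_xy(centers[[k]], centers[[k]]$split$validation)
      st <- run_center_based(train_sets[[k]], model, scfg("CB"),
                             seed = derive_seed(seed_tr, "cb", cid),
                             validation = list(X = vxy$X, Y = vxy$Y))
      states[[paste0("CB_", cid)]] <- st
      history[[paste0("CB_", cid)]] <- cbind(strategy = paste0("CB_", cid),
                                             st$history)
      own <- tests[[cid]]
      metrics[[paste0("CB_own_", cid)]] <-
        eval_model(st$best_theta, own, "CB", rep(cid, length(own$X)))
      cross <- eval_model(st$best_theta, pooled_test, "CB_cross",
                          test_center_of())
      cross$model_center <- cid
      metrics[[paste0("CB_cross_", cid)]] <- cross
    }
  }
  metrics_df <- do.call(rbind, c(metrics, list(make.row.names = FALSE)))

  main <- metrics_df[metrics_df$strategy %in%
                       c("CB", "CZ", "FL_PL", "FL_SQ"), ]
  summary_df <- summarize_metrics(metrics_df)
  stats_overall <- if (length(unique(main$strategy)) >= 2)
    tryCatch(compare_strategies(main, grouping = "overall"),
             error = function(e) NULL) else NULL
  stats_per_center <- if (length(unique(main$strategy)) >= 2 &&
                          "CB" %in% main$strategy)
    tryCatch(compare_strategies(main, grouping = "per_center"),
             error = function(e) NULL) else NULL

  r2 <- list()
  for (strat in intersect(config$strategies, c("CZ", "FL_PL", "FL_SQ"))) {
    preds <- model$predict(states[[strat]]$best_theta, pooled_test$X)
    preds <- lapply(preds, pmax, 0)
    r2[[strat]] <- joint_histogram_r2(preds, pooled_test$Y,
                                      tau = config$mask_tau,
                                      bins = config$hist_bins)
  }

  mean_are <- vapply(split(metrics_df$ARE_pct, metrics_df$strategy), mean, 0)
  out <- list(metrics = metrics_df, summary = summary_df,
              stats_overall = stats_overall,
              stats_per_center = stats_per_center,
              r2 = lapply(r2, function(z) z[c("r_squared", "slope",
                                              "intercept", "n_voxels")]),
              mean_are = mean_are,
              history = do.call(rbind, c(history, list(make.row.names = FALSE))),
              config = config)
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

# Serialise experiment artifacts: per-study metrics, summaries, statistics and
# a machine-readable summary JSON.
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(result$stats_overall))
    utils::write.csv(result$stats_overall, file.path(dir, "stats_overall.csv"),
                     row.names = FALSE)
  if (!is.null(result$stats_per_center))
    utils::write.csv(result$stats_per_center,
                     file.path(dir, "stats_per_center.csv"), row.names = FALSE)
  utils::write.csv(result$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  cfg <- result$config
  cfg$profiles <- lapply(cfg$profiles, unclass)
  jsonlite::write_json(
    list(mean_are_pct = as.list(result$mean_are),
         r2 = result$r2,
         config = unclass(cfg)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; centre
#' profiles are given as a list of mappings under `profiles` with the
#' arguments of [center_profile()].
#'
#' @param path YAML file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- if (!is.null(y$profiles))
    lapply(y$profiles, function(p) do.call(center_profile, p))
  else default_center_profiles(n_studies = y$n_studies %||% 50L)
  args <- y[setdiff(names(y), c("profiles", "n_studies"))]
  do.call(experiment_config, c(list(profiles = profiles), args))
}
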