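#' Derive documented risk events from ground-truth stages and weather
#'
#' Applies the alert rules to the *true* stage timeline (instead of model
#' predictions): rain-damage events at true-flowering intervals whose
#' rainfall exceeds the threshold, pest-outbreak events in the true
#' pre-veraison window under warm-humid conditions. These synthetic event
#' records play the role of independently documented incidents when scoring
#' model-issued alerts.
#'
#' @param dataset A \code{vp_dataset}.
#' @param rain_threshold Collection-level rainfall threshold (mm).
#' @param rules A \code{\link{risk_rule_config}}.
#' @return Data frame: site_id, event_type, doy, confidence.
#' @export
documented_events <- function(dataset, rain_threshold,
                              rules = risk_rule_config()) {
  ev <- lapply(dataset, function(s) {
    true_stages <- as.character(s$timeline$stage_per_interval)
    rain <- detect_rain_risk(true_stages, s$biweekly_rain, rain_threshold,
                             s$season_start_doy, s$site_id)
    ver <- s$timeline$onset_doy["veraison"]
    pest <- detect_pest_risk(if (is.na(ver)) NA else ver, s$daily_temp,
                             s$daily_rh, rules, s$season_start_doy, s$site_id)
    rbind(
      if (nrow(rain)) data.frame(site_id = rain$site_id,
                                 event_type = "rain_damage", doy = rain$doy,
                                 confidence = "high"),
      if (nrow(pest)) data.frame(site_id = pest$site_id,
                                 event_type = "pest_outbreak", doy = pest$doy,
                                 confidence = "high"))
  })
  out <- do.call(rbind, ev)
  if (is.null(out)) {
    out <- data.frame(site_id = character(0), event_type = character(0),
                      doy = integer(0), confidence = character(0))
  }
  out
}

#' Model-issued alerts for a collection
#'
#' Runs per-interval stage prediction for every site, then the rain and pest
#' rules on the predictions.
#'
#' @param model A trained \code{vp_model}.
#' @param dataset Imputed \code{vp_dataset}.
#' @param norm_params Normalization parameters from training.
#' @param rain_threshold Collection-level rainfall threshold (mm).
#' @param rules A \code{\link{risk_rule_config}}.
#' @return List: \code{alerts} (data frame), \code{predictions} (per-site
#'   per-interval data frame), \code{pred_onsets} (site_id, stage,
#'   onset_doy).
#' @export
issue_alerts <- function(model, dataset, norm_params, rain_threshold,
                         rules = risk_rule_config()) {
  alerts <- list(); preds <- list(); onsets <- list()
  for (s in dataset) {
    pr <- predict_stages(model, s, norm_params)
    on <- transitions_from_stages(pr$stage_pred, s$season_start_doy)
    rain <- detect_rain_risk(pr$stage_pred, s$biweekly_rain, rain_threshold,
                             s$season_start_doy, s$site_id)
    ver <- if ("veraison" %in% names(on)) on[["veraison"]] else NA
    pest <- detect_pest_risk(ver, s$daily_temp, s$daily_rh, rules,
                             s$season_start_doy, s$site_id)
    alerts[[length(alerts) + 1L]] <-
      rbind(rain[c("site_id", "alert_type", "doy", "stage_context")],
            pest[c("site_id", "alert_type", "doy", "stage_context")])
    preds[[length(preds) + 1L]] <- pr
    if (length(on)) {
      onsets[[length(onsets) + 1L]] <-
        data.frame(site_id = s$site_id, stage = names(on),
                   onset_doy = unname(on))
    }
  }
  list(alerts = do.call(rbind, alerts),
       predictions = do.call(rbind, preds),
       pred_onsets = do.call(rbind, onsets))
}

#' Scaled-down end-to-end pipeline
#'
#' Simulates a multi-site season, preprocesses it, tunes hyperparameters
#' with the dream optimizer on a proxy objective, trains the classifier,
#' predicts held-out sites, issues risk alerts and scores everything. The
#' default problem sizes (400 sites, population 10, 20 optimizer iterations,
#' compact network) are chosen for desk-scale runs; see the methods
#' vignette.
#'
#' @param n_sites Number of simulated sites.
#' @param seed Integer master seed.
#' @param clean If TRUE, simulate without spikes or gaps.
#' @param spec Network architecture.
#' @param ado_N,ado_Tmax Tuning population and iterations.
#' @param proxy_epochs Epochs per tuning evaluation.
#' @param tune_sites Training/validation sites used in the tuning subsample.
#' @param intervals_per_site Labeled intervals sampled per site for training.
#' @param verbose Print progress.
#' @return List with metrics, tuned hyperparameters, the model and the
#'   intermediate artifacts.
#' @export
run_pipeline <- function(n_sites = 400L, seed = 42L, clean = TRUE,
                         spec = compact_network_spec(), ado_N = 10L,
                         ado_Tmax = 20L, proxy_epochs = 3L,
                         tune_sites = 60L, intervals_per_site = 8L,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulating ", n_sites, " sites")
  ds <- if (clean) {
    simulate_dataset(n_sites, seed = seed, cloud_rate = 0,
                     gap_mix = rep(0, 5), gap_affected_rate = 0)
  } else simulate_dataset(n_sites, seed = seed)

  splits <- make_splits(ds, split_plan(seed = derive_seed(seed, 2L)))
  train_ids <- splits$site_id[splits$set == "train"]
  test_ids <- splits$site_id[splits$set == "test"]
  # fold 1 of the training portion serves as the validation split
  val_ids <- splits$site_id[splits$set == "train" & splits$fold == 1L]
  fit_ids <- setdiff(train_ids, val_ids)

  say("preprocessing")
  ids <- vapply(ds, `[[`, "", "site_id")
  pp_train <- preprocess_dataset(ds[ids %in% fit_ids])
  norm <- pp_train$norm_params
  pp_val <- preprocess_dataset(ds[ids %in% val_ids], norm_params = norm)
  pp_test <- preprocess_dataset(ds[ids %in% test_ids], norm_params = norm)

  tr <- dataset_to_samples(pp_train$dataset, norm, intervals_per_site,
                           derive_seed(seed, 3L))
  va <- dataset_to_samples(pp_val$dataset, norm, intervals_per_site,
                           derive_seed(seed, 4L))
  te <- dataset_to_samples(pp_test$dataset, norm, Inf)

  say("tuning (N=", ado_N, ", Tmax=", ado_Tmax, ")")
  sub <- function(smp, sites) {
    keep <- smp$site_id %in% sites
    list(X = smp$X[keep, , drop = FALSE], y = smp$y[keep],
         site_id = smp$site_id[keep], interval = smp$interval[keep],
         zone = smp$zone[keep])
  }
  tune_tr <- sub(tr, utils::head(unique(tr$site_id), tune_sites))
  tune_va <- sub(va, utils::head(unique(va$site_id), max(10L, tune_sites %/% 2L)))
  tuned <- tune_hyperparameters(
    tune_tr, tune_va,
    ado_config(N = ado_N, Tmax = ado_Tmax, seed = derive_seed(seed, 5L)),
    proxy_epochs = proxy_epochs, spec = spec)
  theta <- tuned$theta
  say("tuned: lr=", signif(theta$learning_rate, 3), " batch=",
      theta$batch_size, " dropout=", round(theta$dropout, 2), " k=",
      theta$kernel_size, " epochs=", theta$epochs)

  say("final training (", theta$epochs, " epochs)")
  fit <- train_model(tr, va, theta, loss_config(), spec,
                     seed = derive_seed(seed, 6L), verbose = verbose)

  say("predicting ", length(pp_test$dataset), " test sites")
  rules <- risk_rule_config()
  rain_thr <- rain_threshold_from(pp_test$dataset, rules$rain_percentile)
  out <- issue_alerts(fit$model, pp_test$dataset, norm, rain_thr, rules)

  # interval-stage accuracy over intervals with a true phenological label
  truth <- do.call(rbind, lapply(pp_test$dataset, function(s) {
    data.frame(site_id = s$site_id, interval = seq_len(N_INTERVALS),
               stage_true = as.character(s$timeline$stage_per_interval))
  }))
  joined <- merge(out$predictions, truth, by = c("site_id", "interval"))
  labeled <- joined[joined$stage_true != "pre_season", ]
  sm <- stage_metrics(labeled$stage_pred, labeled$stage_true)

  true_onsets <- do.call(rbind, lapply(pp_test$dataset, function(s) {
    od <- s$timeline$onset_doy
    if (!length(od)) return(NULL)
    data.frame(site_id = s$site_id, stage = names(od), onset_doy = unname(od))
  }))
  tm <- timing_mae(out$pred_onsets, true_onsets)

  events <- documented_events(pp_test$dataset, rain_thr, rules)
  matches <- match_events(out$alerts, events)
  am <- lapply(seq_len(nrow(matches)), function(i) {
    c(type = matches$type[i],
      alert_metrics(matches$TP[i], matches$FN[i], matches$FP[i]))
  })

  list(stage_metrics = sm, timing = tm, alerts = out$alerts,
       pred_onsets = out$pred_onsets,
       events = events, event_matching = matches, alert_metrics = am,
       theta = theta, model = fit$model, history = fit$history,
       norm_params = norm, splits = splits,
       n_test_sites = length(pp_test$dataset))
}
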