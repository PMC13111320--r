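#' Split plan
#'
#' @param train_fraction Fraction of sites in the training portion (0.70).
#' @param n_folds Cross-validation folds over the training portion (5).
#' @param seed Integer seed.
#' @return A \code{split_plan} list.
#' @export
split_plan <- function(train_fraction = 0.70, n_folds = 5L, seed = 42L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_folds >= 2)
  structure(list(train_fraction = train_fraction,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "split_plan")
}

#' Zone-stratified, site-grouped train/test split and CV folds
#'
#' Sites (not samples) are assigned, so no site ever spans train and test or
#' two folds. Within each zone, a shuffled \code{train_fraction} goes to the
#' training portion; the held-out rest is the test set. The five folds
#' partition the training portion, round-robin within zone so fold zone
#' mixes track the plan. Deterministic under the plan seed.
#'
#' @param dataset A \code{vp_dataset}.
#' @param plan A \code{\link{split_plan}}.
#' @return Data frame: site_id, zone, set ("train"/"test"), fold (NA for
#'   test sites).
#' @export
make_splits <- function(dataset, plan = split_plan()) {
  set.seed(plan$seed)
  site_id <- vapply(dataset, `[[`, "", "site_id")
  zone <- vapply(dataset, `[[`, "", "zone")
  out <- data.frame(site_id = site_id, zone = zone,
                    set = NA_character_, fold = NA_integer_,
                    stringsAsFactors = FALSE)
  for (z in unique(zone)) {
    idx <- which(zone == z)
    if (length(idx) < plan$n_folds) {
      vp_stop("zone '", z, "' has fewer sites than folds")
    }
    idx <- idx[sample.int(length(idx))]
    n_tr <- round(plan$train_fraction * length(idx))
    tr <- idx[seq_len(n_tr)]
    out$set[tr] <- "train"
    out$set[idx[-seq_len(n_tr)]] <- "test"
    out$fold[tr] <- rep_len(seq_len(plan$n_folds), length(tr))
  }
  out
}

#' Classification metrics over the four stages
#'
#' @param pred,true Character vectors of stage labels.
#' @return List: \code{accuracy_pct}, \code{macro_f1}, \code{per_class}
#'   (precision/recall/F1/support), \code{confusion} (counts) and
#'   \code{confusion_pct} (row-normalized percentages).
#' @export
stage_metrics <- function(pred, true) {
  if (!all(pred %in% STAGES) || !all(true %in% STAGES)) {
    vp_stop("labels must be one of: ", paste(STAGES, collapse = ", "))
  }
  cm <- table(factor(true, levels = STAGES), factor(pred, levels = STAGES))
  cm <- matrix(as.numeric(cm), 4, 4, dimnames = list(STAGES, STAGES))
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy_pct = 100 * sum(tp) / sum(cm),
       macro_f1 = mean(f1),
       per_class = data.frame(stage = STAGES, precision = prec,
                              recall = rec, f1 = f1, support = support),
       confusion = cm,
       confusion_pct = 100 * cm / pmax(1, support))
}

#' Mean absolute timing error over matched stage onsets
#'
#' @param pred,true Data frames with columns site_id, stage, onset_doy.
#' @return List: \code{mae_days}, \code{median_abs_days}, \code{n_matched},
#'   \code{n_unmatched} (pairs present in only one input).
#' @export
timing_mae <- function(pred, true) {
  m <- merge(pred, true, by = c("site_id", "stage"),
             suffixes = c("_pred", "_true"))
  if (!nrow(m)) vp_stop("no matched (site, stage) onset pairs")
  err <- abs(m$onset_doy_pred - m$onset_doy_true)
  n_un <- (nrow(pred) - nrow(m)) + (nrow(true) - nrow(m))
  list(mae_days = mean(err), median_abs_days = stats::median(err),
       n_matched = nrow(m), n_unmatched = n_un, errors = err)
}

#' Percentile bootstrap confidence interval of a mean
#'
#' @param x Per-sample metric contributions.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Integer seed (deterministic).
#' @param level Confidence level (default 0.95).
#' @return List: \code{lower}, \code{upper}, \code{estimate}, \code{B}.
#' @export
bootstrap_ci <- function(x, B = 1000L, seed = 1L, level = 0.95) {
  if (length(x) < 2) vp_stop("need at least 2 observations")
  if (B < 100) vp_stop("B must be >= 100")
  set.seed(as.integer(seed))
  n <- length(x)
  means <- vapply(seq_len(B), function(b) mean(x[sample.int(n, replace = TRUE)]),
                  numeric(1))
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lower = qs[1], upper = qs[2], estimate = mean(x), B = as.integer(B))
}

#' Paired two-tailed t-test between fold-level metrics
#'
#' Classical paired t-test at \code{alpha} (default 0.01). Degenerate cases:
#' all differences zero gives t = 0, p = 1, not significant; constant
#' non-zero differences give an infinite statistic reported with p = 0 and a
#' \code{degenerate} flag.
#'
#' @param a,b Equal-length numeric vectors of per-fold metrics.
#' @param alpha Significance level.
#' @return List: \code{t}, \code{p}, \code{significant}, \code{degenerate}.
#' @export
compare_models_ttest <- function(a, b, alpha = 0.01) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, significant = FALSE, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, significant = TRUE,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, degenerate = FALSE)
}

# column indices of one feature (1 = ndvi, 2 = evi, 3 = rain) in a flattened
# row-major 26 x 3 sample matrix
feature_columns <- function(feature, input_h = N_INTERVALS, input_w = 3L) {
  seq.int(feature, input_h * input_w, by = input_w)
}

#' Permutation importance of a pseudo-image feature column
#'
#' Accuracy drop when one feature's column is shuffled across test samples
#' (the whole per-sample column block moves as a unit), averaged over
#' \code{n_repeats} shuffles.
#'
#' @param model A trained \code{vp_model}.
#' @param X,y Test samples (\code{\link{dataset_to_samples}} layout).
#' @param feature 1 (NDVI), 2 (EVI) or 3 (rainfall).
#' @param n_repeats Number of shuffles.
#' @param seed Integer seed.
#' @return List: \code{delta_accuracy} (baseline minus mean permuted),
#'   \code{baseline_accuracy}, \code{permuted_accuracy} (per repeat).
#' @export
permutation_importance <- function(model, X, y, feature, n_repeats = 5L,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  cols <- feature_columns(feature, model$spec$input_h, model$spec$input_w)
  base <- eval_on(model, X, y, loss_config(mode = "plain_ce"))$accuracy
  perm <- vapply(seq_len(n_repeats), function(r) {
    Xp <- X
    Xp[, cols] <- X[sample.int(nrow(X)), cols]
    eval_on(model, Xp, y, loss_config(mode = "plain_ce"))$accuracy
  }, numeric(1))
  list(delta_accuracy = base - mean(perm), baseline_accuracy = base,
       permuted_accuracy = perm)
}

# pool a flattened 26 x 3 causal sample matrix to 13 x 3: NDVI/EVI rows by
# mean, rainfall by sum renormalized through a doubled range (equivalent to
# the mean on the normalized scale); the trailing half-filled pooled row of
# an odd cutoff keeps the single observed interval's value
pool_rows_13 <- function(X, intervals) {
  n <- nrow(X)
  out <- matrix(0, n, 13L * 3L)
  for (i in seq_len(13L)) {
    r1 <- (2L * i - 2L) * 3L
    r2 <- (2L * i - 1L) * 3L
    o <- (i - 1L) * 3L
    both <- intervals >= 2L * i
    one <- intervals == 2L * i - 1L
    for (f in 1:3) {
      v <- numeric(n)
      v[both] <- (X[both, r1 + f] + X[both, r2 + f]) / 2
      v[one] <- X[one, r1 + f]
      out[, o + f] <- v
    }
  }
  out
}

#' Component ablation grid
#'
#' Trains and evaluates the 2 x 2 x 2 variant grid {hyperparameters: tuned
#' vs default; resolution: 26 vs 13 pooled rows; features: with vs without
#' rainfall} under a shared seed and reports one summary row per variant.
#'
#' @param train,val,test Sample lists (\code{\link{dataset_to_samples}}).
#' @param theta_tuned Tuned hyperparameters (e.g. from
#'   \code{\link{tune_hyperparameters}}).
#' @param theta_default Untuned defaults used by the "default" arm.
#' @param spec A \code{\link{network_spec}} (its \code{input_h} is adjusted
#'   for the 13-row arm).
#' @param loss_cfg A \code{\link{loss_config}}.
#' @param seed Integer seed.
#' @param epochs Optional epoch override for all arms (scaled-down runs).
#' @return Data frame: hyperparams, rows, rainfall, accuracy_pct, macro_f1.
#' @export
run_ablation <- function(train, val, test, theta_tuned,
                         theta_default = list(learning_rate = 1e-3,
                                              batch_size = 64L,
                                              dropout = 0.45,
                                              kernel_size = 3L,
                                              epochs = 50L),
                         spec = compact_network_spec(),
                         loss_cfg = loss_config(), seed = 42L,
                         epochs = NULL) {
  variants <- expand.grid(hyperparams = c("tuned", "default"),
                          rows = c(26L, 13L), rainfall = c(TRUE, FALSE),
                          stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(variants)), function(vi) {
    v <- variants[vi, ]
    theta <- if (v$hyperparams == "tuned") theta_tuned else theta_default
    tr <- train; va <- val; te <- test
    sp <- spec
    if (!v$rainfall) {
      rc <- feature_columns(3L)
      tr$X[, rc] <- 0; va$X[, rc] <- 0; te$X[, rc] <- 0
    }
    if (v$rows == 13L) {
      tr$X <- pool_rows_13(tr$X, tr$interval)
      va$X <- pool_rows_13(va$X, va$interval)
      te$X <- pool_rows_13(te$X, te$interval)
      sp$input_h <- 13L
    }
    fit <- train_model(tr, va, theta, loss_cfg, sp, seed = seed,
                       epochs = epochs)
    ev <- eval_on(fit$model, te$X, te$y, loss_config(mode = "plain_ce"))
    sm <- stage_metrics(STAGES[ev$pred], STAGES[te$y])
    data.frame(hyperparams = v$hyperparams, rows = v$rows,
               rainfall = v$rainfall, accuracy_pct = sm$accuracy_pct,
               macro_f1 = sm$macro_f1)
  })
  do.call(rbind, res)
}
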