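#' Assemble labeled training samples from a preprocessed dataset
#'
#' One sample per (site, interval): the causal pseudo-image up to interval t
#' flattened row-major, labeled with the GDD-derived stage at t. Pre-season
#' intervals are dropped (the classifier learns the four phenological
#' stages). Optionally subsamples intervals per site to bound the sample
#' count.
#'
#' @param dataset Imputed \code{vp_dataset}.
#' @param norm_params A \code{normalization_params}.
#' @param intervals_per_site If finite, number of labeled intervals sampled
#'   per site (without replacement); Inf keeps all.
#' @param seed Seed for the interval subsample.
#' @return List: \code{X} (n x 78 matrix), \code{y} (integer 1..4),
#'   \code{site_id}, \code{interval}, \code{zone}.
#' @export
dataset_to_samples <- function(dataset, norm_params,
                               intervals_per_site = Inf, seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list(); ys <- list(); sid <- list(); itv <- list(); zn <- list()
  for (s in dataset) {
    lab <- as.integer(s$timeline$stage_per_interval) - 1L  # 0 = pre_season
    use <- which(lab >= 1L)
    if (!length(use)) next
    if (is.finite(intervals_per_site) && length(use) > intervals_per_site) {
      use <- sort(sample(use, intervals_per_site))
    }
    m <- vapply(use, function(t) {
      as.vector(t(build_pseudo_image(s, t, norm_params)))
    }, numeric(N_INTERVALS * 3L))
    rows[[length(rows) + 1L]] <- t(m)
    ys[[length(ys) + 1L]] <- lab[use]
    sid[[length(sid) + 1L]] <- rep(s$site_id, length(use))
    itv[[length(itv) + 1L]] <- use
    zn[[length(zn) + 1L]] <- rep(s$zone, length(use))
  }
  list(X = do.call(rbind, rows), y = unlist(ys),
       site_id = unlist(sid), interval = unlist(itv), zone = unlist(zn))
}

onehot_of <- function(y, nc = 4L) {
  Z <- matrix(0, length(y), nc)
  Z[cbind(seq_along(y), y)] <- 1
  Z
}

confusion_counts <- function(true, pred, nc = 4L) {
  tab <- table(factor(true, levels = seq_len(nc)),
               factor(pred, levels = seq_len(nc)))
  matrix(as.numeric(tab), nc, nc)
}

eval_on <- function(model, X, y, cfg, batch = 256L) {
  n <- nrow(X)
  probs <- matrix(NA_real_, n, 4L)
  for (b in seq(1L, n, by = batch)) {
    idx <- b:min(n, b + batch - 1L)
    probs[idx, ] <- model_probs(model, X[idx, , drop = FALSE])
  }
  pred <- max.col(probs, ties.method = "first")
  list(loss = compute_loss(probs, onehot_of(y), cfg),
       accuracy = mean(pred == y),
       confusion = confusion_counts(y, pred),
       pred = pred, probs = probs)
}

#' Train the stage classifier
#'
#' Minibatch Adam on the selected loss. With an adaptive weighted loss the
#' class-weight vector is recomputed after every epoch from the validation
#' confusion (per-class recall). Deterministic under \code{seed}.
#'
#' @param train List from \code{\link{dataset_to_samples}} (training sites).
#' @param val List from \code{\link{dataset_to_samples}} (validation sites;
#'   disjoint site ids).
#' @param theta Hyperparameters: \code{learning_rate}, \code{batch_size},
#'   \code{dropout}, \code{kernel_size}, \code{epochs} (see
#'   \code{\link{decode_position}}).
#' @param loss_cfg A \code{\link{loss_config}}.
#' @param spec A \code{\link{network_spec}}.
#' @param seed Integer seed.
#' @param epochs Override for \code{theta$epochs} (e.g. a proxy run).
#' @param verbose Print per-epoch progress.
#' @return List: \code{model}, \code{history} (data frame with epoch,
#'   train_loss, val_loss, val_accuracy, per-class recall and weights),
#'   \code{loss_cfg} (final weights), \code{theta}.
#' @export
train_model <- function(train, val, theta, loss_cfg = loss_config(),
                        spec = compact_network_spec(), seed = 42L,
                        epochs = NULL, verbose = FALSE) {
  missing_cls <- setdiff(seq_len(4L), unique(train$y))
  if (length(missing_cls)) {
    vp_stop("training set has no samples of class: ",
            paste(STAGES[missing_cls], collapse = ", "))
  }
  set.seed(as.integer(seed))
  model <- build_network(spec, dropout = theta$dropout,
                         kernel_size = theta$kernel_size,
                         seed = derive_seed(seed, 1L))
  opt <- adam_init(model)
  n <- nrow(train$X)
  n_epochs <- epochs %||% theta$epochs
  batch <- min(theta$batch_size, n)
  cw_state <- NULL
  step <- 0L
  hist <- vector("list", n_epochs)

  for (ep in seq_len(n_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b in seq(1L, n, by = batch)) {
      idx <- ord[b:min(n, b + batch - 1L)]
      Xb <- train$X[idx, , drop = FALSE]
      Z <- onehot_of(train$y[idx])
      B <- nrow(Xb)
      A <- matrix(as.vector(t(Xb)), ncol = 1)
      fw <- nn_forward(model, A, B, training = TRUE)
      model <- fw$model  # batch-norm running stats
      probs <- softmax_rows(fw$out)
      ep_loss <- ep_loss + compute_loss(probs, Z, loss_cfg); nb <- nb + 1L
      dlogits <- loss_grad_logits(probs, Z, loss_cfg)
      grads <- nn_backward(model, fw$caches, dlogits)
      step <- step + 1L
      upd <- adam_step(model, grads, opt, theta$learning_rate, step)
      model <- upd$model; opt <- upd$opt
    }
    vl <- eval_on(model, val$X, val$y, loss_cfg)
    if (loss_cfg$mode == "weighted_ce" && isTRUE(loss_cfg$adaptive)) {
      cw_state <- update_class_weights(vl$confusion,
                                       loss_cfg$weight_mapping, cw_state)
      loss_cfg$weights <- cw_state$weights
    }
    rec <- if (!is.null(cw_state)) cw_state$recall else {
      sup <- rowSums(vl$confusion)
      ifelse(sup > 0, diag(vl$confusion) / sup, NA_real_)
    }
    hist[[ep]] <- data.frame(
      epoch = ep, train_loss = ep_loss / nb, val_loss = vl$loss,
      val_accuracy = vl$accuracy,
      t(stats::setNames(rec, paste0("recall_", STAGES))),
      t(stats::setNames(loss_cfg$weights, paste0("w_", STAGES))))
    if (verbose) {
      message(sprintf("epoch %d train %.4f val %.4f acc %.3f", ep,
                      ep_loss / nb, vl$loss, vl$accuracy))
    }
  }
  list(model = model, history = do.call(rbind, hist),
       loss_cfg = loss_cfg, theta = theta)
}

#' Tune hyperparameters with the augmented dream optimizer
#'
#' The tuning objective is the validation loss of a short proxy training run
#' (reduced epochs) at the decoded hyperparameters; full epochs are reserved
#' for the final fit.
#'
#' @param train,val Sample lists (\code{\link{dataset_to_samples}}).
#' @param cfg An \code{\link{ado_config}} (e.g. N = 10, Tmax = 20).
#' @param proxy_epochs Epochs per tuning evaluation.
#' @param loss_cfg A \code{\link{loss_config}}.
#' @param spec A \code{\link{network_spec}}.
#' @return List: \code{theta} (decoded best), \code{result} (raw
#'   \code{\link{ado_optimize}} output).
#' @export
tune_hyperparameters <- function(train, val, cfg, proxy_epochs = 3L,
                                 loss_cfg = loss_config(),
                                 spec = compact_network_spec()) {
  space <- hyper_space()
  objective <- function(pos) {
    theta <- decode_position(pos, space)
    fit <- train_model(train, val, theta, loss_cfg, spec,
                       seed = derive_seed(cfg$seed, 7L),
                       epochs = proxy_epochs)
    utils::tail(fit$history$val_loss, 1L)
  }
  res <- ado_optimize(objective, space, cfg)
  list(theta = decode_position(res$best, space), result = res)
}
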