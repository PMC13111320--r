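#' Loss configuration
#'
#' Three losses over the 4-way softmax output: plain categorical
#' cross-entropy, weighted cross-entropy (class weight vector summing to 1;
#' the loss scales weights by the class count so that uniform weights
#' reproduce the plain loss exactly), and focal loss with modulating factor
#' \code{(1 - S)^alpha}. Adaptive weighting recomputes the weight vector
#' every epoch from per-class error rates through a monotone mapping
#' (exponential by default).
#'
#' @param mode One of \code{"plain_ce"}, \code{"weighted_ce"},
#'   \code{"focal"}.
#' @param weights Class weight 4-vector summing to 1 (weighted mode).
#' @param adaptive If TRUE, weights are recomputed per epoch from the
#'   validation confusion.
#' @param weight_mapping Name of the error-to-weight mapping:
#'   \code{"identity"}, \code{"cube"}, \code{"exp"} (default),
#'   \code{"exp100"}, \code{"ten_y"}.
#' @param focal_exponent Focusing exponent alpha >= 0 (focal mode; 0 reduces
#'   to plain cross-entropy).
#' @return A \code{loss_config} list.
#' @export
loss_config <- function(mode = c("weighted_ce", "plain_ce", "focal"),
                        weights = rep(0.25, 4), adaptive = TRUE,
                        weight_mapping = "exp", focal_exponent = 2.0) {
  mode <- match.arg(mode)
  if (abs(sum(weights) - 1) > 1e-8) vp_stop("class weights must sum to 1")
  if (focal_exponent < 0) vp_stop("focal_exponent must be >= 0")
  structure(list(mode = mode, weights = weights, adaptive = adaptive,
                 weight_mapping = weight_mapping,
                 focal_exponent = focal_exponent),
            class = "loss_config")
}

weight_mappings <- list(
  identity = function(y) y,
  cube = function(y) y^3,
  exp = function(y) exp(y),
  exp100 = function(y) exp(100 * y),
  ten_y = function(y) 10^y
)

#' Mean loss of a batch
#'
#' @param probs n x 4 matrix of predicted class probabilities.
#' @param onehot n x 4 one-hot label matrix.
#' @param cfg A \code{\link{loss_config}}.
#' @return Scalar mean loss (probabilities clamped at 1e-12 before the log).
#' @export
compute_loss <- function(probs, onehot, cfg = loss_config()) {
  stopifnot(ncol(probs) == ncol(onehot), nrow(probs) == nrow(onehot))
  p_true <- rowSums(probs * onehot)
  lp <- log(pmax(p_true, 1e-12))
  nc <- ncol(probs)
  loss_i <- switch(cfg$mode,
    plain_ce = -lp,
    weighted_ce = {
      w_true <- as.vector(onehot %*% (nc * cfg$weights))
      -w_true * lp
    },
    focal = -(1 - p_true)^cfg$focal_exponent * lp
  )
  mean(loss_i)
}

# gradient of the mean loss wrt logits (n x 4)
loss_grad_logits <- function(probs, onehot, cfg) {
  n <- nrow(probs)
  nc <- ncol(probs)
  switch(cfg$mode,
    plain_ce = (probs - onehot) / n,
    weighted_ce = {
      w_true <- as.vector(onehot %*% (nc * cfg$weights))
      (probs - onehot) * w_true / n
    },
    focal = {
      # L = -(1 - p_t)^a log(p_t); chain rule through the softmax gives
      # dL/dz_j = dL/dp_t * p_t * (1[j = t] - p_j)
      a <- cfg$focal_exponent
      pt <- pmax(rowSums(probs * onehot), 1e-12)
      q <- pmax(1 - pt, 0)
      dLdp <- ifelse(q > 0 & a > 0, a * q^(a - 1) * log(pt), 0) - q^a / pt
      (dLdp * pt) * (onehot - probs) / n
    }
  )
}

#' Update adaptive class weights from a confusion matrix
#'
#' Per-class error rate \code{Mr_j = 1 - recall_j} (recall on the validation
#' split); weights \code{w_j = alpha(Mr_j) / sum_i alpha(Mr_i)} for a
#' monotone mapping alpha. A class absent from the epoch keeps its previous
#' recall (carry-forward).
#'
#' @param confusion 4 x 4 count matrix, rows = true class, cols = predicted.
#' @param mapping Mapping name (see \code{\link{loss_config}}).
#' @param prev Optional previous \code{class_weight_state} for carry-forward.
#' @return A \code{class_weight_state}: \code{recall}, \code{error_rate},
#'   \code{weights} (summing to 1).
#' @export
update_class_weights <- function(confusion, mapping = "exp", prev = NULL) {
  stopifnot(nrow(confusion) == ncol(confusion))
  nc <- nrow(confusion)
  support <- rowSums(confusion)
  recall <- ifelse(support > 0, diag(confusion) / support, NA_real_)
  if (anyNA(recall)) {
    carry <- if (!is.null(prev)) prev$recall else rep(1, nc)
    recall[is.na(recall)] <- carry[is.na(recall)]
  }
  mr <- 1 - recall
  f <- weight_mappings[[mapping]]
  if (is.null(f)) vp_stop("unknown weight mapping: ", mapping)
  a <- f(mr)
  structure(list(recall = recall, error_rate = mr, weights = a / sum(a)),
            class = "class_weight_state")
}
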