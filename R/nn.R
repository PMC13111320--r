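# CNN engine for pseudo-image classification.
#
# Activations are stored as (batch * positions) x channels matrices, with
# positions in row-major (h, w) order within each sample. Convolutions
# gather patch rows through precomputed index maps (im2col) so the channel
# mixing reduces to BLAS matrix products; the memory-bound steps (gather,
# scatter, depthwise convolution, batch-norm, clipped rectifier) run in
# compiled kernels. Every layer implements an explicit backward pass,
# verified against numerical gradients in the test suite.

# index map for a kh x kw kernel over an H x W grid, stride sh along rows
# ('same' padding); entries are input positions, 0 marks padding
make_gather <- function(H, W, kh, kw, sh) {
  out_h <- as.integer(ceiling(H / sh))
  pad_total <- max((out_h - 1L) * sh + kh - H, 0L)
  pad_top <- pad_total %/% 2L
  pad_left <- (kw - 1L) %/% 2L
  K <- kh * kw
  idx <- matrix(0L, out_h * W, K)
  k <- 0L
  for (di in 0:(kh - 1L)) {
    for (dj in 0:(kw - 1L)) {
      k <- k + 1L
      for (oh in seq_len(out_h)) {
        ih <- (oh - 1L) * sh + di + 1L - pad_top
        for (ow in seq_len(W)) {
          iw <- ow + dj - pad_left
          p_out <- (oh - 1L) * W + ow
          if (ih >= 1L && ih <= H && iw >= 1L && iw <= W) {
            idx[p_out, k] <- (ih - 1L) * W + iw
          }
        }
      }
    }
  }
  list(idx = idx, P_in = H * W, P_out = out_h * W,
       out_h = out_h, out_w = W, K = K,
       key = paste("g", H, W, kh, kw, sh, sep = "_"))
}

# batch-expanded gather maps are cached per (layer geometry, batch size)
.gather_cache <- new.env(parent = emptyenv())

batch_gather <- function(g, B) {
  key <- paste0(g$key, "_B", B)
  G <- .gather_cache[[key]]
  if (is.null(G)) {
    G <- cpp_expand_gather(g$idx, B, g$P_in)
    .gather_cache[[key]] <- G
  }
  G
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

layer_conv <- function(g, cin, cout, use_bias = FALSE) {
  list(type = "conv", g = g, cin = cin, cout = cout,
       W = he_init(g$K * cin, cout, g$K * cin),
       b = if (use_bias) numeric(cout) else NULL)
}

layer_conv1x1 <- function(cin, cout) {
  list(type = "conv1x1", cin = cin, cout = cout,
       W = he_init(cin, cout, cin))
}

layer_dwconv <- function(g, c) {
  list(type = "dwconv", g = g, c = c,
       W = matrix(stats::rnorm(g$K * c, sd = sqrt(2 / g$K)), g$K, c))
}

layer_bn <- function(c, momentum = 0.9, eps = 1e-5, act = FALSE) {
  list(type = if (act) "bnact" else "bn", c = c,
       gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c),
       momentum = momentum, eps = eps)
}

layer_relu6 <- function() list(type = "relu6")
layer_gap <- function(P) list(type = "gap", P = P)
layer_dense <- function(cin, cout) {
  list(type = "dense", W = he_init(cin, cout, cin), b = numeric(cout))
}
layer_dropout <- function(p) list(type = "dropout", p = p)
layer_save <- function(id) list(type = "save", id = id)
layer_add <- function(id) list(type = "add", id = id)

nn_forward <- function(model, A, B, training = FALSE) {
  layers <- model$layers
  caches <- vector("list", length(layers))
  saved <- list()
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    switch(L$type,
      conv = {
        G <- batch_gather(L$g, B)
        patches <- cpp_gather_patches(A, G)
        out <- patches %*% L$W
        if (!is.null(L$b)) out <- out + rep(L$b, rep.int(nrow(out), L$cout))
        caches[[li]] <- list(patches = patches, G = G, n_in = nrow(A))
        A <- out
      },
      conv1x1 = {
        caches[[li]] <- list(A = A)
        A <- A %*% L$W
      },
      dwconv = {
        G <- batch_gather(L$g, B)
        caches[[li]] <- list(A = A, G = G, n_in = nrow(A))
        A <- cpp_dwconv_fwd(A, G, L$W)
      },
      bn = ,
      bnact = {
        fused <- L$type == "bnact"
        if (training) {
          mu <- colMeans(A)
          va <- colMeans(A * A) - mu * mu
          va[va < 0] <- 0
          inv_sd <- 1 / sqrt(va + L$eps)
          r <- if (fused) cpp_bnact_fwd(A, mu, inv_sd, L$gamma, L$beta)
               else cpp_bn_fwd(A, mu, inv_sd, L$gamma, L$beta)
          model$layers[[li]]$run_mean <-
            L$momentum * L$run_mean + (1 - L$momentum) * mu
          model$layers[[li]]$run_var <-
            L$momentum * L$run_var + (1 - L$momentum) * va
          caches[[li]] <- list(xhat = r$xhat, inv_sd = inv_sd,
                               out = if (fused) r$y)
          A <- r$y
        } else {
          inv_sd <- 1 / sqrt(L$run_var + L$eps)
          sc <- L$gamma * inv_sd
          sh <- L$beta - L$run_mean * sc
          A <- if (fused) cpp_affine_relu6(A, sc, sh)
               else cpp_col_affine(A, sc, sh)
        }
      },
      relu6 = {
        A <- cpp_relu6_fwd(A)
        caches[[li]] <- list(out = A)
      },
      gap = {
        grp <- rep(seq_len(B), each = L$P)
        A <- rowsum(A, grp) / L$P
      },
      dense = {
        caches[[li]] <- list(A = A)
        A <- A %*% L$W + rep(L$b, rep.int(nrow(A), ncol(L$W)))
      },
      dropout = {
        if (training && L$p > 0) {
          mask <- (matrix(stats::runif(length(A)), nrow(A)) >= L$p) / (1 - L$p)
          caches[[li]] <- list(mask = mask)
          A <- A * mask
        } else caches[[li]] <- list(mask = NULL)
      },
      save = {
        saved[[L$id]] <- A
      },
      add = {
        A <- A + saved[[L$id]]
      }
    )
  }
  list(out = A, caches = caches, model = model)
}

nn_backward <- function(model, caches, dA) {
  layers <- model$layers
  grads <- vector("list", length(layers))
  saved_grads <- list()
  for (li in rev(seq_along(layers))) {
    L <- layers[[li]]
    cc <- caches[[li]]
    switch(L$type,
      conv = {
        g <- list(W = crossprod(cc$patches, dA))
        if (!is.null(L$b)) g$b <- colSums(dA)
        dpatch <- tcrossprod(dA, L$W)
        grads[[li]] <- g
        dA <- cpp_scatter_patches(dpatch, cc$G, cc$n_in, L$cin)
      },
      conv1x1 = {
        grads[[li]] <- list(W = crossprod(cc$A, dA))
        dA <- tcrossprod(dA, L$W)
      },
      dwconv = {
        r <- cpp_dwconv_bwd(cc$A, cc$G, L$W, dA, cc$n_in)
        grads[[li]] <- list(W = r$W)
        dA <- r$dA
      },
      bn = {
        r <- cpp_bn_bwd(dA, cc$xhat, L$gamma, cc$inv_sd)
        grads[[li]] <- list(gamma = r$dgamma, beta = r$dbeta)
        dA <- r$dA
      },
      bnact = {
        r <- cpp_bnact_bwd(dA, cc$out, cc$xhat, L$gamma, cc$inv_sd)
        grads[[li]] <- list(gamma = r$dgamma, beta = r$dbeta)
        dA <- r$dA
      },
      relu6 = {
        dA <- cpp_relu6_bwd(dA, cc$out)
      },
      gap = {
        dA <- dA[rep(seq_len(nrow(dA)), each = L$P), , drop = FALSE] / L$P
      },
      dense = {
        grads[[li]] <- list(W = crossprod(cc$A, dA), b = colSums(dA))
        dA <- tcrossprod(dA, L$W)
      },
      dropout = {
        if (!is.null(cc$mask)) dA <- dA * cc$mask
      },
      save = {
        if (!is.null(saved_grads[[L$id]])) {
          dA <- dA + saved_grads[[L$id]]
        }
      },
      add = {
        saved_grads[[L$id]] <- dA
      }
    )
  }
  grads
}

# parameter fields by layer type (those updated by the optimizer)
param_fields <- function(type) {
  switch(type,
    conv = c("W", "b"), conv1x1 = "W", dwconv = "W",
    bn = c("gamma", "beta"), bnact = c("gamma", "beta"),
    dense = c("W", "b"),
    character(0))
}

adam_init <- function(model) {
  lapply(model$layers, function(L) {
    fs <- param_fields(L$type)
    fs <- fs[!vapply(fs, function(f) is.null(L[[f]]), logical(1))]
    stats::setNames(lapply(fs, function(f) {
      list(m = L[[f]] * 0, v = L[[f]] * 0)
    }), fs)
  })
}

adam_step <- function(model, grads, opt, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^step
  corr2 <- 1 - beta2^step
  for (li in seq_along(model$layers)) {
    st <- opt[[li]]
    if (!length(st)) next
    for (f in names(st)) {
      gr <- grads[[li]][[f]]
      if (is.null(gr)) next
      st[[f]]$m <- beta1 * st[[f]]$m + (1 - beta1) * gr
      st[[f]]$v <- beta2 * st[[f]]$v + (1 - beta2) * gr * gr
      mhat <- st[[f]]$m / corr1
      vhat <- st[[f]]$v / corr2
      model$layers[[li]][[f]] <- model$layers[[li]][[f]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
    opt[[li]] <- st
  }
  list(model = model, opt = opt)
}
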