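#' Bounded search space for the dream optimizer
#'
#' @param lower,upper Numeric vectors of per-dimension bounds (upper must
#'   strictly exceed lower).
#' @param scale Per-dimension scale, \code{"linear"} or \code{"log10"}
#'   (log10 requires positive lower bounds; the optimizer then works on the
#'   log of the bounds).
#' @param names Optional dimension names.
#' @return A \code{search_space} list with fields \code{lower}, \code{upper}
#'   on the search scale, \code{scale} and \code{dim}.
#' @export
search_space <- function(lower, upper, scale = NULL, names = NULL) {
  stopifnot(length(lower) == length(upper))
  if (any(upper <= lower)) vp_stop("upper bound must exceed lower in every dimension")
  if (is.null(scale)) scale <- rep("linear", length(lower))
  lo <- lower; up <- upper
  logd <- scale == "log10"
  if (any(logd & lower <= 0)) vp_stop("log10 scale requires positive lower bounds")
  lo[logd] <- log10(lower[logd])
  up[logd] <- log10(upper[logd])
  structure(list(lower = lo, upper = up, scale = scale,
                 dim = length(lower), names = names),
            class = "search_space")
}

#' Dream-optimizer configuration
#'
#' Defaults follow the published parameter settings: exploration for the
#' first \code{floor(0.9 * Tmax)} iterations with five static groups, a 0.9
#' probability of the forgetting/supplementing move versus dream-sharing, and
#' a PSO blend with weight \code{alpha = 0.6} toward the dream-optimizer
#' proposal, acceleration coefficients \code{gamma1 = gamma2 = 2} and inertia
#' \code{w = 0.7}.
#'
#' @param N Population size (>= \code{n_groups}).
#' @param Tmax Total iterations (>= 2).
#' @param u Probability of forgetting/supplementing vs dream-sharing.
#' @param n_groups Number of exploration groups (5).
#' @param alpha Blend weight on the dream-optimizer proposal (1 = PSO off).
#' @param gamma1,gamma2 PSO cognitive/social coefficients.
#' @param inertia PSO inertia weight.
#' @param paper_pso If TRUE, drop the uniform random multipliers r1, r2 from
#'   the velocity update (the published update prints none; the default
#'   keeps the conventional stochastic PSO form).
#' @param seed Integer seed.
#' @return An \code{ado_config} list (with \code{Td = floor(0.9 * Tmax)}).
#' @export
ado_config <- function(N = 30L, Tmax = 300L, u = 0.9, n_groups = 5L,
                       alpha = 0.6, gamma1 = 2, gamma2 = 2, inertia = 0.7,
                       paper_pso = FALSE, seed = 1L) {
  if (Tmax < 2) vp_stop("Tmax must be >= 2")
  if (N < n_groups) vp_stop("population must be at least as large as n_groups")
  if (u < 0 || u > 1 || alpha < 0 || alpha > 1) {
    vp_stop("u and alpha must be in [0, 1]")
  }
  Td <- floor(0.9 * Tmax)
  if (Td < 1 || Td >= Tmax) Td <- max(1L, min(Tmax - 1L, Td))
  structure(list(N = as.integer(N), Tmax = as.integer(Tmax),
                 Td = as.integer(Td), u = u, n_groups = as.integer(n_groups),
                 alpha = alpha, gamma1 = gamma1, gamma2 = gamma2,
                 inertia = inertia, paper_pso = paper_pso,
                 seed = as.integer(seed)),
            class = "ado_config")
}

#' Number of forgotten dimensions during exploration
#'
#' \code{k_q = randi(ceil(Dim/(8q)), max(2, ceil(Dim/(3q))))}, clamped so the
#' lower bound never exceeds the upper and the count stays in [1, Dim].
#'
#' @param q Group index 1..5.
#' @param dim Problem dimensionality.
#' @return Integer count of dimensions to forget.
#' @export
forget_count_exploration <- function(q, dim) {
  lo <- ceiling(dim / (8 * q))
  hi <- max(2, ceiling(dim / (3 * q)))
  lo <- min(lo, hi)
  min(dim, max(1L, randi(lo, hi)))
}

#' Number of forgotten dimensions during exploitation
#'
#' \code{k_r = randi(2, max(2, ceil(Dim/3)))}, clamped to [1, Dim].
#'
#' @param dim Problem dimensionality.
#' @return Integer count of dimensions to forget.
#' @export
forget_count_exploitation <- function(dim) {
  hi <- max(2, ceiling(dim / 3))
  min(dim, max(1L, randi(2, hi)))
}

# cosine decay factors for the forgetting/supplementing perturbation
exploration_factor <- function(t, Tmax, Td) {
  0.5 * (cos(pi * (t + Tmax - Td) / Tmax) + 1)
}
exploitation_factor <- function(t, Tmax) {
  0.5 * (cos(pi * t / Tmax) + 1)
}

#' Repair an out-of-bounds position
#'
#' Low-dimensional problems (Dim <= 15) resample each violating coordinate
#' uniformly within its bounds; higher-dimensional problems copy the
#' coordinate from a uniformly chosen other agent (whose coordinates are in
#' bounds by induction).
#'
#' @param pos Numeric position vector.
#' @param space A \code{\link{search_space}}.
#' @param population Matrix N x Dim of current agent positions.
#' @param i Index of the agent being repaired.
#' @return In-bounds position vector.
#' @export
enforce_bounds <- function(pos, space, population, i) {
  bad <- which(pos < space$lower | pos > space$upper)
  if (!length(bad)) return(pos)
  if (space$dim <= 15) {
    pos[bad] <- space$lower[bad] +
      stats::runif(length(bad)) * (space$upper[bad] - space$lower[bad])
  } else {
    others <- setdiff(seq_len(nrow(population)), i)
    for (j in bad) {
      m <- others[randi(1L, length(others))]
      pos[j] <- population[m, j]
    }
    # copied values are in bounds by induction, but guard numerically
    pos <- pmin(space$upper, pmax(space$lower, pos))
  }
  pos
}

# PSO-blended candidate for agent i: alpha * DOA proposal + (1-alpha) * (x + v)
pso_blend <- function(doa_pos, x, v, pbest, gbest, cfg) {
  if (cfg$paper_pso) {
    r1 <- 1; r2 <- 1
  } else {
    r1 <- stats::runif(length(x)); r2 <- stats::runif(length(x))
  }
  v_new <- cfg$inertia * v + cfg$gamma1 * r1 * (pbest - x) +
    cfg$gamma2 * r2 * (gbest - x)
  list(pos = cfg$alpha * doa_pos + (1 - cfg$alpha) * (x + v_new),
       vel = v_new)
}

# evaluate objective, mapping non-finite results to +Inf
safe_eval <- function(objective, pos) {
  f <- tryCatch(objective(pos), error = function(e) Inf)
  if (!is.finite(f)) Inf else f
}

#' Initialize the dream-optimizer state
#'
#' Uniform positions \code{X = Xl + rand * (Xu - Xl)} on the search scale,
#' round-robin assignment into five groups, zero velocities, and initial
#' best bookkeeping.
#'
#' @param objective Function mapping a position vector to a scalar cost.
#' @param space A \code{\link{search_space}}.
#' @param cfg An \code{\link{ado_config}}.
#' @return An \code{ado_state} list.
#' @export
initialize_population <- function(objective, space, cfg) {
  X <- matrix(stats::runif(cfg$N * space$dim), cfg$N, space$dim)
  X <- sweep(sweep(X, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
  fit <- apply(X, 1, function(p) safe_eval(objective, p))
  groups <- rep(seq_len(cfg$n_groups), length.out = cfg$N)

  gb_idx <- which.min(fit)
  group_best <- lapply(seq_len(cfg$n_groups), function(q) {
    idx <- which(groups == q)
    b <- idx[which.min(fit[idx])]
    list(pos = X[b, ], fit = fit[b])
  })
  structure(list(
    t = 0L, X = X, V = matrix(0, cfg$N, space$dim), fit = fit,
    groups = groups,
    pbest = X, pbest_fit = fit,
    group_best = group_best,
    gbest = X[gb_idx, ], gbest_fit = fit[gb_idx],
    history = numeric(0)
  ), class = "ado_state")
}

# one iteration; phase chosen by t < Td
ado_iterate <- function(state, objective, space, cfg) {
  t <- state$t
  explore <- t < cfg$Td
  dim <- space$dim
  k_r <- if (!explore) forget_count_exploitation(dim) else NA_integer_

  for (i in seq_len(cfg$N)) {
    if (explore) {
      q <- state$groups[i]
      base <- state$group_best[[q]]$pos          # memory reset to group best
      k <- forget_count_exploration(q, dim)
      fac <- exploration_factor(t, cfg$Tmax, cfg$Td)
    } else {
      base <- state$gbest                        # memory reset to global best
      k <- k_r
      fac <- exploitation_factor(t, cfg$Tmax)
    }
    pos <- base
    K <- if (k >= dim) seq_len(dim) else sample.int(dim, k)
    for (j in K) {
      if (explore && stats::runif(1) >= cfg$u) {
        # dream-sharing: copy coordinate from a random agent (not self);
        # agents already updated this iteration contribute their new value
        m <- i
        while (m == i) m <- randi(1L, cfg$N)
        pos[j] <- state$X[m, j]
      } else {
        pos[j] <- base[j] +
          (space$lower[j] + stats::runif(1) *
             (space$upper[j] - space$lower[j])) * fac
      }
    }
    bl <- pso_blend(pos, state$X[i, ], state$V[i, ],
                    state$pbest[i, ], state$gbest, cfg)
    newpos <- enforce_bounds(bl$pos, space, state$X, i)
    f <- safe_eval(objective, newpos)

    state$X[i, ] <- newpos
    state$V[i, ] <- bl$vel
    state$fit[i] <- f
    if (f < state$pbest_fit[i]) {
      state$pbest[i, ] <- newpos; state$pbest_fit[i] <- f
    }
    if (explore) {
      q <- state$groups[i]
      if (f < state$group_best[[q]]$fit) {
        state$group_best[[q]] <- list(pos = newpos, fit = f)
      }
    }
    if (f < state$gbest_fit) {
      state$gbest <- newpos; state$gbest_fit <- f
    }
  }
  state$t <- t + 1L
  state$history <- c(state$history, state$gbest_fit)
  state
}

#' Run the augmented dream optimizer
#'
#' Minimizes \code{objective} over the box: \code{Td = floor(0.9 Tmax)}
#' exploration iterations (group memory, forgetting/supplementing with a
#' cosine-decayed uniform perturbation, dream-sharing with probability
#' \code{1 - u}) followed by exploitation iterations (global-best memory, no
#' dream-sharing), with every proposal blended against a PSO velocity update.
#' The best-so-far history is monotone non-increasing and the run is
#' deterministic under \code{cfg$seed}.
#'
#' @param objective Function position -> scalar cost (non-finite values are
#'   treated as +Inf and the run continues).
#' @param space A \code{\link{search_space}}.
#' @param cfg An \code{\link{ado_config}}.
#' @return List: \code{best} (position on the search scale), \code{value}
#'   (best cost), \code{history} (best cost per iteration), \code{state}.
#' @export
ado_optimize <- function(objective, space, cfg = ado_config()) {
  set.seed(cfg$seed)
  state <- initialize_population(objective, space, cfg)
  for (t in seq_len(cfg$Tmax)) {
    state <- ado_iterate(state, objective, space, cfg)
  }
  list(best = state$gbest, value = state$gbest_fit,
       history = state$history, state = state)
}
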