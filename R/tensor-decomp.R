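#' Stack a synchronized dataset into a space x time x subject tensor
#'
#' @param dataset A \code{\link{grayordinate_dataset}}.
#' @param synced Must be \code{TRUE}: the low-rank model assumes temporally
#'   synchronized subjects and does not work well on asynchronous data, so
#'   stacking unsynchronized data is refused.
#' @return An object of class \code{data_tensor} whose \code{values} is a
#'   3-way array with axes (space, time, subject), slice \code{s} being
#'   subject \code{s}'s matrix; spatial metadata is copied from the dataset.
#' @export
build_tensor <- function(dataset, synced) {
  stopifnot(inherits(dataset, "grayordinate_dataset"))
  if (!isTRUE(synced)) {
    stop(paste(
      "refusing to build a tensor from unsynchronized data: the low-rank",
      "model assumes temporal synchrony across subjects (run",
      "group_brainsync() first and pass synced = TRUE)"
    ))
  }
  v <- n_space(dataset)
  t_len <- n_time(dataset)
  s <- n_subjects(dataset)
  vals <- array(0, dim = c(v, t_len, s))
  for (i in seq_len(s)) vals[, , i] <- dataset$subjects[[i]]
  structure(
    list(
      values = vals,
      cortical_index = dataset$cortical_index,
      subcortical_index = dataset$subcortical_index,
      subcortical_grid_coords = dataset$subcortical_grid_coords,
      grid_dims = dataset$grid_dims,
      subject_ids = dataset$subject_ids
    ),
    class = "data_tensor"
  )
}

#' Optimizer settings for \code{\link{nascar_decompose}}
#'
#' Nadam (Nesterov-accelerated adaptive moment estimation) hyperparameters
#' plus the plateau policy: when the best objective has not improved for
#' \code{patience} iterations the step size is multiplied by \code{decay}
#' and the parameters are reset to the best iterate seen (adaptive-moment
#' methods do not descend monotonically, so the running best is tracked and
#' returned); optimization at a given rank stops when the step size falls
#' below \code{min_step_frac} of its initial value or \code{max_iter} is
#' reached.
#'
#' @param step_size Initial Nadam step size.
#' @param beta1,beta2 First/second moment decay rates.
#' @param eps Adaptive-denominator stabilizer.
#' @param max_iter Maximum iterations per rank.
#' @param tol Relative objective-improvement threshold that counts as
#'   progress.
#' @param patience Iterations without progress before a step-size decay.
#' @param decay Multiplicative step-size decay factor.
#' @param min_step_frac Stop once the step size is below this fraction of
#'   \code{step_size}.
#' @param init_starts Number of random starts for the new-component
#'   initialization at each rank. Rank-1 power iteration on a tensor has
#'   basins of attraction around every component (unlike the matrix case),
#'   so several seeded starts are refined and the one capturing the most
#'   residual energy is kept.
#' @param init_iters Alternating power iterations per initialization start.
#' @return List of settings.
#' @export
nascar_opts <- function(step_size = 1e-2, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, max_iter = 1000L, tol = 1e-6,
                        patience = 25L, decay = 0.5, min_step_frac = 1e-3,
                        init_starts = 8L, init_iters = 10L) {
  list(
    step_size = step_size, beta1 = beta1, beta2 = beta2, eps = eps,
    max_iter = as.integer(max_iter), tol = tol,
    patience = as.integer(patience), decay = decay,
    min_step_frac = min_step_frac,
    init_starts = as.integer(init_starts),
    init_iters = as.integer(init_iters)
  )
}

# Khatri-Rao (columnwise Kronecker) product: rows of B vary fastest.
khatri_rao <- function(a, b) {
  a[rep(seq_len(nrow(a)), each = nrow(b)), , drop = FALSE] *
    b[rep(seq_len(nrow(b)), times = nrow(a)), , drop = FALSE]
}

# Jointly optimize all current factor columns with Nadam; returns the best
# iterate and the best-so-far objective trace (logged every iteration).
nascar_optimize_rank <- function(x1, x2, x3, xnorm2, a, b, c_, opts) {
  v <- nrow(a); t_len <- nrow(b); s <- nrow(c_)
  lr <- opts$step_size
  ma <- va <- a * 0; mb <- vb <- b * 0; mc <- vc <- c_ * 0
  tt <- 0
  best <- NULL
  best_loss <- Inf
  trace <- numeric(0)
  stall <- 0L
  blow <- 0L
  for (it in seq_len(opts$max_iter)) {
    ga_g <- crossprod(a); gb_g <- crossprod(b); gc_g <- crossprod(c_)
    g1 <- x1 %*% khatri_rao(c_, b)
    g2 <- x2 %*% khatri_rao(c_, a)
    g3 <- x3 %*% khatri_rao(b, a)
    inner <- sum(a * g1)
    model2 <- sum(ga_g * gb_g * gc_g)
    loss <- xnorm2 - 2 * inner + model2
    if (!is.finite(loss)) {
      stop("tensor decomposition diverged (non-finite objective); ",
           "reduce step_size in nascar_opts()")
    }
    if (loss < best_loss) {
      improved <- (best_loss - loss) > opts$tol * (best_loss + 1e-12 * xnorm2)
      best_loss <- loss
      best <- list(a = a, b = b, c = c_)
      stall <- if (improved) 0L else stall + 1L
      blow <- 0L
    } else {
      stall <- stall + 1L
      blow <- if (loss > 100 * max(best_loss, 1e-12 * xnorm2)) blow + 1L else 0L
    }
    trace <- c(trace, best_loss)
    if (blow > 50L) {
      stop("tensor decomposition diverged (objective grew for 50 consecutive ",
           "iterations); reduce step_size in nascar_opts()")
    }
    if (stall >= opts$patience) {
      lr <- lr * opts$decay
      a <- best$a; b <- best$b; c_ <- best$c
      ma <- va <- a * 0; mb <- vb <- b * 0; mc <- vc <- c_ * 0
      tt <- 0
      stall <- 0L
      if (lr < opts$step_size * opts$min_step_frac) break
      next
    }
    grad_a <- 2 * (a %*% (gb_g * gc_g) - g1)
    grad_b <- 2 * (b %*% (ga_g * gc_g) - g2)
    grad_c <- 2 * (c_ %*% (ga_g * gb_g) - g3)
    tt <- tt + 1
    b1 <- opts$beta1; b2 <- opts$beta2
    nadam <- function(theta, m, v_, g) {
      m <- b1 * m + (1 - b1) * g
      v_ <- b2 * v_ + (1 - b2) * g * g
      mhat <- m / (1 - b1^(tt + 1))
      vhat <- v_ / (1 - b2^tt)
      step <- lr * (b1 * mhat + (1 - b1) * g / (1 - b1^tt)) /
        (sqrt(vhat) + opts$eps)
      list(theta = theta - step, m = m, v = v_)
    }
    ua <- nadam(a, ma, va, grad_a); a <- ua$theta; ma <- ua$m; va <- ua$v
    ub <- nadam(b, mb, vb, grad_b); b <- ub$theta; mb <- ub$m; vb <- ub$v
    uc <- nadam(c_, mc, vc, grad_c); c_ <- uc$theta; mc <- uc$m; vc <- uc$v
  }
  list(a = best$a, b = best$b, c = best$c, loss = best_loss, trace = trace)
}

#' Rank-incremental CP decomposition with Nadam updates
#'
#' Fits the canonical polyadic (CP) model
#' \deqn{X \approx \sum_{r=1}^R \lambda_r\, a_r \circ b_r \circ c_r}
#' to a space x time x subject tensor by minimizing the squared
#' reconstruction error with full-gradient Nadam updates on all factor
#' entries, using rank-incremental warm starts: the rank-1 problem is solved
#' first, and for each \code{r} in \code{2..R} the first \code{r - 1}
#' components are initialized from the rank-\code{(r - 1)} solution while the
#' new component is initialized randomly (seeded) at small scale, after which
#' all \code{r} components are jointly re-optimized. The warm start makes
#' the solution robust to initialization; the fresh component is the only
#' random part. After convergence at each rank, factors are renormalized to
#' unit norm with the scale folded into \code{lambda}, the sign convention
#' (largest-magnitude spatial entry positive) is applied, and components are
#' sorted by descending \code{lambda}.
#'
#' Internally the space axis is reordered into a canonical, data-derived
#' ordering before any computation and restored afterwards, so permuting the
#' vertices/voxels before decomposition and un-permuting the spatial factors
#' afterwards yields bit-identical results at a fixed seed: the spatial
#' patterns found cannot be an artifact of voxel ordering.
#'
#' @param tensor A \code{\link{build_tensor}} result.
#' @param rank Number of components \code{R} (the conventional choice for
#'   full-scale group fMRI analyses is \code{R = 30}, a deliberate
#'   over-estimate of the number of networks; small ranks around 5--8 are
#'   typically sufficient to recover the dominant networks).
#' @param opts Optimizer settings from \code{\link{nascar_opts}}.
#' @param seed Integer seed for the random component initializations.
#' @return An object of class \code{cp_decomposition}: list of
#'   \code{network_component}s (each with \code{magnitude}, unit-norm
#'   \code{spatial}, \code{temporal} and \code{subject} factors) sorted by
#'   descending magnitude, plus \code{fit_history} (per-rank final relative
#'   error, non-increasing in rank), \code{conv_trace} (per-rank best-so-far
#'   objective traces), \code{rank_requested} and \code{seed}.
#' @export
nascar_decompose <- function(tensor, rank, opts = nascar_opts(), seed = 1L) {
  stopifnot(inherits(tensor, "data_tensor"))
  x <- tensor$values
  if (anyNA(x)) stop("tensor contains NA/NaN values")
  dm <- dim(x)
  v <- dm[1]; t_len <- dm[2]; s <- dm[3]
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be >= 1")
  if (rank >= min(v * t_len, t_len * s, v * s)) {
    stop("rank too large for tensor dimensions")
  }

  # canonical space ordering (see Details)
  x1_raw <- matrix(x, v, t_len * s)
  ord <- canonical_row_order(x1_raw)
  x1 <- x1_raw[ord, , drop = FALSE]
  xp <- array(x1, dim = c(v, t_len, s))
  x2 <- matrix(aperm(xp, c(2, 1, 3)), t_len, v * s)
  x3 <- matrix(aperm(xp, c(3, 1, 2)), s, v * t_len)
  xnorm2 <- sum(x1^2)

  set.seed(seed)
  unit <- function(n) {
    z <- stats::rnorm(n)
    z / sqrt(sum(z^2))
  }
  # New-component initialization: seeded random unit starts for the temporal
  # and subject factors, each refined by a few alternating power iterations
  # against the current residual. Rank-1 power iteration on a tensor is only
  # locally convergent (each component has a basin of attraction), so
  # several starts are refined and the one capturing the most residual
  # energy is kept — deterministic given the seed, and equivariant under
  # space-axis permutation because the spatial factor is derived from the
  # data rather than drawn.
  init_component <- function(a, b, c_) {
    nrm <- function(z) {
      n <- sqrt(sum(z^2))
      if (n < 1e-300) z else z / n
    }
    refine <- function(bn, cn) {
      an <- NULL
      for (k in seq_len(opts$init_iters)) {
        an <- drop(x1 %*% as.vector(outer(bn, cn)))
        if (!is.null(a)) an <- an - drop(a %*% (crossprod(b, bn) * crossprod(c_, cn)))
        an <- nrm(an)
        bn2 <- drop(x2 %*% as.vector(outer(an, cn)))
        if (!is.null(a)) bn2 <- bn2 - drop(b %*% (crossprod(a, an) * crossprod(c_, cn)))
        bn <- nrm(bn2)
        cn2 <- drop(x3 %*% as.vector(outer(an, bn)))
        if (!is.null(a)) cn2 <- cn2 - drop(c_ %*% (crossprod(a, an) * crossprod(b, bn)))
        cn <- nrm(cn2)
      }
      lam0 <- sum(an * drop(x1 %*% as.vector(outer(bn, cn))))
      if (!is.null(a)) {
        lam0 <- lam0 - sum(an * drop(a %*% (crossprod(b, bn) * crossprod(c_, cn))))
      }
      if (lam0 < 0) {
        an <- -an
        lam0 <- -lam0
      }
      list(a = an, b = bn, c = cn, lam0 = lam0)
    }
    best <- NULL
    for (m in seq_len(max(1L, opts$init_starts))) {
      cand <- refine(unit(t_len), unit(s))
      if (is.null(best) || cand$lam0 > best$lam0) best <- cand
    }
    sc <- max(best$lam0, 1e-8 * sqrt(xnorm2))^(1 / 3)
    list(a = best$a * sc, b = best$b * sc, c = best$c * sc)
  }

  a <- b <- c_ <- NULL
  fit_history <- numeric(0)
  conv_trace <- list()
  for (r in seq_len(rank)) {
    ini <- init_component(a, b, c_)
    a <- cbind(a, ini$a)
    b <- cbind(b, ini$b)
    c_ <- cbind(c_, ini$c)
    fit <- nascar_optimize_rank(x1, x2, x3, xnorm2, a, b, c_, opts)
    a <- fit$a; b <- fit$b; c_ <- fit$c
    fit_history <- c(fit_history, sqrt(max(fit$loss, 0) / xnorm2))
    conv_trace[[r]] <- fit$trace
  }

  # normalize, sign-fix, sort; restore the input space ordering
  inv <- integer(v)
  inv[ord] <- seq_len(v)
  lambda <- numeric(rank)
  comps <- vector("list", rank)
  for (r in seq_len(rank)) {
    na_ <- sqrt(sum(a[, r]^2)); nb <- sqrt(sum(b[, r]^2)); nc_ <- sqrt(sum(c_[, r]^2))
    lam <- na_ * nb * nc_
    if (!(lam > .Machine$double.eps * (xnorm2 + 1))) {
      # degenerate (e.g. zero tensor): keep unit-norm placeholder factors
      av <- c(1, rep(0, v - 1)); bv <- c(1, rep(0, t_len - 1)); cv <- c(1, rep(0, s - 1))
      lam <- 0
    } else {
      av <- a[, r] / na_; bv <- b[, r] / nb; cv <- c_[, r] / nc_
    }
    imax <- which.max(abs(av))
    if (av[imax] < 0) {
      av <- -av
      bv <- -bv
    }
    lambda[r] <- lam
    comps[[r]] <- structure(
      list(magnitude = lam, spatial = av[inv], temporal = bv, subject = cv),
      class = "network_component"
    )
  }
  o <- order(-lambda)
  structure(
    list(
      components = comps[o],
      lambda = lambda[o],
      rank_requested = rank,
      fit_history = fit_history,
      conv_trace = conv_trace,
      seed = as.integer(seed)
    ),
    class = "cp_decomposition"
  )
}

#' @export
print.cp_decomposition <- function(x, ...) {
  cat(sprintf(
    "cp_decomposition: %d components, lambda = %s, final relative error = %.4g\n",
    length(x$components),
    paste(sprintf("%.3g", x$lambda), collapse = ", "),
    utils::tail(x$fit_history, 1)
  ))
  invisible(x)
}

# Factor matrices (spatial V x R, temporal T x R, subject S x R) from either
# a cp_decomposition or a synthetic_ground_truth.
factor_matrices <- function(x) {
  if (inherits(x, "cp_decomposition")) {
    list(
      spatial = vapply(x$components, `[[`, numeric(length(x$components[[1]]$spatial)), "spatial"),
      temporal = vapply(x$components, `[[`, numeric(length(x$components[[1]]$temporal)), "temporal"),
      subject = vapply(x$components, `[[`, numeric(length(x$components[[1]]$subject)), "subject"),
      lambda = x$lambda
    )
  } else if (inherits(x, "synthetic_ground_truth")) {
    list(
      spatial = x$spatial_maps,
      temporal = x$temporal_courses,
      subject = x$subject_loadings,
      lambda = x$magnitudes
    )
  } else {
    stop("cannot extract factor matrices from object of class ", class(x)[1])
  }
}

#' Match estimated components to ground-truth networks
#'
#' Greedy one-to-one assignment between estimated and true components,
#' maximizing the product over the three modes of the absolute cosine
#' similarity (the congruence coefficient). CP components are sign
#' indeterminate (any two modes of a component may be jointly negated), so
#' congruences are reported as absolute values and a per-match sign is
#' returned that makes the matched spatial cosine nonnegative.
#'
#' @param estimated A \code{\link{cp_decomposition}}.
#' @param truth A \code{synthetic_ground_truth} (or another decomposition);
#'   the estimated rank must be at least the number of true networks.
#' @return Data frame with one row per true component: estimated index,
#'   per-mode congruences, their product, and the spatial sign flip applied.
#' @export
match_components <- function(estimated, truth) {
  fe <- factor_matrices(estimated)
  ft <- factor_matrices(truth)
  re <- ncol(fe$spatial)
  rt <- ncol(ft$spatial)
  if (re < rt) stop("estimated rank must be >= number of true components")
  cosm <- function(a, b) {
    crossprod(a, b) / outer(sqrt(colSums(a^2)), sqrt(colSums(b^2)))
  }
  cs <- cosm(fe$spatial, ft$spatial)
  ct <- cosm(fe$temporal, ft$temporal)
  cu <- cosm(fe$subject, ft$subject)
  score <- abs(cs) * abs(ct) * abs(cu)
  est_of <- integer(rt)
  avail_e <- rep(TRUE, re)
  avail_t <- rep(TRUE, rt)
  for (k in seq_len(rt)) {
    masked <- score
    masked[!avail_e, ] <- -Inf
    masked[, !avail_t] <- -Inf
    ij <- arrayInd(which.max(masked), dim(masked))
    est_of[ij[2]] <- ij[1]
    avail_e[ij[1]] <- FALSE
    avail_t[ij[2]] <- FALSE
  }
  data.frame(
    true_index = seq_len(rt),
    est_index = est_of,
    spatial = abs(cs[cbind(est_of, seq_len(rt))]),
    temporal = abs(ct[cbind(est_of, seq_len(rt))]),
    subject = abs(cu[cbind(est_of, seq_len(rt))]),
    score = score[cbind(est_of, seq_len(rt))],
    sign = ifelse(cs[cbind(est_of, seq_len(rt))] < 0, -1, 1)
  )
}

#' Fraction of tensor variance explained by a decomposition
#'
#' Computes \code{1 - ||X - Xhat||^2 / ||X||^2} exactly via Gram matrices
#' (no reconstruction of the full tensor).
#'
#' @param decomposition A \code{\link{cp_decomposition}} (may have zero
#'   components, giving 0).
#' @param tensor The \code{\link{data_tensor}} it was fitted to.
#' @return A fraction in \code{[0, 1]} (up to numerical error).
#' @export
explained_variance <- function(decomposition, tensor) {
  stopifnot(inherits(tensor, "data_tensor"))
  x <- tensor$values
  xnorm2 <- sum(x^2)
  if (xnorm2 == 0) stop("tensor is identically zero: explained variance undefined")
  if (length(decomposition$components) == 0L) return(0)
  f <- factor_matrices(decomposition)
  dm <- dim(x)
  if (nrow(f$spatial) != dm[1] || nrow(f$temporal) != dm[2] ||
      nrow(f$subject) != dm[3]) {
    stop("decomposition and tensor dimensions are inconsistent")
  }
  x1 <- matrix(x, dm[1], dm[2] * dm[3])
  g1 <- x1 %*% khatri_rao(f$subject, f$temporal)
  inner <- sum(f$lambda * colSums(f$spatial * g1))
  model2 <- sum(
    crossprod(f$spatial) * crossprod(f$temporal) * crossprod(f$subject) *
      outer(f$lambda, f$lambda)
  )
  resid <- xnorm2 - 2 * inner + model2
  1 - resid / xnorm2
}
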