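# ---- trimmed multivariate Gaussian (single cluster) --------------------------
#
# The cell classifier is a trimmed maximum-likelihood Gaussian fit: with n
# observations and trimming level alpha, the h = n - floor(n*alpha) most
# Gaussian-typical observations are retained and the remaining floor(n*alpha)
# trimmed. The fit alternates concentration steps (C-steps): score all points
# under the current (mu, Sigma), retain the h highest log-densities,
# re-estimate mu and Sigma from the retained set (MLE denominator, so each
# C-step cannot decrease the trimmed log-likelihood), until the retained set
# is stable. Multiple restarts guard against local optima; restart 1 is
# always the deterministic full-sample moment estimate.

# floor(n*alpha) with a guard against binary-float underrun (200*0.05 etc.)
n_trimmed_for <- function(n, alpha) as.integer(floor(n * alpha + 1e-9))

# ridge-regularized scatter: sigma + eps*trace(sigma)/d * I, then an absolute
# eigenvalue floor so the fit is defined even for degenerate retained sets
regularize_scatter <- function(sigma, reg_eps = 1e-6, eig_floor = 1e-12) {
  d <- ncol(sigma)
  sigma <- (sigma + t(sigma)) / 2
  sigma <- sigma + diag(reg_eps * max(sum(diag(sigma)) / d, eig_floor), d)
  ev <- eigen(sigma, symmetric = TRUE)
  if (ev$values[d] < eig_floor) {
    vals <- pmax(ev$values, eig_floor)
    sigma <- ev$vectors %*% (vals * t(ev$vectors))
    sigma <- (sigma + t(sigma)) / 2
  }
  sigma
}

# Gaussian log-density of rows of X under (mu, sigma), via Cholesky
mvn_logdensity <- function(X, mu, sigma) {
  d <- ncol(X)
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("singular covariance after regularization; increase reg_eps",
         call. = FALSE))
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Fit a single trimmed multivariate Gaussian
#'
#' @param X Numeric matrix, n observations x d variables (cells x bins).
#' @param alpha Trimming fraction in [0, 0.5]: floor(n*alpha) observations
#'   are trimmed as outliers.
#' @param n_starts Number of restarts; restart 1 is the deterministic
#'   full-sample moments initialization, the rest are random small-subset
#'   moment initializations.
#' @param max_iter Maximum C-steps per restart.
#' @param tol Convergence tolerance on the objective change.
#' @param seed Optional seed for the random restarts (local RNG; global
#'   state is untouched). With `n_starts = 1` the fit is deterministic
#'   without a seed.
#' @param reg_eps Relative ridge added to the scatter (fraction of mean
#'   eigenvalue).
#' @param extra_inits Optional list of additional deterministic
#'   initializations, each a list with `mu` and `sigma` (used by
#'   [ctl_curve()] to warm-start each alpha from its neighbor, which keeps
#'   the curve smooth). They replace random restarts, keeping the total
#'   number of starts at `n_starts`.
#' @param eig_floor Absolute eigenvalue floor of the scatter.
#' @return A `trimmed_fit`: list with `alpha`, `mu`, `sigma`, `retained`,
#'   `trimmed` (integer index sets), `objective` (trimmed log-likelihood:
#'   sum of Gaussian log-densities over retained points), `mean_objective`,
#'   `iterations`, `converged`, `objective_trace`.
#' @export
trimmed_fit <- function(X, alpha, n_starts = 20L, max_iter = 100L,
                        tol = 1e-8, seed = NULL,
                        reg_eps = 1e-6, eig_floor = 1e-12,
                        extra_inits = list()) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (alpha < 0 || alpha > 0.5)
    stop("alpha must be in [0, 0.5]", call. = FALSE)
  n_trim <- n_trimmed_for(n, alpha)
  h <- n - n_trim
  if (h < d + 1L)
    stop(sprintf("retained size %d too small to estimate a %d-dim scatter (need > d)",
                 h, d), call. = FALSE)

  one_start <- function(mu0, sigma0, iter_cap = max_iter) {
    mu <- mu0; sigma <- sigma0
    retained <- integer(0)
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      ll <- mvn_logdensity(X, mu, sigma)
      new_retained <- sort(order(ll, decreasing = TRUE)[seq_len(h)])
      obj <- sum(ll[new_retained])
      trace <- c(trace, obj)
      stable <- identical(new_retained, retained)
      small_gain <- length(trace) > 1L &&
        abs(obj - trace[length(trace) - 1L]) <= tol * (1 + abs(obj))
      retained <- new_retained
      if (stable || small_gain) { converged <- TRUE; break }
      if (iter >= iter_cap) break
      mu <- colMeans(X[retained, , drop = FALSE])
      cen <- sweep(X[retained, , drop = FALSE], 2L, mu)
      sigma <- regularize_scatter(crossprod(cen) / h, reg_eps, eig_floor)
    }
    # polish: report the moments of the final retained set and the retained
    # set under those moments, so (mu, sigma, retained, objective) are a
    # consistent fixed-point description (a C-step, so never a decrease)
    mu <- colMeans(X[retained, , drop = FALSE])
    cen <- sweep(X[retained, , drop = FALSE], 2L, mu)
    sigma <- regularize_scatter(crossprod(cen) / h, reg_eps, eig_floor)
    ll <- mvn_logdensity(X, mu, sigma)
    retained <- sort(order(ll, decreasing = TRUE)[seq_len(h)])
    trace <- c(trace, sum(ll[retained]))
    list(mu = mu, sigma = sigma, retained = retained,
         objective = trace[length(trace)], iterations = iter,
         converged = converged, trace = trace)
  }

  init_full <- function() {
    mu0 <- colMeans(X)
    cen <- sweep(X, 2L, mu0)
    list(mu = mu0,
         sigma = regularize_scatter(crossprod(cen) / n, reg_eps, eig_floor))
  }
  init_random <- function() {
    idx <- sample.int(n, min(n, d + 1L))
    mu0 <- colMeans(X[idx, , drop = FALSE])
    cen <- sweep(X[idx, , drop = FALSE], 2L, mu0)
    list(mu = mu0,
         sigma = regularize_scatter(crossprod(cen) / length(idx),
                                    reg_eps, eig_floor))
  }

  # deterministic starts run to convergence; random starts get two C-steps
  # each and only the most promising few are concentrated fully (the
  # standard fast two-stage scheme for trimmed estimators)
  run_starts <- function() {
    best <- NULL
    take <- function(res) {
      if (is.null(best) || res$objective > best$objective) best <<- res
    }
    for (ini in c(list(init_full()), extra_inits))
      take(one_start(ini$mu, ini$sigma))
    n_random <- max(0L, n_starts - 1L - length(extra_inits))
    if (n_random > 0L) {
      shorts <- lapply(seq_len(n_random), function(s) {
        ini <- init_random()
        one_start(ini$mu, ini$sigma, iter_cap = 2L)
      })
      objs <- vapply(shorts, `[[`, numeric(1), "objective")
      n_keep <- min(n_random, max(2L, ceiling(n_random / 5)))
      for (i in order(objs, decreasing = TRUE)[seq_len(n_keep)])
        take(one_start(shorts[[i]]$mu, shorts[[i]]$sigma))
    }
    best
  }
  best <- if (is.null(seed)) run_starts() else withr::with_seed(seed, run_starts())

  structure(list(alpha = alpha,
                 mu = best$mu,
                 sigma = best$sigma,
                 retained = best$retained,
                 trimmed = setdiff(seq_len(n), best$retained),
                 objective = best$objective,
                 mean_objective = best$objective / h,
                 iterations = best$iterations,
                 converged = best$converged,
                 objective_trace = best$trace,
                 n = n, d = d),
            class = "trimmed_fit")
}

#' @export
print.trimmed_fit <- function(x, ...) {
  cat(sprintf(
    "<trimmed_fit> alpha=%.3f n=%d retained=%d trimmed=%d objective=%.4f (%s)\n",
    x$alpha, x$n, length(x$retained), length(x$trimmed), x$objective,
    if (x$converged) sprintf("converged in %d C-steps", x$iterations)
    else "not converged"))
  invisible(x)
}

# ---- classification trimmed likelihood (CTL) curve ---------------------------

#' Sweep a trimming-level grid and build the CTL curve
#'
#' Runs one trimmed fit per grid alpha (same seed policy per alpha, so the
#' curve is reproducible) and records the trimmed log-likelihood objective
#' and its per-retained-point mean. The mean objective is non-decreasing in
#' alpha: each larger alpha may drop strictly lower-density points.
#'
#' @param X Numeric matrix (cells x bins).
#' @param alpha_grid Ascending grid in [0, 0.5], at least 5 values.
#'   Default 0.01..0.45 by 0.01.
#' @param n_starts,max_iter,tol,seed,reg_eps,eig_floor Passed to
#'   [trimmed_fit()]; the same `seed` is used at every alpha.
#' @return A `ctl_curve`: list with `alphas`, `objectives`,
#'   `mean_objectives`, `n_trimmed`, `fits`, and (after
#'   [select_alpha_auto()]) `selected_alpha`, `selection_mode`.
#' @export
ctl_curve <- function(X, alpha_grid = seq(0.01, 0.45, by = 0.01),
                      n_starts = 20L, max_iter = 100L, tol = 1e-8,
                      seed = NULL, reg_eps = 1e-6, eig_floor = 1e-12) {
  if (length(alpha_grid) < 5L)
    stop("alpha grid needs at least 5 values", call. = FALSE)
  if (is.unsorted(alpha_grid, strictly = TRUE))
    stop("alpha grid must be strictly ascending", call. = FALSE)
  if (min(alpha_grid) < 0 || max(alpha_grid) > 0.5)
    stop("alpha grid must lie in [0, 0.5]", call. = FALSE)
  # sweep from the largest alpha down: heavily trimmed fits sit on an
  # unambiguous clean core, and each smaller alpha inherits it as a warm
  # start, which keeps every fit on the global branch of the curve
  fits <- vector("list", length(alpha_grid))
  warm <- list()
  for (i in rev(seq_along(alpha_grid))) {
    a <- alpha_grid[i]
    fits[[i]] <- tryCatch(
      trimmed_fit(X, a, n_starts = n_starts, max_iter = max_iter, tol = tol,
                  seed = seed, reg_eps = reg_eps, eig_floor = eig_floor,
                  extra_inits = warm),
      error = function(e)
        stop(sprintf("CTL curve failed at alpha=%.3f: %s", a,
                     conditionMessage(e)), call. = FALSE))
    warm <- list(list(mu = fits[[i]]$mu, sigma = fits[[i]]$sigma))
  }
  structure(list(alphas = alpha_grid,
                 objectives = vapply(fits, `[[`, numeric(1), "objective"),
                 mean_objectives = vapply(fits, `[[`, numeric(1),
                                          "mean_objective"),
                 n_trimmed = vapply(fits, function(f) length(f$trimmed),
                                    integer(1)),
                 fits = fits,
                 selected_alpha = NA_real_,
                 selection_mode = NA_character_,
                 low_confidence = NA),
            class = "ctl_curve")
}

#' Automatically select the trimming level from a CTL curve
#'
#' Normalizes the forward differences of the mean trimmed log-likelihood by
#' the grid step and by the curve's total range, then returns the smallest
#' grid alpha from which every subsequent normalized slope stays below
#' `flatness_tol` — the first point of sustained flatness, i.e. the elbow
#' where further trimming stops removing genuinely atypical cells. A curve
#' that is flat everywhere returns the grid minimum; a curve that never
#' flattens returns the grid minimum with `low_confidence = TRUE`.
#'
#' @param curve A `ctl_curve`.
#' @param flatness_tol Normalized-slope threshold (curve range = 1, alpha in
#'   native units). Default 0.02.
#' @return The input curve with `selected_alpha`, `selection_mode = "auto"`
#'   and `low_confidence` filled in.
#' @export
select_alpha_auto <- function(curve, flatness_tol = 5) {
  stopifnot(inherits(curve, "ctl_curve"))
  m <- curve$mean_objectives
  a <- curve$alphas
  rng <- diff(range(m))
  low_confidence <- FALSE
  if (rng <= 0) {
    sel <- a[1L]                       # strictly flat curve
  } else {
    slope <- diff(m) / (diff(a) * rng)
    # index of last slope >= tol; selection is the grid point after it
    last_steep <- if (any(slope >= flatness_tol))
      max(which(slope >= flatness_tol)) else 0L
    if (last_steep >= length(a) - 1L) {
      sel <- a[1L]
      low_confidence <- TRUE           # never flattens
    } else {
      sel <- a[last_steep + 1L]
    }
  }
  curve$selected_alpha <- sel
  curve$selection_mode <- "auto"
  curve$low_confidence <- low_confidence
  curve
}

#' @export
print.ctl_curve <- function(x, ...) {
  cat(sprintf("<ctl_curve> %d alphas in [%.2f, %.2f]", length(x$alphas),
              min(x$alphas), max(x$alphas)))
  if (!is.na(x$selected_alpha))
    cat(sprintf("; selected alpha = %.3f (%s%s)", x$selected_alpha,
                x$selection_mode,
                if (isTRUE(x$low_confidence)) ", low confidence" else ""))
  cat("\n")
  invisible(x)
}

#' Export a CTL curve as TSV
#' @param curve A `ctl_curve`.
#' @param path Output TSV path.
#' @export
save_ctl_curve <- function(curve, path) {
  dt <- data.table::data.table(alpha = curve$alphas,
                               objective = curve$objectives,
                               mean_objective = curve$mean_objectives,
                               n_trimmed = curve$n_trimmed)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
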