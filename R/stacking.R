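#' Pointwise leave-one-out predictive densities of a fitted model
#'
#' Computes, for every observation, the out-of-sample predictive
#' density `p(y_i | y_-i)` of a fitted topographic model, holding the
#' estimated smoothing parameters and residual variance fixed.
#'
#' Method `"exact"` uses the closed-form case-deletion identities of
#' the penalized Gaussian model: with hat value
#' `h_i = x_i' (X'X + S)^-1 x_i`, the left-out predictive distribution
#' is normal with mean `(mu_i - h_i y_i) / (1 - h_i)` and variance
#' `sigma^2 / (1 - h_i)`.
#'
#' Method `"psis"` approximates the same quantity by Pareto-smoothed
#' importance sampling from posterior draws: the importance ratios
#' `1 / p(y_i | theta_s)` have their upper tail (20%) replaced by
#' quantiles of a generalized Pareto distribution fitted to the tail
#' exceedances; points whose estimated tail-shape `k` exceeds
#' `k_threshold` fall back to the exact computation and are recorded in
#' the diagnostics.
#'
#' @param fit a `gam_fit`.
#' @param data optional trial-amplitude data.frame used to verify that
#'   the fit matches (hash check); the densities are computed from the
#'   response stored in the fit.
#' @param method `"exact"` or `"psis"`.
#' @param n_draws posterior draws for `"psis"`.
#' @param k_threshold Pareto tail-shape fallback threshold
#'   (default 0.7).
#' @param seed integer seed for the draws.
#' @return numeric vector of predictive densities with attributes
#'   `khat` (per-point tail shapes, `"psis"` only) and `n_fallback`.
#' @export
pointwise_loo <- function(fit, data = NULL,
                          method = c("exact", "psis"),
                          n_draws = 1000L, k_threshold = 0.7, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "gam_fit"))
  if (!is.null(data)) {
    h <- rlang::hash(list(data$amplitude, nrow(data)))
    if (!identical(h, fit$data_hash)) {
      stop("data does not match the data the model was fitted to",
           call. = FALSE)
    }
  }
  exact <- loo_exact_gaussian(fit)
  if (method == "exact") {
    attr(exact, "n_fallback") <- 0L
    return(exact)
  }
  draws <- draw_posterior(fit, n_draws, seed)      # S x p
  mu <- fit$X %*% t(draws)                         # n x S
  sigma <- sqrt(fit$scale)
  n <- length(fit$y)
  dens <- numeric(n)
  khat <- numeric(n)
  n_fb <- 0L
  for (i in seq_len(n)) {
    lik <- stats::dnorm(fit$y[i], mu[i, ], sigma)
    ps <- psis_smooth(-log(pmax(lik, 1e-300)))
    khat[i] <- ps$khat
    if (!is.finite(ps$khat) || ps$khat > k_threshold) {
      dens[i] <- exact[i]
      n_fb <- n_fb + 1L
    } else {
      w <- ps$weights
      dens[i] <- sum(w * lik) / sum(w)
    }
  }
  attr(dens, "khat") <- khat
  attr(dens, "n_fallback") <- n_fb
  dens
}

# internal: closed-form conditional leave-one-out predictive densities
# for the penalized Gaussian fit
loo_exact_gaussian <- function(fit) {
  X <- fit$X
  p <- ncol(X)
  A <- crossprod(X)
  if (length(fit$penalties)) {
    for (j in seq_along(fit$penalties)) {
      pen <- fit$penalties[[j]]
      A[pen$cols, pen$cols] <- A[pen$cols, pen$cols] + fit$sp[j] * pen$S
    }
  }
  R <- chol(A)
  XAi <- t(backsolve(R, forwardsolve(t(R), t(X))))   # X A^-1
  h <- rowSums(XAi * X)
  h <- pmin(h, 1 - 1e-10)
  mu <- as.numeric(X %*% fit$coefficients)
  m_loo <- (mu - h * fit$y) / (1 - h)
  v_loo <- fit$scale / (1 - h)
  stats::dnorm(fit$y, m_loo, sqrt(v_loo))
}

#' Pareto-smoothed importance weights
#'
#' Smooths a vector of log importance ratios by fitting a generalized
#' Pareto distribution (by the profile-posterior method of Zhang and
#' Stephens) to the largest 20% of the ratios and replacing them with
#' expected order statistics of the fitted tail, truncated at the raw
#' maximum.
#'
#' @param log_ratios numeric vector of log importance ratios.
#' @param tail_frac fraction of the sample treated as the tail
#'   (default 0.2).
#' @return list with `weights` (smoothed ratios on the natural scale,
#'   normalized to maximum 1) and `khat` (estimated tail shape).
#' @export
psis_smooth <- function(log_ratios, tail_frac = 0.2) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- ceiling(tail_frac * S)
  if (M < 5L || stats::sd(lw) < 1e-12) {
    return(list(weights = exp(lw), khat = -Inf))
  }
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1L):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  gpd <- gpd_fit(exceed)
  if (!is.finite(gpd$k)) {
    return(list(weights = exp(lw), khat = gpd$k))
  }
  q <- (seq_len(M) - 0.5) / M
  smoothed <- exp(cutoff) + gpd_quantile(q, gpd$k, gpd$sigma)
  smoothed <- pmin(smoothed, 1)     # truncate at the raw maximum (=1)
  w <- exp(lw)
  w[tail_ids[order(exceed)]] <- smoothed
  list(weights = w, khat = gpd$k)
}

# internal: Zhang-Stephens (2009) generalized Pareto fit to exceedances
# (profile-posterior weighting over a theta grid; shape k > 0 = heavy tail)
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L || x[n] <= 0) return(list(k = -Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  q1 <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * q1)
  k_of <- function(th) mean(log1p(-th * x))
  prof <- vapply(theta, function(th) {
    k <- k_of(th)
    if (!is.finite(k) || k == 0 || -th / k <= 0) return(-Inf)
    n * (log(-th / k) - k - 1)
  }, 0)
  if (!any(is.finite(prof))) return(list(k = -Inf, sigma = NA_real_))
  w <- exp(prof - max(prof))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- k_of(theta_hat)
  list(k = k, sigma = -k / theta_hat)
}

# internal: GPD quantile function (exceedance scale), shape k, scale sigma
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k    # sigma*((1-p)^{-k}-1)/k
}

#' Stacking weights from a matrix of LOO predictive densities
#'
#' Maximizes the average log pointwise predictive density of the
#' weighted model mixture, `(1/n) sum_i log sum_k w_k p_ki`, over the
#' probability simplex, by exponentiated-gradient ascent with step
#' halving. The objective is concave, so the attained value is the
#' global maximum; exact ties between models (identical density
#' columns) keep their symmetric uniform weights, and weights that
#' converge below a snapping tolerance are set to exactly zero when
#' this does not decrease the objective.
#'
#' @param loo numeric `n x K` matrix of positive leave-one-out
#'   predictive densities (columns = models).
#' @param max_iter,tol optimizer controls; convergence is declared when
#'   the objective improves by less than `tol`.
#' @return object of class `stack_weights`: list with `w` (simplex
#'   vector), `objective`, `ranking` (model indices by decreasing
#'   weight) and `iterations`.
#' @export
stack_weights <- function(loo, max_iter = 10000L, tol = 1e-10) {
  loo <- as.matrix(loo)
  n <- nrow(loo)
  K <- ncol(loo)
  if (K < 2L) stop("need at least 2 models", call. = FALSE)
  if (any(!is.finite(loo)) || any(loo <= 0)) {
    stop("predictive densities must be positive and finite", call. = FALSE)
  }
  obj <- function(w) mean(log(loo %*% w))
  w <- rep(1 / K, K)
  f <- obj(w)
  eta <- 1
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mix <- as.numeric(loo %*% w)
    grad <- unname(colMeans(loo / mix))
    improved <- FALSE
    while (eta > 1e-12) {
      w_new <- w * exp(eta * grad)
      w_new <- w_new / sum(w_new)
      f_new <- obj(w_new)
      if (f_new >= f - 1e-15) { improved <- TRUE; break }
      eta <- eta / 2
    }
    if (!improved || iter >= max_iter) break
    delta <- f_new - f
    w <- w_new
    f <- f_new
    eta <- min(eta * 1.5, 100)
    if (delta < tol && iter > 10L) break
  }
  # snap negligible weights to exact zero when it costs nothing
  snap <- w < 1e-3
  if (any(snap) && !all(snap)) {
    w_try <- ifelse(snap, 0, w)
    w_try <- w_try / sum(w_try)
    if (obj(w_try) >= f - 1e-12) {
      w <- w_try
      f <- obj(w)
    }
  }
  structure(list(w = w, objective = f,
                 ranking = order(w, decreasing = TRUE),
                 iterations = iter),
            class = "stack_weights")
}

#' @export
print.stack_weights <- function(x, ...) {
  cat(sprintf("<stack_weights K=%d, objective=%.6f>\n", length(x$w),
              x$objective))
  cat("  weights:", paste(sprintf("%.3f", x$w), collapse = " "), "\n")
  invisible(x)
}

#' Fit and stack a set of candidate topographic models
#'
#' Fits every [gam_spec()] to the same trial-amplitude data, computes
#' each model's pointwise leave-one-out predictive densities, and
#' solves the simplex-constrained stacking problem. Models whose fit
#' does not converge are excluded, with the reason recorded.
#'
#' @param data trial-amplitude data.frame.
#' @param specs list of [gam_spec()] (default [default_gam_specs()]).
#' @param loo_method `"psis"` (default, with exact fallback per point)
#'   or `"exact"`.
#' @param k_by,k_re basis dimensions passed to [fit_topo_gam()].
#' @param n_draws posterior draws for PSIS.
#' @param seed integer seed.
#' @return object of class `stack_result`: `weights` (data.frame
#'   `model_name`, `weight`, `loo_objective`), `w`, `objective`,
#'   `loo_matrix`, `fits`, `excluded`, `diagnostics`.
#' @export
compare_models <- function(data, specs = default_gam_specs(),
                           loo_method = c("psis", "exact"),
                           k_by = c(5, 5), k_re = c(3, 3),
                           n_draws = 1000L, seed = 1L) {
  loo_method <- match.arg(loo_method)
  stopifnot(length(specs) >= 2L)
  names <- vapply(specs, function(s) s$model_name, "")
  fits <- list()
  cols <- list()
  excluded <- character(0)
  diagnostics <- list()
  for (i in seq_along(specs)) {
    fit <- tryCatch(fit_topo_gam(data, specs[[i]], k_by = k_by, k_re = k_re),
                    error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      excluded[names[i]] <- if (inherits(fit, "error"))
        conditionMessage(fit) else "smoothing-parameter estimation did not converge"
      next
    }
    dens <- pointwise_loo(fit, method = loo_method, n_draws = n_draws,
                          seed = derive_seed(seed, names[i]))
    fits[[names[i]]] <- fit
    cols[[names[i]]] <- dens
    diagnostics[[names[i]]] <- list(
      n_fallback = attr(dens, "n_fallback"),
      khat_max = if (!is.null(attr(dens, "khat")))
        max(attr(dens, "khat")) else NA_real_)
  }
  if (length(cols) < 2L) {
    stop("fewer than 2 candidate models converged", call. = FALSE)
  }
  loo_mat <- do.call(cbind, cols)
  sw <- stack_weights(loo_mat)
  weights <- data.frame(model_name = colnames(loo_mat),
                        weight = sw$w,
                        loo_objective = colMeans(log(loo_mat)),
                        stringsAsFactors = FALSE)
  weights <- weights[order(-weights$weight), ]
  rownames(weights) <- NULL
  structure(list(weights = weights, w = sw$w, objective = sw$objective,
                 loo_matrix = loo_mat, fits = fits, excluded = excluded,
                 diagnostics = diagnostics),
            class = "stack_result")
}

#' @export
print.stack_result <- function(x, ...) {
  cat("<stack_result>\n")
  df <- x$weights
  df$weight <- sprintf("%d%%", round(100 * df$weight))
  print(df, row.names = FALSE)
  if (length(x$excluded)) {
    cat("  excluded:", paste(names(x$excluded), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bar chart of stacking weights
#'
#' @param result a `stack_result`.
#' @return a ggplot object.
#' @export
plot_stack_weights <- function(result) {
  stopifnot(inherits(result, "stack_result"))
  df <- result$weights
  df$model_name <- factor(df$model_name, levels = rev(df$model_name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight,
                                   y = .data$model_name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(labels = function(v)
      sprintf("%d%%", round(100 * v)), limits = c(0, 1)) +
    ggplot2::labs(x = "stacking weight", y = NULL) +
    ggplot2::theme_minimal()
}
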