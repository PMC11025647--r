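#' Tensor-product P-spline basis over the electrode plane
#'
#' Builds marginal B-spline bases over the x and y coordinates (cubic
#' where the requested dimension allows, with equally spaced knots over
#' `[-1, 1]`) and their tensor product, together with the two penalty
#' blocks of the tensor term: the Kronecker products of each marginal
#' second-difference penalty with the identity on the other margin.
#' Because the marginal dimensions and penalties are separate, no
#' assumption is made that smoothness is consistent between the two
#' coordinates. The marginal B-splines form a partition of unity, so
#' the constant function lies in the penalty null space
#' (`S %*% 1 = 0`).
#'
#' @param layout an [make_layout()] electrode layout (used for a rank
#'   warning on degenerate layouts; the basis itself is defined on the
#'   unit square enclosing the disk).
#' @param kx,ky marginal basis dimensions, at least 3.
#' @return object of class `tensor_basis` with fields `kx`, `ky`,
#'   `knots_x`, `knots_y`, `degree_x`, `degree_y` and `penalties` (two
#'   `kx*ky` square blocks).
#' @export
build_tensor_basis <- function(layout = NULL, kx = 5L, ky = 5L) {
  stopifnot(kx >= 3, ky >= 3)
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "electrode_layout"))
    if (stats::sd(layout$x) < 1e-8 || stats::sd(layout$y) < 1e-8) {
      warning("electrode layout is (near) collinear; tensor term will be rank deficient",
              call. = FALSE)
    }
  }
  mx <- marginal_bspline(kx)
  my <- marginal_bspline(ky)
  S1 <- kronecker(mx$S, diag(ky))
  S2 <- kronecker(diag(kx), my$S)
  structure(list(kx = as.integer(kx), ky = as.integer(ky),
                 knots_x = mx$knots, knots_y = my$knots,
                 degree_x = mx$degree, degree_y = my$degree,
                 penalties = list(S1, S2)),
            class = "tensor_basis")
}

# internal: marginal B-spline basis of dimension k on [-1, 1] with a
# second-difference penalty on the coefficients
marginal_bspline <- function(k, range = c(-1, 1)) {
  degree <- min(3L, k - 1L)
  nseg <- k - degree
  dx <- diff(range) / nseg
  knots <- seq(range[1] - degree * dx, range[2] + degree * dx, by = dx)
  D <- diff(diag(k), differences = 2L)
  list(degree = degree, knots = knots, S = crossprod(D))
}

#' Evaluate a tensor basis at coordinates
#'
#' Columns are ordered x-major: column `(i - 1) * ky + j` is the
#' product of marginal basis function `i` in x and `j` in y.
#'
#' @param basis a [build_tensor_basis()] result.
#' @param x,y coordinate vectors (within `[-1, 1]`).
#' @return numeric matrix with `length(x)` rows and `kx * ky` columns.
#' @export
tensor_basis_eval <- function(basis, x, y) {
  stopifnot(inherits(basis, "tensor_basis"), length(x) == length(y))
  Bx <- splines::splineDesign(basis$knots_x, x, ord = basis$degree_x + 1L)
  By <- splines::splineDesign(basis$knots_y, y, ord = basis$degree_y + 1L)
  Bx[, rep(seq_len(basis$kx), each = basis$ky), drop = FALSE] *
    By[, rep(seq_len(basis$ky), times = basis$kx), drop = FALSE]
}

#' Specify one candidate topographic model
#'
#' Describes one additive model of trial amplitudes in terms of its
#' fixed effects, its by-variable tensor smooths (spatially varying
#' coefficient fields for the reanalysis condition and/or surprisal)
#' and its topographic random effects (per-level coefficient vectors on
#' a shared tensor basis, one variance parameter per grouping factor).
#' The default candidate set ([default_gam_specs()]) mirrors the
#' standard model family: a baseline with trial drift and random
#' topographies only, an Agent-Preference-alone model, one
#' surprisal-alone model per surprisal column, and one combined model
#' per surprisal column.
#'
#' @param model_name label for reporting.
#' @param fixed_terms subset of `c("intercept", "cond", "surp",
#'   "trial")`.
#' @param by_smooths subset of `c("cond", "surp")`; each adds a tensor
#'   smooth whose columns are multiplied by that covariate.
#' @param random_topo subset of `c("participant", "item")`.
#' @param surp_var name of the (z-scored) surprisal column used by
#'   `surp` terms.
#' @return object of class `gam_spec`.
#' @export
gam_spec <- function(model_name,
                     fixed_terms = c("intercept", "trial"),
                     by_smooths = character(0),
                     random_topo = c("participant", "item"),
                     surp_var = "surp_z") {
  fixed_terms <- match.arg(fixed_terms,
                           c("intercept", "cond", "surp", "trial"),
                           several.ok = TRUE)
  if (length(by_smooths)) {
    by_smooths <- match.arg(by_smooths, c("cond", "surp"),
                            several.ok = TRUE)
  }
  if (length(random_topo)) {
    random_topo <- match.arg(random_topo, c("participant", "item"),
                             several.ok = TRUE)
  }
  if (!all(by_smooths %in% fixed_terms)) {
    stop("each by-smooth needs the matching fixed main effect ",
         "(the smooth is centered)", call. = FALSE)
  }
  structure(list(model_name = model_name, fixed_terms = fixed_terms,
                 by_smooths = by_smooths, random_topo = random_topo,
                 surp_var = surp_var),
            class = "gam_spec")
}

#' @rdname gam_spec
#' @param surp_vars named character vector of surprisal columns (names
#'   are used in model labels).
#' @export
default_gam_specs <- function(surp_vars = c(surp = "surp_z")) {
  if (is.null(names(surp_vars))) names(surp_vars) <- surp_vars
  specs <- list(
    gam_spec("baseline"),
    gam_spec("agent_preference_alone",
             fixed_terms = c("intercept", "cond", "trial"),
             by_smooths = "cond"))
  for (nm in names(surp_vars)) {
    specs <- c(specs, list(
      gam_spec(paste0("surprisal_", nm, "_alone"),
               fixed_terms = c("intercept", "surp", "trial"),
               by_smooths = "surp", surp_var = surp_vars[[nm]]),
      gam_spec(paste0("surprisal_", nm, "_and_agent_preference"),
               fixed_terms = c("intercept", "surp", "cond", "trial"),
               by_smooths = c("cond", "surp"), surp_var = surp_vars[[nm]])))
  }
  specs
}

# internal: orthonormal basis of the null space of the constant
# coefficient vector (removes the constant function from a partition-
# of-unity spline basis)
constant_null_space <- function(K) {
  qr.Q(qr(matrix(1, K, 1)), complete = TRUE)[, -1, drop = FALSE]
}

#' Assemble the design bundle for a topographic model
#'
#' Builds the full model matrix and penalty list for one [gam_spec()]:
#' fixed-effect columns; for each by-variable smooth, the tensor basis
#' evaluated at the row coordinates, reparameterized to exclude the
#' constant function (which is carried by the fixed main effect) and
#' multiplied elementwise by the covariate; and for each grouping
#' factor, per-level copies of a (typically coarser) tensor basis with
#' a single ridge penalty shared across levels.
#'
#' @param data trial-amplitude data.frame (needs `amplitude`, `x`,
#'   `y`, plus the covariates the spec references; `participant_id` and
#'   `stim_id` for random topographies). Continuous covariates are
#'   expected z-scored.
#' @param spec a [gam_spec()].
#' @param basis tensor basis for by-smooths (default `kx = ky = 5`).
#' @param basis_re tensor basis for random topographies (default
#'   `kx = ky = 3`).
#' @return object of class `gam_design`: `y`, `X`, `penalties` (list
#'   of `list(S, cols)`), `terms` (column indices per term),
#'   `smooth_info`, bases and the spec.
#' @export
assemble_design <- function(data, spec,
                            basis = build_tensor_basis(kx = 5, ky = 5),
                            basis_re = build_tensor_basis(kx = 3, ky = 3)) {
  stopifnot(inherits(spec, "gam_spec"))
  check_columns(data, c("amplitude", "x", "y"), "data")
  n <- nrow(data)
  cols <- list()
  terms <- list()
  penalties <- list()
  smooth_info <- list()
  add_block <- function(name, X) {
    start <- sum(vapply(cols, ncol, 0L)) + 1L
    cols[[length(cols) + 1L]] <<- X
    terms[[name]] <<- seq.int(start, length.out = ncol(X))
  }
  covariate <- function(term) {
    switch(term,
      cond = as.numeric(data$cond),
      surp = data[[spec$surp_var]],
      trial = data$trial_z,
      stop("unknown term: ", term, call. = FALSE))
  }
  if ("intercept" %in% spec$fixed_terms) add_block("intercept",
                                                   matrix(1, n, 1))
  for (term in intersect(c("cond", "surp", "trial"), spec$fixed_terms)) {
    check_needed(data, term, spec)
    add_block(term, matrix(covariate(term), n, 1))
  }
  if (length(spec$by_smooths)) {
    B <- tensor_basis_eval(basis, data$x, data$y)
    Z <- constant_null_space(ncol(B))
    BZ <- B %*% Z
    for (term in spec$by_smooths) {
      nm <- paste0("s(", term, ")")
      add_block(nm, BZ * covariate(term))
      for (S in basis$penalties) {
        penalties[[length(penalties) + 1L]] <-
          list(S = crossprod(Z, S %*% Z), cols = terms[[nm]])
      }
      smooth_info[[nm]] <- list(by = term, Z = Z)
    }
  }
  for (grp in spec$random_topo) {
    col <- if (grp == "participant") "participant_id" else
      if ("item_id" %in% names(data)) "item_id" else "stim_id"
    check_columns(data, col, "data")
    f <- factor(data[[col]])
    Bre <- tensor_basis_eval(basis_re, data$x, data$y)
    K2 <- ncol(Bre)
    L <- nlevels(f)
    Xre <- matrix(0, n, L * K2)
    idx <- as.integer(f)
    for (k in seq_len(K2)) {
      Xre[cbind(seq_len(n), (idx - 1L) * K2 + k)] <- Bre[, k]
    }
    nm <- paste0("re(", grp, ")")
    add_block(nm, Xre)
    penalties[[length(penalties) + 1L]] <-
      list(S = diag(L * K2), cols = terms[[nm]])
    smooth_info[[nm]] <- list(levels = levels(f))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- NULL
  structure(list(y = data$amplitude, X = X, penalties = penalties,
                 terms = terms, smooth_info = smooth_info,
                 basis = basis, basis_re = basis_re, spec = spec,
                 n = n,
                 data_hash = rlang::hash(list(data$amplitude, n))),
            class = "gam_design")
}

# internal: check the data has what a spec term requires
check_needed <- function(data, term, spec) {
  need <- switch(term, cond = "cond", surp = spec$surp_var,
                 trial = "trial_z")
  check_columns(data, need, "data")
}

#' Fit a penalized topographic model
#'
#' Fits the design bundle by penalized least squares with a Gaussian
#' likelihood; the smoothing parameter of each penalty block (two per
#' tensor smooth, one ridge per random-effect grouping) is estimated by
#' restricted marginal likelihood. Penalized blocks correspond to mean
#' zero Gaussian priors with precision proportional to the smoothing
#' parameter, so the returned posterior is the standard Gaussian
#' approximation (coefficient mean plus covariance) conditional on the
#' estimated smoothing parameters; specs with no penalized terms reduce
#' exactly to ordinary least squares.
#'
#' @param design a [assemble_design()] bundle.
#' @param method smoothing-parameter criterion passed to the REML
#'   machinery (`"REML"` default).
#' @param optimizer smoothing-parameter optimizer; the default
#'   extended Fellner-Schall update (`"efs"`) is markedly faster than
#'   full Newton with many penalty blocks and agrees closely.
#' @return object of class `gam_fit`: `coefficients`, `Vp` (posterior
#'   covariance), `sp` (smoothing parameters), `scale` (residual
#'   variance), `edf`, `converged`, plus the design bookkeeping needed
#'   for prediction and cross-validation.
#' @export
fit_gam <- function(design, method = "REML", optimizer = "efs") {
  stopifnot(inherits(design, "gam_design"))
  p <- ncol(design$X)
  dat <- list(y = design$y, X = design$X)
  if (length(design$penalties)) {
    penlist <- lapply(design$penalties, function(pen) {
      S <- matrix(0, p, p)
      S[pen$cols, pen$cols] <- pen$S
      S
    })
    fit <- mgcv::gam(y ~ X - 1, data = dat,
                     paraPen = list(X = penlist), method = method,
                     optimizer = optimizer)
  } else {
    fit <- mgcv::gam(y ~ X - 1, data = dat, method = method)
  }
  beta <- unname(stats::coef(fit))
  structure(list(coefficients = beta, Vp = unname(fit$Vp),
                 sp = if (length(design$penalties)) unname(fit$sp) else
                   numeric(0),
                 scale = fit$sig2, edf = sum(fit$edf),
                 converged = isTRUE(fit$converged),
                 terms = design$terms, smooth_info = design$smooth_info,
                 basis = design$basis, basis_re = design$basis_re,
                 spec = design$spec, X = design$X, y = design$y,
                 penalties = design$penalties, n = design$n,
                 data_hash = design$data_hash),
            class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("<gam_fit %s: n=%d, p=%d, edf=%.1f, scale=%.3f%s>\n",
              x$spec$model_name, x$n, length(x$coefficients), x$edf,
              x$scale, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @rdname fit_gam
#' @param data trial-amplitude data.frame.
#' @param spec a [gam_spec()].
#' @param k_by,k_re marginal basis dimensions for by-smooths and
#'   random topographies.
#' @export
fit_topo_gam <- function(data, spec, k_by = c(5, 5), k_re = c(3, 3),
                         method = "REML", optimizer = "efs") {
  design <- assemble_design(
    data, spec,
    basis = build_tensor_basis(kx = k_by[1], ky = k_by[2]),
    basis_re = build_tensor_basis(kx = k_re[1], ky = k_re[2]))
  fit_gam(design, method = method, optimizer = optimizer)
}

#' Draw from the Gaussian posterior of a fitted model
#'
#' @param fit a `gam_fit`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return matrix `n x p` of coefficient draws.
#' @export
draw_posterior <- function(fit, n = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "gam_fit"))
  with_seed(seed, mgcv::rmvn(n, fit$coefficients, fit$Vp))
}

#' Posterior difference surface over the scalp
#'
#' Computes, on a lattice over the unit disk, the posterior
#' distribution of the fitted amplitude difference between two levels
#' of a predictor, holding the other covariates at their reference
#' value (0 on the z-scale). For the reanalysis condition the default
#' levels are 1 vs 0; for surprisal, +2 vs -2 SD from the mean. The
#' evidence per grid point is summarized by `prob_nonzero`, the larger
#' of the posterior probabilities of the difference being above or
#' below zero (0.5 for a degenerate zero contrast); points with
#' `prob_nonzero < mask_level` are flagged as masked.
#'
#' @param fit a `gam_fit` containing the predictor's terms.
#' @param predictor `"cond"` or `"surp"`.
#' @param levels numeric pair `(level1, level2)`; the surface is
#'   `fitted(level1) - fitted(level2)`.
#' @param grid_n lattice resolution per axis.
#' @param mask_level posterior-probability display threshold
#'   (default 0.8).
#' @param n_draws posterior draws used.
#' @param seed integer seed for the draws.
#' @return object of class `topo_difference`: data.frame `x`, `y`,
#'   `mean_diff`, `prob_nonzero`, `masked`, with the mask level and
#'   predictor as attributes.
#' @export
difference_surface <- function(fit, predictor = c("cond", "surp"),
                               levels = NULL, grid_n = 25L,
                               mask_level = 0.8, n_draws = 2000L,
                               seed = 1L) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(fit, "gam_fit"))
  if (!(predictor %in% names(fit$terms))) {
    stop(sprintf("predictor '%s' is not in the fitted model", predictor),
         call. = FALSE)
  }
  if (is.null(levels)) levels <- if (predictor == "cond") c(1, 0) else
    c(2, -2)
  dlev <- levels[1] - levels[2]
  g <- seq(-1, 1, length.out = grid_n)
  grid <- expand.grid(x = g, y = g)
  grid <- grid[grid$x^2 + grid$y^2 <= 1, , drop = FALSE]
  p <- length(fit$coefficients)
  L <- matrix(0, nrow(grid), p)
  L[, fit$terms[[predictor]]] <- dlev
  snm <- paste0("s(", predictor, ")")
  if (snm %in% names(fit$terms)) {
    B <- tensor_basis_eval(fit$basis, grid$x, grid$y)
    L[, fit$terms[[snm]]] <- (B %*% fit$smooth_info[[snm]]$Z) * dlev
  }
  mean_diff <- as.numeric(L %*% fit$coefficients)
  draws <- draw_posterior(fit, n_draws, seed)
  D <- L %*% t(draws)                        # grid x draws
  p_pos <- rowMeans(D > 0) + 0.5 * rowMeans(D == 0)
  prob <- pmax(p_pos, 1 - p_pos)
  out <- data.frame(x = grid$x, y = grid$y, mean_diff = mean_diff,
                    prob_nonzero = prob, masked = prob < mask_level)
  rownames(out) <- NULL
  structure(out, class = c("topo_difference", "data.frame"),
            predictor = predictor, levels = levels,
            mask_level = mask_level)
}

#' Hierarchical model of a single electrode
#'
#' Replaces the tensor-product smoothers by random slopes at one
#' electrode: `amplitude ~ cond + surp + trial` with by-participant
#' random intercepts and slopes for condition and surprisal, and
#' by-stimulus random intercepts. Inference is the Gaussian
#' approximation around the restricted maximum likelihood fit.
#'
#' @param data trial-amplitude data.frame.
#' @param electrode electrode label present in `data`.
#' @param surp_var surprisal column (default `"surp_z"`).
#' @param min_obs minimum observations required.
#' @return list with `electrode`, `coefficients` (data.frame:
#'   `term`, `estimate`, `se`, `ci_low`, `ci_high`, `prob_nonzero`),
#'   `singular` flag and the `lme4` fit.
#' @export
single_electrode_model <- function(data, electrode, surp_var = "surp_z",
                                   min_obs = 20L) {
  check_columns(data, c("electrode", "amplitude", "cond", surp_var,
                        "trial_z", "participant_id"), "data")
  sub <- data[data$electrode == electrode, , drop = FALSE]
  if (!nrow(sub)) stop("electrode not present in data: ", electrode,
                       call. = FALSE)
  if (nrow(sub) < min_obs) stop("too few observations at electrode ",
                                electrode, call. = FALSE)
  sub$surp <- sub[[surp_var]]
  sub$grp_item <- if ("item_id" %in% names(sub)) sub$item_id else
    sub$stim_id
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(amplitude ~ cond + surp + trial_z +
                 (1 + cond + surp | participant_id) + (1 | grp_item),
               data = sub, REML = TRUE)))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.945)
  p_pos <- stats::pnorm(est / se)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      ci_low = unname(est - z * se),
                      ci_high = unname(est + z * se),
                      prob_nonzero = unname(pmax(p_pos, 1 - p_pos)),
                      stringsAsFactors = FALSE)
  list(electrode = electrode, coefficients = coefs,
       singular = lme4::isSingular(fit), fit = fit)
}
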