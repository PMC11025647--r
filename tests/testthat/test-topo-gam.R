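test_that("tensor bases have the documented dimensions and penalty structure", {
  b <- build_tensor_basis(kx = 3, ky = 3)
  layout <- make_layout(16)
  B <- tensor_basis_eval(b, layout$x, layout$y)
  expect_equal(ncol(B), 9)
  expect_length(b$penalties, 2)
  for (S in b$penalties) {
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
    # constants lie in the penalty null space
    expect_lt(max(abs(S %*% rep(1, 9))), 1e-12)
  }
  # B-splines are a partition of unity on the domain
  expect_equal(rowSums(B), rep(1, 16), tolerance = 1e-12)
  # evaluation is a fixed function of coordinates: electrode points and a
  # grid agree wherever they share coordinates
  g <- expand.grid(x = seq(-1, 1, 0.25), y = seq(-1, 1, 0.25))
  shared <- rbind(g[3, ], data.frame(x = layout$x[1], y = layout$y[1]))
  expect_equal(tensor_basis_eval(b, shared$x, shared$y)[2, ], B[1, ],
               tolerance = 1e-12)
  expect_error(build_tensor_basis(kx = 2), "kx >= 3")
  expect_warning(
    build_tensor_basis(structure(data.frame(label = c("a", "b", "c", "d"),
                                            x = 0, y = c(1, 2, 3, 4) / 5),
                                 class = c("electrode_layout",
                                           "data.frame"))),
    "collinear")
})

test_that("design assembly produces the declared blocks", {
  dat <- make_erp_data(n_items = 8, n_part = 3, n_el = 8, seed = 2)
  base <- assemble_design(dat, gam_spec("baseline"))
  expect_named(base$terms, c("intercept", "trial", "re(participant)",
                             "re(item)"))
  expect_length(base$penalties, 2)   # one ridge per grouping factor
  # by-variable smooth columns equal the (centered) tensor basis scaled
  # elementwise by the covariate
  spec <- gam_spec("combined",
                   fixed_terms = c("intercept", "cond", "surp", "trial"),
                   by_smooths = c("cond", "surp"))
  basis <- build_tensor_basis(kx = 4, ky = 4)
  des <- assemble_design(dat, spec, basis = basis)
  B <- tensor_basis_eval(basis, dat$x, dat$y)
  Z <- qr.Q(qr(matrix(1, 16, 1)), complete = TRUE)[, -1]
  expect_equal(des$X[, des$terms[["s(surp)"]]],
               (B %*% Z) * dat$surp_z, tolerance = 1e-12)
  # a zero condition column zeroes its by-smooth block
  dat0 <- dat
  dat0$cond <- 0
  des0 <- assemble_design(dat0, spec, basis = basis)
  expect_true(all(des0$X[, des0$terms[["s(cond)"]]] == 0))
  # baseline spec has no condition or surprisal terms by construction
  expect_false(any(c("cond", "surp") %in% names(base$terms)))
  expect_error(gam_spec("bad", fixed_terms = "intercept",
                        by_smooths = "cond"), "main effect")
})

test_that("unpenalized fits equal ordinary least squares", {
  dat <- make_erp_data(n_items = 8, n_part = 3, n_el = 8, seed = 6)
  spec <- gam_spec("ols", fixed_terms = c("intercept", "cond", "trial"),
                   by_smooths = character(0), random_topo = character(0))
  fit <- fit_topo_gam(dat, spec)
  ols <- lm(amplitude ~ cond + trial_z, data = dat)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
  expect_length(fit$sp, 0)
})

test_that("an intercept-only truth is recovered exactly in the noise-free limit", {
  dat <- make_erp_data(n_items = 8, n_part = 3, n_el = 8, seed = 7,
                       config = erp_gen_config(
                         baseline = 2.25, beta_trial = 0,
                         field_cond = spatial_field(c(0, 0), 1, 0),
                         field_surp = spatial_field(c(0, 0), 1, 0),
                         sd_participant_field = 0, sd_item_field = 0,
                         sd_noise = 0, n_participants = 3, seed = 7))
  dat$amplitude <- dat$amplitude + rnorm(nrow(dat), 0, 1e-8)
  spec <- gam_spec("cond_alone",
                   fixed_terms = c("intercept", "cond", "trial"),
                   by_smooths = "cond")
  fit <- fit_topo_gam(dat, spec)
  expect_equal(fit$coefficients[fit$terms$intercept], 2.25,
               tolerance = 1e-6)
  expect_lt(max(abs(fit$coefficients[fit$terms[["s(cond)"]]])), 1e-5)
})

test_that("adding a constant to all amplitudes shifts only the intercept", {
  dat <- make_erp_data(n_items = 8, n_part = 4, n_el = 8, seed = 8)
  spec <- gam_spec("combined",
                   fixed_terms = c("intercept", "cond", "surp", "trial"),
                   by_smooths = c("cond", "surp"))
  f1 <- fit_topo_gam(dat, spec, k_by = c(4, 4))
  dat2 <- dat
  dat2$amplitude <- dat$amplitude + 5
  f2 <- fit_topo_gam(dat2, spec, k_by = c(4, 4))
  i <- f1$terms$intercept
  expect_equal(f2$coefficients[i] - f1$coefficients[i], 5,
               tolerance = 1e-6)
  expect_equal(f2$coefficients[-i], f1$coefficients[-i], tolerance = 1e-6)
})

test_that("the trial drift coefficient is recovered within its posterior spread", {
  dat <- make_erp_data(n_items = 24, n_part = 8, n_el = 12, seed = 9)
  spec <- gam_spec("combined",
                   fixed_terms = c("intercept", "cond", "surp", "trial"),
                   by_smooths = c("cond", "surp"))
  fit <- fit_topo_gam(dat, spec)
  j <- fit$terms$trial
  expect_lt(abs(fit$coefficients[j] - 0.5), 2 * sqrt(fit$Vp[j, j]))
  expect_true(fit$converged)
})

test_that("difference surfaces behave on identity contrasts and missing predictors", {
  dat <- make_erp_data(n_items = 8, n_part = 3, n_el = 8, seed = 10)
  spec <- gam_spec("surp_alone",
                   fixed_terms = c("intercept", "surp", "trial"),
                   by_smooths = "surp")
  fit <- fit_topo_gam(dat, spec, k_by = c(4, 4))
  td <- difference_surface(fit, "surp", levels = c(1, 1), n_draws = 500)
  expect_true(all(td$mean_diff == 0))
  expect_true(all(td$prob_nonzero == 0.5))
  expect_true(all(td$x^2 + td$y^2 <= 1))
  expect_error(difference_surface(fit, "cond"), "not in the fitted model")
})

test_that("single-electrode models recover an injected effect and validate input", {
  layout <- make_layout(8)
  cfg <- erp_gen_config(
    field_cond = spatial_field(c(layout$x[3], layout$y[3]), widths = 0.25,
                               amplitudes = -1),
    field_surp = spatial_field(c(0, 0), 1, 0),
    sd_participant_field = 0.2, sd_item_field = 0.1, sd_noise = 0.8,
    n_participants = 10, seed = 12)
  dat <- make_erp_data(n_items = 30, n_part = 10, n_el = 8, seed = 12,
                       config = cfg)
  res <- single_electrode_model(dat, layout$label[3])
  est <- res$coefficients[res$coefficients$term == "cond", ]
  expect_lt(abs(est$estimate - (-1)), 0.4)
  expect_gte(est$prob_nonzero, 0.9)
  expect_error(single_electrode_model(dat, "Nope"), "not present")
})
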