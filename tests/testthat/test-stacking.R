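test_that("the stacking objective is concave and the optimizer attains the optimum", {
  set.seed(11)
  L <- matrix(runif(80, 0.05, 1), 20, 4)
  obj <- function(w) mean(log(L %*% w))
  rsimplex <- function() {
    e <- rexp(4)
    e / sum(e)
  }
  # numerical concavity on random pairs
  for (i in 1:25) {
    w1 <- rsimplex()
    w2 <- rsimplex()
    expect_gte(obj((w1 + w2) / 2), (obj(w1) + obj(w2)) / 2 - 1e-12)
  }
  sw <- stack_weights(L)
  expect_equal(sum(sw$w), 1, tolerance = 1e-10)
  expect_true(all(sw$w >= 0))
  # attained objective beats every unit vector and 100 random points
  for (k in 1:4) {
    expect_gte(sw$objective, obj(diag(4)[, k]) - 1e-10)
  }
  for (i in 1:100) {
    expect_gte(sw$objective, obj(rsimplex()) - 1e-10)
  }
})

test_that("symmetry and dominance cases resolve exactly", {
  set.seed(3)
  col <- runif(20, 0.1, 1)
  expect_equal(stack_weights(cbind(col, col))$w, c(0.5, 0.5))
  L <- cbind(col, col * 0.6)  # model 1 pointwise dominates model 2
  expect_equal(stack_weights(L)$w, c(1, 0))
  expect_error(stack_weights(cbind(col, -col)), "positive")
  expect_error(stack_weights(cbind(col)), "at least 2")
})

test_that("the optimizer matches a fine simplex grid search", {
  set.seed(9)
  L <- matrix(runif(60, 0.05, 1), 20, 3)
  sw <- stack_weights(L)
  grid <- expand.grid(w1 = seq(0, 1, 0.01), w2 = seq(0, 1, 0.01))
  grid <- grid[grid$w1 + grid$w2 <= 1, ]
  best <- max(apply(grid, 1, function(g) {
    mean(log(L %*% c(g[[1]], g[[2]], 1 - g[[1]] - g[[2]])))
  }))
  expect_gte(sw$objective, best - 1e-12)
  expect_lt(sw$objective - best, 1e-4)
})

test_that("exact case-deletion densities agree with a literal refit", {
  dat <- make_erp_data(n_items = 6, n_part = 2, n_el = 4, seed = 14)
  dat <- dat[seq_len(30), ]
  spec <- gam_spec("m", fixed_terms = c("intercept", "cond", "trial"),
                   by_smooths = character(0),
                   random_topo = character(0))
  fit <- fit_topo_gam(dat, spec)
  dens <- pointwise_loo(fit, data = dat, method = "exact")
  # literal refit without observation i, holding sigma^2 fixed
  X <- fit$X
  for (i in c(1, 13, 30)) {
    b_i <- qr.solve(X[-i, , drop = FALSE], fit$y[-i])
    V_i <- fit$scale * solve(crossprod(X[-i, , drop = FALSE]))
    m_i <- sum(X[i, ] * b_i)
    v_i <- fit$scale + drop(X[i, , drop = FALSE] %*% V_i %*% X[i, ])
    expect_equal(dens[i], dnorm(fit$y[i], m_i, sqrt(v_i)),
                 tolerance = 1e-8)
  }
  # exchangeability: duplicated design rows with equal responses get
  # equal leave-one-out densities
  j <- which(duplicated(cbind(X, fit$y)) |
               duplicated(cbind(X, fit$y), fromLast = TRUE))
  if (length(j) >= 2) expect_equal(dens[j[1]], dens[j[2]], tolerance = 1e-10)
  expect_error(pointwise_loo(fit, data = dat[-1, ]), "does not match")
})

test_that("PSIS densities track exact densities within 10% on a small problem", {
  dat <- make_erp_data(n_items = 6, n_part = 2, n_el = 4, seed = 15)
  dat <- dat[seq_len(30), ]
  spec <- gam_spec("m", fixed_terms = c("intercept", "cond", "trial"),
                   by_smooths = "cond", random_topo = character(0))
  fit <- fit_topo_gam(dat, spec, k_by = c(3, 3))
  ex <- pointwise_loo(fit, method = "exact")
  ps <- pointwise_loo(fit, method = "psis", n_draws = 4000, seed = 2)
  expect_lt(max(abs(ps / ex - 1)), 0.10)
  expect_true(all(attr(ps, "khat") < 0.7))
  # forcing the fallback reproduces the exact column for every point
  fb <- pointwise_loo(fit, method = "psis", n_draws = 200,
                      k_threshold = -Inf, seed = 2)
  expect_equal(as.numeric(fb), as.numeric(ex), tolerance = 1e-10)
  expect_equal(attr(fb, "n_fallback"), 30L)
})

test_that("the Pareto tail diagnostic flags heavy-tailed importance ratios", {
  set.seed(4)
  light <- psis_smooth(rnorm(2000, 0, 0.5))
  expect_lt(light$khat, 0.7)
  heavy <- psis_smooth(log(1 / runif(2000)^1.5))  # ratios ~ Pareto(k = 1.5)
  expect_gt(heavy$khat, 0.7)
  # smoothing preserves the bulk: weights equal raw ratios off the tail
  lr <- rnorm(100)
  sm <- psis_smooth(lr)
  raw <- exp(lr - max(lr))
  keep <- rank(lr) <= 80
  expect_equal(sm$weights[keep], raw[keep], tolerance = 1e-12)
})

test_that("compare_models stacks candidate specs and reports diagnostics", {
  dat <- make_erp_data(n_items = 16, n_part = 4, n_el = 8, seed = 16)
  specs <- list(
    gam_spec("baseline"),
    gam_spec("cond", fixed_terms = c("intercept", "cond", "trial"),
             by_smooths = "cond"),
    gam_spec("combined",
             fixed_terms = c("intercept", "cond", "surp", "trial"),
             by_smooths = c("cond", "surp")))
  res <- compare_models(dat, specs, loo_method = "exact",
                        k_by = c(4, 4), seed = 3)
  expect_s3_class(res, "stack_result")
  expect_equal(sum(res$w), 1, tolerance = 1e-10)
  expect_equal(sort(res$weights$model_name),
               sort(c("baseline", "cond", "combined")))
  expect_true(all(is.finite(res$weights$loo_objective)))
  # a duplicated spec shares its weight with its twin symmetrically
  res2 <- compare_models(dat, list(gam_spec("b1"), gam_spec("b2")),
                         loo_method = "exact", seed = 4)
  expect_equal(res2$w, c(0.5, 0.5), tolerance = 1e-6)
})
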