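# small constant-covariate panel: log y = beta + mu_i + gamma_t + eps
const_cov_panel <- function(N_side = 3, T = 5, beta = 2, sd_eps = 0.01,
                            seed = 1) {
  set.seed(seed)
  N <- N_side^2
  w <- lattice_weights(N_side, N_side, "rook")
  logy <- matrix(beta + rnorm(N * T, sd = sd_eps), N, T)
  X <- array(1, dim = c(N, T, 1), dimnames = list(NULL, NULL, "X1"))
  p <- area_panel(exp(logy), matrix(1000, N, T), rep(1, N),
                  rep("R1", N), covariates = X, area_ids = w$ids, years = 1:T)
  list(panel = p, weights = w)
}

test_that("model state has intrinsic priors of the expected rank", {
  sim <- simulate_panel(sim_config(grid_rows = 5, grid_cols = 5, T = 10,
                                   K = 3, seed = 2))
  st <- stvc_build(sim$panel, sim$weights)
  expect_equal(st$rank_s, 24L)
  expect_equal(st$rank_t, 8L)
  expect_length(st$sp_s, 3)
  # spectra: exactly one zero mode for ICAR, two for RW2
  expect_equal(sum(st$sp_s[[1]]$lam < 1e-8), 1L)
  expect_equal(sum(st$sp_t[[1]]$lam < 1e-8), 2L)
})

test_that("non-positive response cells are refused with a pointer to the cell", {
  sim <- simulate_panel(sim_config(grid_rows = 3, grid_cols = 3, T = 4,
                                   K = 1, seed = 4))
  sim$panel$response[5, 2] <- 0
  expect_error(stvc_build(sim$panel, sim$weights), "strictly positive")
})

test_that("degenerate truth is recovered: constant covariate, beta = 2", {
  fx <- const_cov_panel(beta = 2, sd_eps = 0.01, seed = 10)
  fit <- stvc(fx$panel, fx$weights, chains = 2, iterations = 1500,
              burn_in = 500, seed = 10)
  b <- mean(fit$draws$beta[, 1])
  expect_gt(b, 1.95)
  expect_lt(b, 2.05)
  expect_lt(mean(fit$draws$sd_eps), 0.1)
})

test_that("every retained draw satisfies the sum-to-zero constraints", {
  sim <- simulate_panel(sim_config(grid_rows = 4, grid_cols = 4, T = 5,
                                   K = 2, seed = 12))
  fit <- stvc(sim$panel, sim$weights, chains = 2, iterations = 400,
              burn_in = 100, seed = 12)
  mu_sums <- apply(fit$draws$mu, c(2, 3), sum)
  ga_sums <- apply(fit$draws$gamma, c(2, 3), sum)
  expect_lt(max(abs(mu_sums)), 1e-8)
  expect_lt(max(abs(ga_sums)), 1e-8)
  expect_true(all(fit$draws$sd_mu > 0))
  expect_true(all(fit$draws$sd_gamma > 0))
  expect_true(all(fit$draws$sd_eps > 0))
})

test_that("identical seed and config give identical retained draws", {
  sim <- simulate_panel(sim_config(grid_rows = 3, grid_cols = 3, T = 4,
                                   K = 1, seed = 5))
  f1 <- stvc(sim$panel, sim$weights, chains = 2, iterations = 300,
             burn_in = 100, seed = 42)
  f2 <- stvc(sim$panel, sim$weights, chains = 2, iterations = 300,
             burn_in = 100, seed = 42)
  expect_identical(f1$draws, f2$draws)
  f3 <- stvc(sim$panel, sim$weights, chains = 2, iterations = 300,
             burn_in = 100, seed = 43)
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("a noiseless panel is interpolated on the log scale", {
  cfg <- sim_config(grid_rows = 5, grid_cols = 5, T = 8, K = 1,
                    sd_mu = 0.4, sd_gamma = 0.2, sd_eps = 0, beta = 1,
                    covariate_model = "iid_normal", seed = 8)
  sim <- simulate_panel(cfg)
  fit <- stvc(sim$panel, sim$weights, chains = 2, iterations = 1500,
              burn_in = 500, seed = 8)
  rmse <- sqrt(mean((fit$fitted - log(sim$panel$response))^2))
  expect_lt(rmse, 0.01)
})

test_that("covariate standardization rescales beta but not the fit", {
  # mean-zero, non-unit-scale covariate so centering is a no-op and
  # scaling is a pure reparameterization
  set.seed(20)
  N <- 9; T <- 6
  w <- lattice_weights(3, 3, "rook")
  x <- matrix(rnorm(N * T, sd = 3), N, T)
  x <- x - mean(x)
  logy <- 0.5 * x
  X <- array(x, dim = c(N, T, 1), dimnames = list(NULL, NULL, "X1"))
  p <- area_panel(exp(logy), matrix(1000, N, T), rep(1, N), rep("R1", N),
                  covariates = X, area_ids = w$ids, years = 1:T)
  f_std <- stvc(p, w, standardize = TRUE, chains = 2, iterations = 2000,
                burn_in = 800, seed = 21)
  f_raw <- stvc(p, w, standardize = FALSE, chains = 2, iterations = 2000,
                burn_in = 800, seed = 21)
  # beta scale differs by the covariate SD ...
  expect_equal(mean(f_std$draws$beta),
               sd(as.vector(x)) * mean(f_raw$draws$beta), tolerance = 0.05)
  # ... but both interpolate the same noiseless fit
  expect_lt(max(abs(f_std$fitted - f_raw$fitted)), 0.02)
})

test_that("posterior-mean space coefficients are permutation equivariant", {
  cfg <- sim_config(grid_rows = 4, grid_cols = 4, T = 6, K = 1,
                    sd_mu = 0.5, sd_gamma = 0.2, sd_eps = 0.1, seed = 30)
  sim <- simulate_panel(cfg)
  fit <- stvc(sim$panel, sim$weights, chains = 2, iterations = 3000,
              burn_in = 1000, seed = 30)
  set.seed(31)
  perm <- sample(16)
  inv <- order(perm)
  p2 <- sim$panel
  p2$response <- sim$panel$response[perm, ]
  p2$population <- sim$panel$population[perm, ]
  p2$land_area <- sim$panel$land_area[perm]
  p2$region_of <- sim$panel$region_of[perm]
  p2$area_ids <- sim$panel$area_ids[perm]
  p2$covariates <- sim$panel$covariates[perm, , , drop = FALSE]
  w2 <- spatial_weights(lapply(sim$weights$neighbors[perm],
                               function(nb) inv[nb]),
                        ids = sim$weights$ids[perm])
  fit2 <- stvc(p2, w2, chains = 2, iterations = 3000, burn_in = 1000,
               seed = 30)
  m1 <- apply(fit$draws$mu[, 1, ], 1, mean)
  m2 <- apply(fit2$draws$mu[, 1, ], 1, mean)
  expect_lt(max(abs(m2 - m1[perm])), 0.08)  # equal up to Monte-Carlo error
})

test_that("SC/TC tables have the documented shape and ordered quantiles", {
  sim <- simulate_panel(sim_config(grid_rows = 3, grid_cols = 3, T = 5,
                                   K = 2, seed = 40))
  fit <- stvc(sim$panel, sim$weights, chains = 2, iterations = 400,
              burn_in = 100, seed = 40)
  sc <- sc_table(fit)
  tc <- tc_table(fit)
  expect_equal(nrow(sc), 9 * 2)
  expect_equal(nrow(tc), 5 * 2)
  expect_equal(names(tc), c("year", "covariate", "q2.5", "q25", "q50",
                            "q75", "q97.5"))
  expect_true(all(sc$q2.5 <= sc$q25 & sc$q25 <= sc$q50 &
                  sc$q50 <= sc$q75 & sc$q75 <= sc$q97.5))
  # centered tables differ from total tables by the global coefficient
  sc0 <- sc_table(fit, total = FALSE)
  expect_false(isTRUE(all.equal(sc0$q50, sc$q50)))
})

test_that("S3 methods expose coefficients, fitted values and residuals", {
  fx <- const_cov_panel(beta = 1.5, sd_eps = 0.05, seed = 50)
  fit <- stvc(fx$panel, fx$weights, chains = 2, iterations = 400,
              burn_in = 100, seed = 50)
  expect_named(coef(fit), "X1")
  expect_equal(dim(fitted(fit)), c(9L, 5L))
  expect_equal(residuals(fit), fit$log_response - fitted(fit))
  expect_output(print(fit), "Bayesian STVC")
  expect_output(print(summary(fit)), "sigma_mu")
})
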