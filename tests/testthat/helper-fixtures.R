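# Shared fixtures and a cross-file memo cache for expensive computations.

.memo <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .memo)) assign(key, force(expr), envir = .memo)
  get(key, envir = .memo)
}

# tiny 4-area x 3-year balanced panel as a long data.frame
tiny_panel_df <- function() {
  grid <- expand.grid(area_id = c("a1", "a2", "a3", "a4"), year = 2001:2003,
                      stringsAsFactors = FALSE)
  grid$region_id <- ifelse(grid$area_id %in% c("a1", "a2"), "north", "south")
  grid$beds <- seq(10, by = 5, length.out = nrow(grid))
  grid$population <- 1000 + seq_len(nrow(grid))
  grid$land_area <- rep(c(5, 6, 7, 8), times = 3)
  grid$X1 <- sin(seq_len(nrow(grid)))
  grid$X2 <- cos(seq_len(nrow(grid)))
  grid[, c("area_id", "region_id", "year", "beds", "population",
           "land_area", "X1", "X2")]
}

write_tiny_panel_csv <- function(df = tiny_panel_df()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# random symmetric graph over n nodes with edge probability p (always
# includes a hamiltonian path so it is connected)
random_connected_weights <- function(n, p = 0.15) {
  A <- matrix(stats::runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  for (i in seq_len(n - 1)) A[i, i + 1] <- TRUE
  A <- A | t(A)
  spatial_weights(apply(A, 1, which, simplify = FALSE))
}

# brute-force Gi* transcription: explicit loops over the defining sums,
# independent of the vectorized implementation
gi_star_bruteforce <- function(values, weights) {
  n <- length(values)
  W <- weights_matrix(weights)
  diag(W) <- 1  # self-inclusive star
  ybar <- sum(values) / n
  s <- sqrt(sum(values^2) / n - ybar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    swy <- 0; sw <- 0; sw2 <- 0
    for (j in seq_len(n)) {
      swy <- swy + W[i, j] * values[j]
      sw <- sw + W[i, j]
      sw2 <- sw2 + W[i, j]^2
    }
    z[i] <- (swy - ybar * sw) / (s * sqrt((n * sw2 - sw^2) / (n - 1)))
  }
  z
}

# brute-force Mann-Kendall S via explicit pair enumeration
mk_S_bruteforce <- function(x) {
  n <- length(x)
  S <- 0L
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) S <- S + sign(x[v] - x[u])
  }
  as.integer(S)
}

# brute-force spatial Gini terms via ordered-pair loops
gini_terms_bruteforce <- function(values, weights) {
  n <- length(values)
  W <- weights_matrix(weights)
  nb <- 0; nonnb <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- abs(values[i] - values[j])
      if (W[i, j] == 1) nb <- nb + d else if (i != j) nonnb <- nonnb + d
    }
  }
  denom <- 2 * n^2 * mean(values)
  list(neighbor = nb / denom, nonneighbor = nonnb / denom,
       total = (nb + nonnb) / denom)
}

# 50-replication STVC recovery study on the 15x15 / T=10 / K=3 fixture
# (sigma_mu = 0.5, sigma_gamma = 0.3, sigma_eps = 0.2). Expensive; memoized
# so the parameter-recovery and variance-partitioning checks share one run.
recovery_study <- function(n_rep = 50) {
  memoize(paste0("recovery", n_rep), {
    res <- list(sc_cor = matrix(NA_real_, n_rep, 3),
                tc_cor = matrix(NA_real_, n_rep, 3),
                cov_mu = matrix(NA, n_rep, 3), cov_ga = matrix(NA, n_rep, 3),
                cov_eps = logical(n_rep),
                space_share = numeric(n_rep), time_share = numeric(n_rep))
    for (r in seq_len(n_rep)) {
      cfg <- sim_config(grid_rows = 15, grid_cols = 15, T = 10, K = 3,
                        sd_mu = 0.5, sd_gamma = 0.3, sd_eps = 0.2,
                        seed = 9000 + r)
      sim <- simulate_panel(cfg)
      fit <- stvc(sim$panel, sim$weights, seed = 9000 + r)
      for (k in 1:3) {
        res$sc_cor[r, k] <- cor(apply(fit$draws$mu[, k, ], 1, median),
                                sim$truth$mu[, k])
        res$tc_cor[r, k] <- cor(apply(fit$draws$gamma[, k, ], 1, median),
                                sim$truth$gamma[, k])
        ci_mu <- quantile(fit$draws$sd_mu[, k], c(0.025, 0.975))
        ci_ga <- quantile(fit$draws$sd_gamma[, k], c(0.025, 0.975))
        res$cov_mu[r, k] <- ci_mu[1] <= 0.5 && 0.5 <= ci_mu[2]
        res$cov_ga[r, k] <- ci_ga[1] <= 0.3 && 0.3 <= ci_ga[2]
      }
      ci_e <- quantile(fit$draws$sd_eps, c(0.025, 0.975))
      res$cov_eps[r] <- ci_e[1] <= 0.2 && 0.2 <= ci_e[2]
      v <- stvpi(fit)
      res$space_share[r] <- v$scales$share[1]
      res$time_share[r] <- v$scales$share[2]
      if (r == 1) res$first_fit <- fit
    }
    res
  })
}
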