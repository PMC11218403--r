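#' Build the STVC model state
#'
#' Precomputes everything the Gibbs sampler needs for the model
#' `log y[i,t] = sum_k (beta_k + mu[i,k] + gamma[t,k]) X[i,t,k] + eps[i,t]`:
#' the log response, standardized covariates, the intrinsic-CAR structure
#' matrix D - W (rank N - 1), the RW2 second-difference penalty (rank
#' T - 2), and per-covariate spectral decompositions of the scaled
#' structure matrices so each coefficient block can be sampled jointly in
#' O(N^2).
#'
#' @param panel an `area_panel` with strictly positive response (the log is
#'   taken; a zero cell is an error — floor or exclude upstream, no silent
#'   jitter is applied).
#' @param weights a connected `spatial_weights` over the panel's areas.
#' @param covariates character vector of covariate names to include
#'   (default: all panel covariates).
#' @param standardize center and scale each covariate to mean 0, SD 1
#'   (constant covariates, e.g. an explicit intercept column, are left
#'   untouched). Default TRUE.
#' @param include_global sample flat-prior global coefficients beta_k
#'   (default TRUE); without them the sum-to-zero constraints would force
#'   each covariate's average effect to zero.
#' @param hyper_a,hyper_b inverse-gamma shape and rate for every variance
#'   component (default 1 and 0.01).
#' @return an object of class `stvc_state`.
#' @export
stvc_build <- function(panel, weights, covariates = NULL, standardize = TRUE,
                       include_global = TRUE, hyper_a = 1, hyper_b = 0.01) {
  stopifnot(inherits(panel, "area_panel"), inherits(weights, "spatial_weights"))
  if (weights$n != length(panel$area_ids))
    stop("weights and panel cover different numbers of areas")
  if (max(weights_components(weights)) > 1L)
    stop("contiguity graph is disconnected; STVC needs a connected graph")
  if (any(panel$response <= 0)) {
    bad <- which(panel$response <= 0, arr.ind = TRUE)[1, ]
    stop("response must be strictly positive for the log link; cell (",
         panel$area_ids[bad[1]], ", ", panel$years[bad[2]],
         ") is <= 0. Floor the index or exclude the cell upstream.")
  }
  all_names <- dimnames(panel$covariates)[[3]]
  if (is.null(covariates)) covariates <- all_names
  miss <- setdiff(covariates, all_names)
  if (length(miss)) stop("unknown covariate: ", miss[1])
  N <- length(panel$area_ids); T <- length(panel$years)
  K <- length(covariates)
  if (K < 1) stop("need at least one covariate")
  z <- log(panel$response)
  X <- panel$covariates[, , covariates, drop = FALSE]
  centers <- numeric(K); scales <- rep(1, K)
  if (standardize) {
    for (k in seq_len(K)) {
      v <- as.vector(X[, , k])
      s <- stats::sd(v)
      if (s > 0) {  # constant columns (intercepts) are left as-is
        centers[k] <- mean(v); scales[k] <- s
        X[, , k] <- (X[, , k] - centers[k]) / scales[k]
      }
    }
  }
  W <- weights_matrix(weights)
  Qs <- diag(rowSums(W)) - W
  D2 <- diff(diag(T), differences = 2)
  Rt <- crossprod(D2)

  spectral <- function(Q, a) {
    # B = A^{-1/2} Q A^{-1/2}; posterior precision diagonalizes over B's basis
    ai <- 1 / sqrt(a)
    B <- Q * tcrossprod(ai)
    eg <- eigen(B, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    list(V = eg$vectors, lam = lam, ainv = ai,
         w = as.vector(crossprod(eg$vectors, ai)))
  }
  floor_a <- function(a) pmax(a, 1e-10 * max(a))
  sp_s <- vector("list", K); sp_t <- vector("list", K)
  for (k in seq_len(K)) {
    sp_s[[k]] <- spectral(Qs, floor_a(rowSums(X[, , k]^2)))
    sp_t[[k]] <- spectral(Rt, floor_a(colSums(X[, , k]^2)))
  }
  structure(list(
    z = z, X = X, covariates = covariates, N = N, T = T, K = K,
    area_ids = panel$area_ids, years = panel$years,
    covariate_group = if (!is.null(panel$covariate_group))
      panel$covariate_group[covariates] else NULL,
    Qs = Qs, Rt = Rt, rank_s = N - 1L, rank_t = T - 2L,
    sp_s = sp_s, sp_t = sp_t,
    standardize = standardize, centers = centers, scales = scales,
    include_global = include_global,
    hyper_a = hyper_a, hyper_b = hyper_b
  ), class = "stvc_state")
}

#' Fit the STVC model by blocked Gibbs sampling
#'
#' Runs `chains` Markov chains from overdispersed starting points. Each
#' iteration jointly samples every space-coefficient field from its
#' Gaussian full conditional (ICAR prior precision plus likelihood
#' diagonal) constrained to sum to zero by conditioning-by-kriging, every
#' time-coefficient path likewise under the RW2 prior, the global
#' coefficients from their Gaussian conditional, and the variance
#' components from conjugate inverse-gamma conditionals.
#'
#' @param state an `stvc_state` from [stvc_build()].
#' @param chains number of chains (>= 2 for convergence diagnostics;
#'   default 4).
#' @param iterations total iterations per chain (default 5000).
#' @param burn_in discarded initial iterations (default 2000).
#' @param thin keep every `thin`-th post-burn-in draw (default 3).
#' @param seed integer seed; the fit is fully reproducible.
#' @param fix_variances optional list with `sd_mu`, `sd_gamma`, `sd_eps` to
#'   hold the variance components fixed (used for exact-posterior
#'   validation); default NULL (sampled).
#' @return an object of class `stvc`; see [stvc()] for its contents.
#' @export
stvc_fit <- function(state, chains = 4, iterations = 5000, burn_in = 2000,
                     thin = 3, seed = 1L, fix_variances = NULL) {
  stopifnot(inherits(state, "stvc_state"))
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (chains < 1) stop("need at least one chain")
  K <- state$K; N <- state$N; T <- state$T
  Vs <- array(0, c(N, N, K)); lam_s <- matrix(0, N, K)
  ainv_s <- matrix(0, N, K); w_s <- matrix(0, N, K)
  Vt <- array(0, c(T, T, K)); lam_t <- matrix(0, T, K)
  ainv_t <- matrix(0, T, K); w_t <- matrix(0, T, K)
  for (k in seq_len(K)) {
    Vs[, , k] <- state$sp_s[[k]]$V; lam_s[, k] <- state$sp_s[[k]]$lam
    ainv_s[, k] <- state$sp_s[[k]]$ainv; w_s[, k] <- state$sp_s[[k]]$w
    Vt[, , k] <- state$sp_t[[k]]$V; lam_t[, k] <- state$sp_t[[k]]$lam
    ainv_t[, k] <- state$sp_t[[k]]$ainv; w_t[, k] <- state$sp_t[[k]]$w
  }
  fixed <- !is.null(fix_variances)
  set.seed(seed)
  chain_seeds <- sample.int(2^30, chains)
  start_sd <- c(0.1, 1, 0.3, 3)  # overdispersed variance starts, recycled
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    s0 <- start_sd[(ch - 1L) %% length(start_sd) + 1L]
    beta0 <- if (state$include_global) stats::rnorm(K, 0, 1) else numeric(K)
    s_mu0 <- rep(s0, K); s_ga0 <- rep(s0, K); s_eps0 <- s0
    if (fixed) {
      s_mu0 <- rep_len(fix_variances$sd_mu, K)
      s_ga0 <- rep_len(fix_variances$sd_gamma, K)
      s_eps0 <- fix_variances$sd_eps
    }
    res[[ch]] <- stvc_gibbs_chain(
      state$z, state$X, Vs, lam_s, ainv_s, w_s, Vt, lam_t, ainv_t, w_t,
      state$Qs, state$Rt, state$rank_s, state$rank_t,
      state$hyper_a, state$hyper_b, state$include_global,
      as.integer(iterations), as.integer(burn_in), as.integer(thin),
      beta0, s_mu0, s_ga0, s_eps0, fixed)
  }
  n_keep <- res[[1]]$n_keep
  bind_mat <- function(name) do.call(rbind, lapply(res, `[[`, name))
  bind_cube <- function(name) {
    arr <- lapply(res, `[[`, name)
    out <- array(0, c(dim(arr[[1]])[1:2], chains * n_keep))
    for (ch in seq_len(chains))
      out[, , (ch - 1L) * n_keep + seq_len(n_keep)] <- arr[[ch]]
    out
  }
  draws <- list(
    beta = bind_mat("beta"),
    mu = bind_cube("mu"),
    gamma = bind_cube("gamma"),
    sd_mu = bind_mat("sd_mu"),
    sd_gamma = bind_mat("sd_gamma"),
    sd_eps = matrix(unlist(lapply(res, `[[`, "sd_eps")), ncol = 1))
  colnames(draws$beta) <- colnames(draws$sd_mu) <- colnames(draws$sd_gamma) <-
    state$covariates
  dimnames(draws$mu) <- list(state$area_ids, state$covariates, NULL)
  dimnames(draws$gamma) <- list(as.character(state$years), state$covariates, NULL)

  # convergence diagnostics on the scalar parameters
  scalar_chains <- function(name, col) {
    sapply(res, function(r) as.matrix(r[[name]])[, col])
  }
  diag_names <- c(paste0("beta.", state$covariates),
                  paste0("sd_mu.", state$covariates),
                  paste0("sd_gamma.", state$covariates), "sd_eps")
  diag_list <- c(lapply(seq_len(K), function(k) scalar_chains("beta", k)),
                 lapply(seq_len(K), function(k) scalar_chains("sd_mu", k)),
                 lapply(seq_len(K), function(k) scalar_chains("sd_gamma", k)),
                 list(scalar_chains("sd_eps", 1)))
  rhat <- vapply(diag_list, split_rhat, numeric(1))
  ess <- vapply(diag_list, function(m) sum(apply(m, 2, ess_one)), numeric(1))
  names(rhat) <- names(ess) <- diag_names
  var_rhat <- rhat[grepl("^sd_", diag_names)]
  converged <- all(is.finite(var_rhat)) && all(var_rhat <= 1.1)
  if (!converged)
    warning("non-convergence flagged: R-hat > 1.1 on a variance component")

  fitted <- Reduce(`+`, lapply(res, `[[`, "eta_mean")) / chains
  dimnames(fitted) <- dimnames(state$z)
  structure(list(
    draws = draws, rhat = rhat, ess = ess, converged = converged,
    fitted = fitted, residuals = state$z - fitted,
    log_response = state$z,
    covariates = state$covariates, covariate_group = state$covariate_group,
    area_ids = state$area_ids, years = state$years,
    include_global = state$include_global,
    standardize = state$standardize, centers = state$centers,
    scales = state$scales,
    chains = chains, iterations = iterations, burn_in = burn_in,
    thin = thin, seed = seed, n_draws = chains * n_keep,
    fixed_variances = if (fixed) fix_variances else NULL
  ), class = "stvc")
}

#' Fit a Bayesian spatiotemporally varying coefficients model
#'
#' One-call interface: builds the model state ([stvc_build()]) and runs the
#' blocked Gibbs sampler ([stvc_fit()]). The model is
#' `log y[i,t] = sum_k (beta_k + mu[i,k] + gamma[t,k]) X[i,t,k] + eps[i,t]`
#' with an intrinsic CAR prior on each space-coefficient field mu[,k], an
#' RW2 prior on each time-coefficient path gamma[,k] (both sum-to-zero),
#' flat priors on the global levels beta_k, and inverse-gamma priors on
#' the variance components (sigma_mu_k, sigma_gamma_k, sigma_eps).
#'
#' @inheritParams stvc_build
#' @inheritParams stvc_fit
#' @param ... passed to [stvc_fit()].
#' @return an object of class `stvc` with posterior `draws` (`beta`,
#'   `mu` N x K x draws, `gamma` T x K x draws, `sd_mu`, `sd_gamma`,
#'   `sd_eps`, all SDs on the standard-deviation scale), split R-hat and
#'   effective sample sizes for the scalar parameters, a `converged` flag
#'   (R-hat <= 1.1 on every variance), posterior-mean `fitted` values and
#'   `residuals` on the log scale.
#' @seealso [sc_table()], [tc_table()], [stvpi()]
#' @examples
#' \donttest{
#' sim <- simulate_panel(sim_config(grid_rows = 5, grid_cols = 5, T = 6,
#'                                  K = 1, seed = 7))
#' fit <- stvc(sim$panel, sim$weights, chains = 2, iterations = 600,
#'             burn_in = 200, seed = 7)
#' summary(fit)
#' }
#' @export
stvc <- function(panel, weights, covariates = NULL, standardize = TRUE,
                 include_global = TRUE, hyper_a = 1, hyper_b = 0.01, ...) {
  state <- stvc_build(panel, weights, covariates, standardize,
                      include_global, hyper_a, hyper_b)
  stvc_fit(state, ...)
}

# split-R-hat over a (draws x chains) matrix
split_rhat <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  half <- floor(n / 2)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[n - half + seq_len(half), , drop = FALSE])
  cm <- colMeans(sub)
  W <- mean(apply(sub, 2, stats::var))
  B <- half * stats::var(cm)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size of one chain via Geyer's initial positive sequence
ess_one <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  if (length(ac) %% 2 == 1) ac <- ac[-length(ac)]
  pair <- ac[seq(1, length(ac), by = 2)] + ac[seq(2, length(ac), by = 2)]
  neg <- which(pair <= 0)
  if (length(neg)) pair <- pair[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(pmax(pair, 0)))
}

#' @export
print.stvc <- function(x, ...) {
  cat("Bayesian STVC model fit (blocked Gibbs)\n")
  cat(sprintf("  %d areas x %d years, %d covariate(s): %s\n",
              length(x$area_ids), length(x$years), length(x$covariates),
              paste(x$covariates, collapse = ", ")))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d draws\n",
              x$chains, x$iterations, x$burn_in, x$thin, x$n_draws))
  cat("  converged:", x$converged,
      sprintf("(max variance R-hat %.3f)\n",
              max(x$rhat[grepl("^sd_", names(x$rhat))])))
  if (x$include_global) {
    cat("  global coefficients (posterior mean):\n")
    print(round(colMeans(x$draws$beta), 4))
  }
  invisible(x)
}

#' @export
summary.stvc <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  qtab <- function(m) t(apply(as.matrix(m), 2, function(v)
    c(mean = mean(v), stats::quantile(v, probs))))
  out <- list(
    beta = if (object$include_global) qtab(object$draws$beta) else NULL,
    sd_mu = qtab(object$draws$sd_mu),
    sd_gamma = qtab(object$draws$sd_gamma),
    sd_eps = qtab(object$draws$sd_eps),
    rhat = object$rhat, ess = object$ess, converged = object$converged)
  class(out) <- "summary.stvc"
  out
}

#' @export
print.summary.stvc <- function(x, ...) {
  if (!is.null(x$beta)) { cat("Global coefficients:\n"); print(round(x$beta, 4)) }
  cat("\nSpace-coefficient SDs (sigma_mu):\n"); print(round(x$sd_mu, 4))
  cat("\nTime-coefficient SDs (sigma_gamma):\n"); print(round(x$sd_gamma, 4))
  cat("\nResidual SD (sigma_eps):\n"); print(round(x$sd_eps, 4))
  cat("\nConverged:", x$converged, "| max R-hat:",
      round(max(x$rhat), 3), "\n")
  invisible(x)
}

#' @export
coef.stvc <- function(object, ...) {
  if (!object$include_global) return(numeric(0))
  colMeans(object$draws$beta)
}

#' @export
fitted.stvc <- function(object, ...) object$fitted

#' @export
residuals.stvc <- function(object, ...) object$residuals

#' Plot posterior time-coefficient paths
#'
#' Draws each covariate's time-coefficient path (posterior median) with
#' narrow (25-75%) and wide (2.5-97.5%) credible bands.
#'
#' @param x an `stvc` fit.
#' @param total add the global coefficient to each path (default TRUE).
#' @param ... passed to `matplot`-level graphics.
#' @export
plot.stvc <- function(x, total = TRUE, ...) {
  tc <- tc_table(x, total = total)
  ks <- unique(tc$covariate)
  old <- graphics::par(mfrow = c(1, length(ks)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in ks) {
    s <- tc[tc$covariate == k, ]
    yl <- range(s$q2.5, s$q97.5)
    plot(s$year, s$q50, type = "n", ylim = yl, xlab = "year",
         ylab = "time-coefficient", main = k, ...)
    graphics::polygon(c(s$year, rev(s$year)), c(s$q2.5, rev(s$q97.5)),
                      col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
    graphics::polygon(c(s$year, rev(s$year)), c(s$q25, rev(s$q75)),
                      col = grDevices::adjustcolor("steelblue", 0.4), border = NA)
    graphics::lines(s$year, s$q50, lwd = 2, col = "steelblue4")
  }
  invisible(x)
}

#' Space-coefficient posterior table
#'
#' Posterior quantiles (2.5/25/50/75/97.5%) of each area's space
#' coefficient for each covariate.
#'
#' @param fit an `stvc` object.
#' @param total report `beta_k + mu[i,k]` (the total local spatial effect,
#'   default TRUE); `FALSE` reports the centered field alone.
#' @return data.frame with columns `area`, `covariate`, `q2.5`, `q25`,
#'   `q50`, `q75`, `q97.5`.
#' @export
sc_table <- function(fit, total = TRUE) {
  stopifnot(inherits(fit, "stvc"))
  coef_tab(fit, fit$draws$mu, fit$area_ids, "area", total)
}

#' Time-coefficient posterior table
#'
#' Posterior quantiles (2.5/25/50/75/97.5%) of each year's time
#' coefficient for each covariate.
#'
#' @param fit an `stvc` object.
#' @param total report `beta_k + gamma[t,k]` (default TRUE) or the
#'   centered path alone.
#' @return data.frame with columns `year`, `covariate`, `q2.5`, `q25`,
#'   `q50`, `q75`, `q97.5`.
#' @export
tc_table <- function(fit, total = TRUE) {
  stopifnot(inherits(fit, "stvc"))
  out <- coef_tab(fit, fit$draws$gamma, as.character(fit$years), "year", total)
  out$year <- as.integer(out$year)
  out
}

coef_tab <- function(fit, arr, unit_ids, unit_name, total) {
  K <- length(fit$covariates)
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  rows <- list()
  for (k in seq_len(K)) {
    d <- arr[, k, , drop = FALSE][, 1, ]  # units x draws
    if (total && fit$include_global)
      d <- sweep(d, 2, fit$draws$beta[, k], "+")
    q <- t(apply(d, 1, stats::quantile, probs = probs))
    df <- data.frame(u = unit_ids, covariate = fit$covariates[k],
                     q[, 1], q[, 2], q[, 3], q[, 4], q[, 5],
                     stringsAsFactors = FALSE, row.names = NULL)
    names(df) <- c(unit_name, "covariate", "q2.5", "q25", "q50", "q75", "q97.5")
    rows[[k]] <- df
  }
  do.call(rbind, rows)
}
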