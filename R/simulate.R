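#' Simulation configuration for synthetic areal panels
#'
#' Bundles the generative settings for [simulate_panel()]: lattice size and
#' contiguity, number of years and covariates, region partitioning, the
#' standard deviations of the intrinsic-CAR space-coefficient fields
#' (`sd_mu`), of the second-order random-walk time-coefficient paths
#' (`sd_gamma`), the global coefficient levels (`beta`), and the residual
#' SD (`sd_eps`).
#'
#' @param grid_rows,grid_cols lattice dimensions; N = rows x cols >= 9.
#' @param T number of years (>= 4; the RW2 prior needs at least 3
#'   increments).
#' @param K number of covariates.
#' @param contiguity `"rook"` or `"queen"`.
#' @param region_blocks number of blocks along each lattice axis; regions
#'   are contiguous square-ish blocks (region count = region_blocks^2,
#'   mimicking provinces containing many counties).
#' @param sd_mu,sd_gamma length-K non-negative SDs (recycled if scalar).
#' @param beta length-K global coefficient levels (recycled if scalar).
#' @param sd_eps non-negative residual SD.
#' @param covariate_model `"iid_normal"` or `"spatially_smoothed"` (iid
#'   fields averaged over the contiguity star, then an AR(1) blend over
#'   years, re-standardized).
#' @param seed integer seed; every draw in [simulate_panel()] derives from
#'   it, so identical configs give identical panels.
#' @return a `sim_config` list.
#' @export
sim_config <- function(grid_rows = 15, grid_cols = 15, T = 10, K = 3,
                       contiguity = "rook", region_blocks = 2,
                       sd_mu = 0.5, sd_gamma = 0.3, beta = 1,
                       sd_eps = 0.2, covariate_model = "spatially_smoothed",
                       seed = 1L) {
  N <- grid_rows * grid_cols
  if (N < 9) stop("lattice must have at least 9 cells")
  if (T < 4) stop("T must be >= 4 (RW2 needs >= 3 increments)")
  sd_mu <- rep_len(sd_mu, K); sd_gamma <- rep_len(sd_gamma, K)
  beta <- rep_len(beta, K)
  if (any(c(sd_mu, sd_gamma, sd_eps) < 0)) stop("SDs must be >= 0")
  covariate_model <- match.arg(covariate_model,
                               c("iid_normal", "spatially_smoothed"))
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols, T = T, K = K,
                 contiguity = contiguity, region_blocks = region_blocks,
                 sd_mu = sd_mu, sd_gamma = sd_gamma, beta = beta,
                 sd_eps = sd_eps, covariate_model = covariate_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw an intrinsic CAR (ICAR) field on a contiguity graph
#'
#' Samples from the intrinsic conditional autoregressive prior with
#' precision `(D - W) / sd^2` restricted to the sum-to-zero subspace: the
#' draw is built on the positive-eigenvalue eigenvectors of the structure
#' matrix `D - W`, so the field sums to zero by construction and its
#' covariance is `sd^2` times the Moore-Penrose pseudo-inverse of `D - W`.
#'
#' @param weights a `spatial_weights` object; the graph must be connected.
#' @param sd conditional-scale standard deviation (sigma_mu); `sd = 0`
#'   returns the zero field.
#' @param seed optional integer seed.
#' @return numeric vector of length `weights$n` summing to zero (|sum| <
#'   1e-10).
#' @export
simulate_icar_field <- function(weights, sd, seed = NULL) {
  stopifnot(inherits(weights, "spatial_weights"))
  comp <- weights_components(weights)
  if (max(comp) > 1L)
    stop("graph is disconnected (", max(comp), " components); component sizes: ",
         paste(tabulate(comp), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- weights$n
  if (sd == 0) return(numeric(n))
  eg <- icar_spectrum(weights)
  z <- stats::rnorm(n - 1L)
  f <- as.vector(eg$vectors %*% (z / sqrt(eg$values))) * sd
  f - mean(f)  # numerical tidy-up; eigenvectors are already orthogonal to 1
}

# eigendecomposition of the ICAR structure matrix D - W, zero mode removed
icar_spectrum <- function(weights) {
  W <- weights_matrix(weights)
  Q <- diag(rowSums(W)) - W
  eg <- eigen(Q, symmetric = TRUE)
  keep <- seq_len(weights$n - 1L)  # drop the constant null vector (last)
  list(values = eg$values[keep], vectors = eg$vectors[, keep, drop = FALSE])
}

#' Draw a second-order random-walk (RW2) path
#'
#' Second differences `g[t] - 2 g[t-1] + g[t-2]` are iid N(0, sd^2); the
#' path is centered to sum to zero (its level belongs to the global
#' coefficient, and the linear component is left free, matching the
#' intrinsic-prior convention).
#'
#' @param T path length (>= 4).
#' @param sd innovation standard deviation (sigma_gamma).
#' @param seed optional integer seed.
#' @return numeric vector of length `T` summing to zero.
#' @export
simulate_rw2_path <- function(T, sd, seed = NULL) {
  if (T < 4) stop("T must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(numeric(T))
  inc <- stats::rnorm(T - 2L, sd = sd)
  g <- numeric(T)
  for (t in 3:T) g[t] <- 2 * g[t - 1] - g[t - 2] + inc[t - 2L]
  g - mean(g)
}

#' Simulate a synthetic areal panel with known spatiotemporal structure
#'
#' Generates covariates, ICAR space-coefficient fields mu[,k], RW2
#' time-coefficient paths gamma[,k], and iid residuals, and sets
#' `log y[i,t] = sum_k (beta_k + mu[i,k] + gamma[t,k]) X[i,t,k] + eps[i,t]`,
#' i.e. a log-Gaussian response under a spatiotemporally varying
#' coefficients structure. Population and land area are drawn log-normal
#' and a raw resource (beds) column is back-solved so that
#' [compute_hrdi()] on (beds, population, land_area) reproduces `y`
#' exactly. Covariates are standardized to mean 0, SD 1 after generation
#' so coefficient scales are comparable.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (an `area_panel` whose response is the HRDI
#'   scale y and which carries the back-solved `beds` in
#'   `attr(panel, "beds")`), `weights`, and `truth` (list: `beta`, `mu`
#'   N x K, `gamma` T x K, `sd_mu`, `sd_gamma`, `sd_eps`, `log_response`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$grid_rows * config$grid_cols
  T <- config$T; K <- config$K
  w <- lattice_weights(config$grid_rows, config$grid_cols, config$contiguity)

  # contiguous block regions ("provinces")
  rb <- config$region_blocks
  row_blk <- pmin(ceiling(seq_len(config$grid_rows) / (config$grid_rows / rb)), rb)
  col_blk <- pmin(ceiling(seq_len(config$grid_cols) / (config$grid_cols / rb)), rb)
  region_of <- sprintf("R%d%d", rep(row_blk, each = config$grid_cols),
                       rep(col_blk, times = config$grid_rows))

  # covariates
  X <- array(stats::rnorm(N * T * K), dim = c(N, T, K),
             dimnames = list(w$ids, NULL, paste0("X", seq_len(K))))
  if (config$covariate_model == "spatially_smoothed") {
    for (k in seq_len(K)) {
      for (t in seq_len(T)) {
        v <- X[, t, k]
        X[, t, k] <- vapply(seq_len(N), function(i)
          mean(v[c(i, w$neighbors[[i]])]), numeric(1))
      }
      for (t in 2:T) X[, t, k] <- 0.7 * X[, t - 1, k] + 0.3 * X[, t, k]
    }
  }
  for (k in seq_len(K)) {
    v <- as.vector(X[, , k])
    X[, , k] <- (X[, , k] - mean(v)) / stats::sd(v)
  }

  mu <- sapply(seq_len(K), function(k) simulate_icar_field(w, config$sd_mu[k]))
  gamma <- sapply(seq_len(K), function(k) simulate_rw2_path(T, config$sd_gamma[k]))
  mu <- matrix(mu, N, K); gamma <- matrix(gamma, T, K)
  eps <- matrix(stats::rnorm(N * T, sd = config$sd_eps), N, T)

  logy <- eps
  for (k in seq_len(K)) {
    coef_ik <- outer(mu[, k], gamma[, k], "+") + config$beta[k]  # N x T
    logy <- logy + coef_ik * X[, , k]
  }
  if (any(!is.finite(exp(logy))))
    stop("non-finite response (overflow); use smaller coefficient/noise SDs")
  y <- exp(logy)

  population <- matrix(stats::rlnorm(N * T, meanlog = 10, sdlog = 0.5), N, T)
  land_area <- stats::rlnorm(N, meanlog = 7, sdlog = 0.4)
  beds <- y * sqrt((population / 1000) * land_area)
  dimnames(beds) <- list(w$ids, as.character(seq_len(T)))

  grp <- stats::setNames(
    rep(c("socioeconomic", "environmental"), length.out = max(K, 1))[seq_len(K)],
    dimnames(X)[[3]])
  panel <- area_panel(y, population, land_area, region_of,
                      covariates = X, area_ids = w$ids, years = seq_len(T),
                      covariate_group = if (K > 0) grp else NULL)
  attr(panel, "beds") <- beds
  attr(panel, "response_unit") <- "hrdi"
  list(panel = panel, weights = w,
       truth = list(beta = config$beta, mu = mu, gamma = gamma,
                    sd_mu = config$sd_mu, sd_gamma = config$sd_gamma,
                    sd_eps = config$sd_eps, log_response = logy))
}

#' Deterministic hot/cold spot fixture panel
#'
#' A 14 x 14 lattice, 10-year panel built to exercise the emerging-pattern
#' classifier deterministically: a persistent 3 x 3 high-value block whose
#' intensity rises year over year (classifies as intensifying hot), a
#' block that turns high only in the final year (new hot), and a block
#' that turns and stays low from year 4 through the final year
#' (consecutive cold). The background is a unit-SD seeded noise field
#' around a flat surface, leaving every non-block cell without a pattern.
#'
#' @param T number of years (default 10).
#' @param seed seed for the background jitter.
#' @return list with `panel`, `weights`, and `blocks` (index vectors
#'   `hot`, `new`, `cold`, plus the block `centers`).
#' @export
simulate_hotspot_panel <- function(T = 10, seed = 99L) {
  rows <- 14L; cols <- 14L; N <- rows * cols
  w <- lattice_weights(rows, cols, "rook")
  set.seed(seed)
  cell <- function(r, c) (r - 1L) * cols + c
  block <- function(rs, cs) as.vector(outer(rs, cs, cell))
  hot <- block(1:3, 1:3)                     # rising high plateau
  new <- block(1:3, (cols - 2L):cols)        # high in the final year only
  cold <- block((rows - 2L):rows, 1:3)       # low plateau from year 4
  vals <- matrix(10, N, T) + matrix(stats::rnorm(N * T, sd = 1), N, T)
  for (t in seq_len(T)) vals[hot, t] <- 11 + t
  vals[new, T] <- 18
  for (t in 4:T) vals[cold, t] <- 4
  region_of <- rep(c("R1", "R2"), each = N / 2)
  population <- matrix(1000, N, T)
  land_area <- rep(1, N)
  panel <- area_panel(vals, population, land_area, region_of,
                      area_ids = w$ids, years = seq_len(T))
  centers <- list(hot = cell(2L, 2L), new = cell(2L, cols - 1L),
                  cold = cell(rows - 1L, 2L))
  list(panel = panel, weights = w,
       blocks = list(hot = hot, new = new, cold = cold, centers = centers))
}
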