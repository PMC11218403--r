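#' Spatiotemporal variance partitioning index (STVPI)
#'
#' Attributes the explainable spatiotemporal variation to each factor on
#' the standard-deviation scale. Per posterior draw, with denominator
#' `D = sum_k (sigma_mu_k + sigma_gamma_k) + sigma_eps`, the k-th factor's
#' share is `rho_k = 100 * (sigma_mu_k + sigma_gamma_k) / D`; its
#' space-scale and time-scale shares are `100 * sigma_mu_k / D` and
#' `100 * sigma_gamma_k / D`; group shares sum rho_k over each covariate
#' group; the overall space and time scale shares sum the per-factor
#' scale shares; the model share is `100 - 100 * sigma_eps / D`. Shares
#' are computed per draw and then summarized (posterior mean point
#' estimates, 2.5/97.5% credible bounds), so the joint posterior
#' dependence of the components propagates into the intervals.
#'
#' Per draw the shares satisfy `sum_k rho_k + residual = 100` and
#' `space + time + residual = 100` exactly.
#'
#' @param fit an `stvc` fit (or any list with draw matrices `sd_mu`,
#'   `sd_gamma` (draws x K) and `sd_eps` (draws x 1)).
#' @param grouping named character vector mapping each covariate to
#'   `"socioeconomic"` or `"environmental"`; defaults to the grouping
#'   stored in the fit. Required for group shares.
#' @return object of class `stvpi`: list of data.frames `factors`
#'   (per-factor total/space/time shares with CIs), `groups`, `scales`
#'   (space, time, residual), `model` (model vs residual share), and the
#'   per-draw share matrices in `draws`.
#' @export
stvpi <- function(fit, grouping = NULL) {
  sd_mu <- as.matrix(fit$draws$sd_mu)
  sd_ga <- as.matrix(fit$draws$sd_gamma)
  sd_eps <- as.vector(fit$draws$sd_eps)
  K <- ncol(sd_mu)
  cov_names <- colnames(sd_mu)
  if (is.null(cov_names)) cov_names <- paste0("X", seq_len(K))
  if (is.null(grouping)) grouping <- fit$covariate_group
  if (!is.null(grouping)) {
    miss <- setdiff(cov_names, names(grouping))
    if (length(miss)) stop("no group assignment for covariate: ", miss[1])
    grouping <- grouping[cov_names]
  }
  D <- rowSums(sd_mu) + rowSums(sd_ga) + sd_eps
  rho <- 100 * (sd_mu + sd_ga) / D          # draws x K
  space_k <- 100 * sd_mu / D
  time_k <- 100 * sd_ga / D
  resid <- 100 * sd_eps / D
  space <- rowSums(space_k); time <- rowSums(time_k)
  model <- 100 - resid

  ci <- function(v) stats::quantile(v, c(0.025, 0.975))
  summ <- function(m, labels) {
    m <- as.matrix(m)
    data.frame(name = labels,
               share = colMeans(m),
               lower = apply(m, 2, function(v) ci(v)[1]),
               upper = apply(m, 2, function(v) ci(v)[2]),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  factors <- cbind(summ(rho, cov_names),
                   space_share = colMeans(space_k),
                   time_share = colMeans(time_k))
  groups <- NULL
  if (!is.null(grouping)) {
    gnames <- sort(unique(grouping))
    gm <- sapply(gnames, function(g)
      rowSums(rho[, grouping == g, drop = FALSE]))
    groups <- summ(gm, gnames)
  }
  scales <- summ(cbind(space, time, resid), c("space", "time", "residual"))
  model_tab <- summ(cbind(model, resid), c("model", "residual"))
  structure(list(factors = factors, groups = groups, scales = scales,
                 model = model_tab,
                 draws = list(rho = rho, space_k = space_k, time_k = time_k,
                              residual = resid)),
            class = "stvpi")
}

#' @export
print.stvpi <- function(x, ...) {
  cat("Spatiotemporal variance partitioning (posterior mean %, 95% CI):\n")
  cat(sprintf("  model %.2f%% [%.2f, %.2f] | residual %.2f%% [%.2f, %.2f]\n",
              x$model$share[1], x$model$lower[1], x$model$upper[1],
              x$model$share[2], x$model$lower[2], x$model$upper[2]))
  cat(sprintf("  space %.2f%% | time %.2f%%\n",
              x$scales$share[1], x$scales$share[2]))
  cat("  per-factor shares:\n")
  print(data.frame(x$factors[, c("name", "share", "lower", "upper")],
                   row.names = NULL), digits = 4)
  invisible(x)
}

#' Rank spatiotemporal determinants by explained share
#'
#' Sorts factors by posterior-mean STVPI share (descending) and returns
#' the shortest prefix whose cumulative share reaches
#' `cumulative_threshold`. If the threshold exceeds the total model share
#' all factors are returned with a warning.
#'
#' @param result an `stvpi` object.
#' @param cumulative_threshold percentage of variation the selected
#'   determinants must jointly explain (default 84).
#' @return data.frame of the selected determinants: `name`, `share`,
#'   `lower`, `upper`, `cumulative`.
#' @export
rank_determinants <- function(result, cumulative_threshold = 84) {
  stopifnot(inherits(result, "stvpi"))
  f <- result$factors[order(-result$factors$share), ]
  f$cumulative <- cumsum(f$share)
  total <- sum(result$factors$share)
  if (cumulative_threshold > total) {
    warning(sprintf(
      "threshold %.2f%% exceeds the total model share %.2f%%; returning all factors",
      cumulative_threshold, total))
    rownames(f) <- NULL
    return(f)
  }
  keep <- seq_len(which(f$cumulative >= cumulative_threshold)[1])
  out <- f[keep, ]
  rownames(out) <- NULL
  out
}
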