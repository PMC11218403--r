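#' Classical Gini coefficient
#'
#' `G = sum_i sum_j |y_i - y_j| / (2 n^2 ybar)` over all ordered pairs.
#' Scale-invariant; 0 means perfect equality.
#'
#' @param values numeric vector of non-negative values, n >= 2, mean > 0.
#' @return Gini coefficient in [0, 1).
#' @examples
#' classical_gini(c(1, 2, 3, 4))  # 0.25
#' @export
classical_gini <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (any(!is.finite(values)) || any(values < 0)) stop("values must be finite and >= 0")
  m <- mean(values)
  if (m <= 0) stop("mean of values must be > 0")
  sum(abs(outer(values, values, "-"))) / (2 * n^2 * m)
}

#' Neighbor / non-neighbor spatial Gini decomposition
#'
#' Splits the Gini double sum into the part contributed by neighbor pairs
#' (binary contiguity weight 1) and by non-neighbor pairs, over ordered
#' pairs (the i = j terms are zero either way). The two components add
#' exactly to the classical Gini of the same values.
#'
#' @param values numeric vector (one value per area), n >= 2, mean > 0.
#' @param weights a `spatial_weights` object over the same areas.
#' @return list with `neighbor`, `nonneighbor`, `total`, and
#'   `neighbor_share_pct` (100 * neighbor / total; `NA` when total is 0).
#' @examples
#' w <- spatial_weights(list(2L, c(1L, 3L), 2L))  # path 1-2-3
#' spatial_gini_decompose(c(1, 2, 4), w)
#' @export
spatial_gini_decompose <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(values)
  if (n != weights$n) stop("values/weights length mismatch: ", n, " vs ", weights$n)
  if (n < 2) stop("need at least 2 areas")
  m <- mean(values)
  if (m <= 0) stop("mean of values must be > 0")
  denom <- 2 * n^2 * m
  nb_sum <- 0
  for (i in seq_len(n)) {
    js <- weights$neighbors[[i]]
    if (length(js)) nb_sum <- nb_sum + sum(abs(values[i] - values[js]))
  }
  tot_sum <- sum(abs(outer(values, values, "-")))
  neighbor <- nb_sum / denom
  total <- tot_sum / denom
  nonneighbor <- (tot_sum - nb_sum) / denom
  share <- if (total > 0) min(100, max(0, 100 * neighbor / total)) else NA_real_
  list(neighbor = neighbor, nonneighbor = nonneighbor, total = total,
       neighbor_share_pct = share)
}

#' Spatial Gini decomposition per region and year
#'
#' Applies [spatial_gini_decompose()] within each region (adjacency
#' restricted to within-region pairs) for every year of the panel.
#' Singleton regions are skipped with a warning.
#'
#' @param panel an `area_panel`.
#' @param weights a `spatial_weights` object over the panel's areas (same
#'   order).
#' @return data.frame with columns `region`, `year`, `neighbor`,
#'   `nonneighbor`, `total`, `neighbor_share_pct`, `n_areas`; attribute
#'   `region_means` holds each region's mean total Gini over years, and
#'   attribute `skipped` any skipped singleton regions.
#' @export
gini_by_region_year <- function(panel, weights) {
  stopifnot(inherits(panel, "area_panel"), inherits(weights, "spatial_weights"))
  if (weights$n != length(panel$area_ids))
    stop("weights and panel cover different numbers of areas")
  regions <- sort(unique(panel$region_of))
  skipped <- character(0)
  rows <- list()
  for (rg in regions) {
    idx <- which(panel$region_of == rg)
    if (length(idx) < 2) {
      warning("region ", rg, " has a single area; skipped")
      skipped <- c(skipped, rg)
      next
    }
    wr <- subset_weights(weights, idx)
    for (ti in seq_along(panel$years)) {
      d <- spatial_gini_decompose(panel$response[idx, ti], wr)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, year = panel$years[ti],
        neighbor = d$neighbor, nonneighbor = d$nonneighbor, total = d$total,
        neighbor_share_pct = d$neighbor_share_pct,
        n_areas = length(idx), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  means <- tapply(out$total, out$region, mean)
  attr(out, "region_means") <- means
  attr(out, "skipped") <- skipped
  out
}

#' Theil-Sen slope
#'
#' Median of all pairwise slopes (x[v] - x[u]) / (v - u), u < v.
#'
#' @param x numeric series; `t` optional time points (default 1..T).
#' @param t time coordinates.
#' @return slope per unit time.
#' @export
theil_sen_slope <- function(x, t = seq_along(x)) {
  n <- length(x)
  if (n < 2) stop("need at least 2 points")
  ij <- utils::combn(n, 2)
  stats::median((x[ij[2, ]] - x[ij[1, ]]) / (t[ij[2, ]] - t[ij[1, ]]))
}

#' Temporal trend of a regional Gini series
#'
#' Mann-Kendall test plus Theil-Sen slope on a per-region series of total
#' Gini values. Verdict is `decreasing` if p < alpha and slope < 0,
#' `increasing` if p < alpha and slope > 0, else `none` (a constant series
#' gives z = 0, p = 1, verdict `none`).
#'
#' @param series numeric vector of yearly Gini totals (length >= 4).
#' @param alpha significance level (default 0.05).
#' @return list with `slope_per_year`, `mann_kendall_z`, `p_value`,
#'   `verdict`.
#' @export
gini_trend <- function(series, alpha = 0.05) {
  if (length(series) < 4) stop("need at least 4 years for a trend verdict")
  mk <- mann_kendall(series)
  slope <- theil_sen_slope(series)
  verdict <- if (mk$p < alpha && slope < 0) "decreasing"
             else if (mk$p < alpha && slope > 0) "increasing"
             else "none"
  list(slope_per_year = slope, mann_kendall_z = mk$z, p_value = mk$p,
       verdict = verdict)
}

#' Trend verdicts for all regions
#'
#' @param gini_table output of [gini_by_region_year()].
#' @param alpha significance level.
#' @return data.frame of per-region slope, Mann-Kendall z, p, verdict, plus
#'   attribute `summary`: counts and percentages (2-decimal, half-up) of
#'   decreasing / increasing / none regions.
#' @export
gini_trends_by_region <- function(gini_table, alpha = 0.05) {
  regions <- unique(gini_table$region)
  rows <- lapply(regions, function(rg) {
    s <- gini_table[gini_table$region == rg, ]
    s <- s[order(s$year), ]
    tr <- gini_trend(s$total, alpha)
    data.frame(region = rg, slope_per_year = tr$slope_per_year,
               mann_kendall_z = tr$mann_kendall_z, p_value = tr$p_value,
               verdict = tr$verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  counts <- table(factor(out$verdict, levels = c("decreasing", "increasing", "none")))
  attr(out, "summary") <- list(
    counts = as.list(as.integer(counts)) |> stats::setNames(names(counts)),
    percentages = lapply(as.integer(counts), function(k)
      round_half_up(100 * k / nrow(out), 2)) |> stats::setNames(names(counts)))
  out
}

# round half up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
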