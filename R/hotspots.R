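#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test. `S = sum_{u<v} sign(x_v - x_u)`;
#' the variance uses the tie correction
#' `var_S = [n(n-1)(2n+5) - sum_g t_g(t_g-1)(2t_g+5)] / 18` over tie groups
#' g, and the continuity-corrected normal score is `z = (S-1)/sqrt(var_S)`
#' for S > 0, `(S+1)/sqrt(var_S)` for S < 0, and 0 at S = 0. The p-value
#' is two-sided normal. An all-tied series returns S = 0, z = 0, p = 1.
#'
#' @param x numeric series (length >= 4 for a meaningful test; length >= 2
#'   accepted).
#' @return list with `S` (integer), `var_S`, `z`, `p`.
#' @examples
#' mann_kendall(c(1, 2, 3, 4, 5))$S  # 10
#' @export
mann_kendall <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])  # d[v,u] = sign(x_v - x_u) for v > u
  ties <- table(x)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (S > 0) (S - 1) / sqrt(var_S)
       else if (S < 0) (S + 1) / sqrt(var_S)
       else 0
  if (var_S == 0) z <- 0  # all values tied
  p <- if (z == 0) 1 else 2 * stats::pnorm(-abs(z))
  list(S = as.integer(S), var_S = var_S, z = z, p = p)
}

#' Getis-Ord Gi* z-scores for one cross-section
#'
#' Self-inclusive local statistic under binary contiguity: with star set
#' J(i) = neighbors of i plus i itself (all weights 1),
#' `z_i = (sum_{j in J} y_j - ybar |J|) /
#'        (s * sqrt((n |J| - |J|^2) / (n - 1)))`,
#' where ybar and s are the global mean and population standard deviation
#' over all n areas. Positive z flags high-value clustering (hot),
#' negative low-value clustering (cold). A constant field has s = 0; by
#' convention all z are then 0 (with a warning).
#'
#' @param values numeric vector, one value per area (n >= 3).
#' @param weights a `spatial_weights` object.
#' @return numeric vector of z-scores.
#' @export
gi_star_slice <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(values)
  if (n != weights$n) stop("values/weights length mismatch")
  if (n < 3) stop("need at least 3 areas")
  ybar <- mean(values)
  s <- sqrt(mean(values^2) - ybar^2)  # population SD
  if (!is.finite(s) || s <= 0) {
    warning("degenerate (constant) field: all Gi* z-scores set to 0")
    return(stats::setNames(numeric(n), weights$ids))
  }
  z <- vapply(seq_len(n), function(i) {
    J <- c(i, weights$neighbors[[i]])
    wsum <- length(J)                      # binary weights: sum w = sum w^2 = |J|
    num <- sum(values[J]) - ybar * wsum
    den <- s * sqrt((n * wsum - wsum^2) / (n - 1))
    num / den
  }, numeric(1))
  stats::setNames(z, weights$ids)
}

#' Gi* z-score cube over a panel
#'
#' With `temporal_window = 0` (the default) each year is scored
#' independently by [gi_star_slice()]. With `temporal_window = 1` the
#' neighborhood of bin (i, t) additionally includes the same spatial star
#' in years t-1 and t+1, and the mean and SD are taken over all N*T bins
#' of the space-time cube.
#'
#' @param panel an `area_panel`.
#' @param weights a `spatial_weights` object.
#' @param temporal_window 0 (per-year spatial Gi*) or 1 (space-time
#'   neighbors in adjacent years).
#' @return object of class `gi_cube`: list with `z` (N x T), `p` (two-sided
#'   normal), `significance` (N x T character: `hot99/hot95/hot90/ns/
#'   cold90/cold95/cold99`), `years`, `area_ids`, `temporal_window`.
#' @export
gi_star_cube <- function(panel, weights, temporal_window = 0) {
  stopifnot(inherits(panel, "area_panel"))
  N <- length(panel$area_ids); T <- length(panel$years)
  z <- matrix(0, N, T, dimnames = list(panel$area_ids, panel$years))
  if (temporal_window == 0) {
    for (ti in seq_len(T)) z[, ti] <- gi_star_slice(panel$response[, ti], weights)
  } else if (temporal_window == 1) {
    y <- panel$response
    n_bins <- N * T
    ybar <- mean(y)
    s <- sqrt(mean(y^2) - ybar^2)
    if (!is.finite(s) || s <= 0) {
      warning("degenerate (constant) cube: all Gi* z-scores set to 0")
    } else {
      stars <- lapply(seq_len(N), function(i) c(i, weights$neighbors[[i]]))
      for (ti in seq_len(T)) {
        ts <- intersect(c(ti - 1L, ti, ti + 1L), seq_len(T))
        for (i in seq_len(N)) {
          J <- stars[[i]]
          wsum <- length(J) * length(ts)
          num <- sum(y[J, ts]) - ybar * wsum
          den <- s * sqrt((n_bins * wsum - wsum^2) / (n_bins - 1))
          z[i, ti] <- num / den
        }
      }
    }
  } else stop("temporal_window must be 0 or 1")
  p <- 2 * stats::pnorm(-abs(z))
  sig <- matrix("ns", N, T, dimnames = dimnames(z))
  sig[z >= 1.645] <- "hot90";  sig[z >= 1.96] <- "hot95";  sig[z >= 2.576] <- "hot99"
  sig[z <= -1.645] <- "cold90"; sig[z <= -1.96] <- "cold95"; sig[z <= -2.576] <- "cold99"
  structure(list(z = z, p = p, significance = sig, years = panel$years,
                 area_ids = panel$area_ids, temporal_window = temporal_window),
            class = "gi_cube")
}

#' @export
print.gi_cube <- function(x, ...) {
  cat("Gi* cube:", nrow(x$z), "areas x", ncol(x$z), "years (temporal window",
      x$temporal_window, ")\n")
  cat("significant-hot bins (z >= 1.96):", sum(x$z >= 1.96),
      "| significant-cold bins (z <= -1.96):", sum(x$z <= -1.96), "\n")
  invisible(x)
}

# classify one area's hot/cold indicator series; internal.
# hot, cold: logical length-T significance vectors; mk: mann_kendall() on
# the area's z series. The same rule set serves both roles: for the cold
# role a *strengthening* trend is a significantly decreasing z, so the
# trend statistic enters as dir * mk$z with dir = +1 (hot) or -1 (cold).
classify_one_series <- function(hot, cold, mk, alpha = 0.05,
                                recency = 1, persistence_frac = 0.9) {
  T <- length(hot)
  need <- ceiling(persistence_frac * T)
  zcrit <- stats::qnorm(1 - alpha / 2)
  trend_sig <- abs(mk$z) >= zcrit
  rule_set <- function(on, off, dir) {
    n_on <- sum(on)
    final_on <- on[T]
    dz <- dir * mk$z
    last_block <- seq(T - recency + 1L, T)
    # (1) new: significant only in the final recency step(s)
    if (final_on && all(on[last_block]) && !any(on[-last_block]))
      return("new")
    # (2) consecutive: one unbroken run ending at T, < pf*T of steps
    if (final_on && n_on < persistence_frac * T) {
      first_on <- min(which(on))
      if (all(on[first_on:T])) return("consecutive")
    }
    # (3)-(5) sustained presence, split on the trend of intensity
    if (n_on >= need && final_on && trend_sig && dz > 0) return("intensifying")
    if (n_on >= need && !trend_sig) return("persistent")
    if (n_on >= need && trend_sig && dz < 0) return("diminishing")
    # (6) sporadic: final on, earlier gapped on-steps, never the opposite
    if (final_on && n_on > 1L && !any(off)) {
      first_on <- min(which(on))
      if (!all(on[first_on:T])) return("sporadic")
    }
    # (7) oscillating: final on with at least one earlier opposite step
    if (final_on && any(off[seq_len(T - 1L)])) return("oscillating")
    # (8) historical: no longer on, but on in >= the persistence threshold
    if (!final_on && sum(on[seq_len(T - 1L)]) >= need) return("historical")
    NA_character_
  }
  h <- rule_set(hot, cold, +1)
  if (!is.na(h)) return(paste(h, "hot"))
  cc <- rule_set(cold, hot, -1)
  if (!is.na(cc)) return(paste(cc, "cold"))
  "no pattern"
}

#' Classify areas into emerging hot/cold spot patterns
#'
#' Evaluates each area's yearly Gi* significance series (hot: z at or above
#' the two-sided alpha cutoff; cold: at or below its negative) against
#' trend-aware rules, in this precedence: new, consecutive, intensifying,
#' persistent, diminishing, sporadic, oscillating, historical — first for
#' hot roles, then with hot/cold roles swapped for the cold categories
#' (a deepening cold spot is "intensifying cold" when the z trend is
#' significantly negative). An area matching no rule is "no pattern".
#'
#' Rule sketch (T steps, persistence threshold `ceiling(persistence_frac*T)`):
#' new = significant only in the final `recency` step(s); consecutive = a
#' single unbroken significant run ending at the final step covering fewer
#' than `persistence_frac * T` steps, with no earlier significant step;
#' intensifying / persistent / diminishing = significant in at least the
#' persistence threshold of steps with Mann-Kendall z trend significantly
#' strengthening / flat / weakening; sporadic = final step significant
#' with earlier gapped significant steps and never the opposite sign;
#' oscillating = final step significant with at least one earlier
#' opposite-sign significant step; historical = not significant in the
#' final step but significant in at least the persistence threshold of
#' steps.
#'
#' @param cube a `gi_cube` from [gi_star_cube()].
#' @param alpha significance level for per-year spots and for the trend
#'   (default 0.05, i.e. |z| >= 1.96).
#' @param recency number of final steps defining "new" (default 1).
#' @param persistence_frac fraction of steps defining sustained presence
#'   (default 0.9: at least 9 of 10 years).
#' @return data.frame with `area`, `category`, `mk_z`, `mk_p`,
#'   `hot_count`, `cold_count`.
#' @export
classify_emerging_pattern <- function(cube, alpha = 0.05, recency = 1,
                                      persistence_frac = 0.9) {
  stopifnot(inherits(cube, "gi_cube"))
  zcrit <- stats::qnorm(1 - alpha / 2)
  N <- nrow(cube$z); T <- ncol(cube$z)
  out <- data.frame(area = cube$area_ids, category = NA_character_,
                    mk_z = NA_real_, mk_p = NA_real_,
                    hot_count = NA_integer_, cold_count = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(N)) {
    zi <- cube$z[i, ]
    hot <- zi >= zcrit
    cold <- zi <= -zcrit
    mk <- mann_kendall(zi)
    out$category[i] <- classify_one_series(hot, cold, mk, alpha,
                                           recency, persistence_frac)
    out$mk_z[i] <- mk$z
    out$mk_p[i] <- mk$p
    out$hot_count[i] <- sum(hot)
    out$cold_count[i] <- sum(cold)
  }
  out
}

#' Summarize emerging-pattern counts
#'
#' Counts areas per category and reports percentages (rounded half-up to 2
#' decimals) both of classified (patterned) areas and of all areas, plus
#' hot and cold totals.
#'
#' @param results data.frame from [classify_emerging_pattern()], or a named
#'   integer vector of per-category counts (categories like
#'   `"consecutive hot"`; `"no pattern"` allowed).
#' @param n_total total number of areas (defaults to `nrow(results)` /
#'   `sum(counts)`).
#' @return list with `counts` (per category), `n_total`, `n_patterned`,
#'   `pct_patterned_of_total`, `pct_of_patterned` and `pct_of_total` (per
#'   category), and `hot`/`cold` totals with their percentages of
#'   patterned areas.
#' @export
summarize_patterns <- function(results, n_total = NULL) {
  if (is.data.frame(results)) {
    counts <- table(results$category)
    counts <- stats::setNames(as.integer(counts), names(counts))
    if (is.null(n_total)) n_total <- nrow(results)
  } else {
    counts <- results
    if (is.null(n_total)) n_total <- sum(counts)
  }
  pat <- counts[names(counts) != "no pattern"]
  n_pat <- sum(pat)
  pct2 <- function(num, den) if (den > 0) round_half_up(100 * num / den, 2) else 0
  hot_n <- sum(pat[grepl(" hot$", names(pat))])
  cold_n <- sum(pat[grepl(" cold$", names(pat))])
  list(
    counts = as.list(pat),
    n_total = n_total,
    n_patterned = n_pat,
    pct_patterned_of_total = pct2(n_pat, n_total),
    pct_of_patterned = lapply(as.list(pat), pct2, den = n_pat),
    pct_of_total = lapply(as.list(pat), pct2, den = n_total),
    hot = list(count = hot_n, pct_of_patterned = pct2(hot_n, n_pat)),
    cold = list(count = cold_n, pct_of_patterned = pct2(cold_n, n_pat))
  )
}
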