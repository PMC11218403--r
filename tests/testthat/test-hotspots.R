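test_that("Mann-Kendall matches exhaustive pair enumeration, with ties", {
  expect_equal(mann_kendall(c(1, 2, 3, 4, 5))$S, 10L)  # n(n-1)/2 maximal
  expect_equal(mann_kendall(c(3, 1, 2, 4))$S, 2L)
  con <- mann_kendall(rep(2, 6))
  expect_equal(con$S, 0L)
  expect_equal(con$z, 0)
  expect_equal(con$p, 1)
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    x <- sample(1:6, n, replace = TRUE)  # forces ties
    mk <- mann_kendall(x)
    expect_equal(mk$S, mk_S_bruteforce(x))
    ties <- table(x); ties <- ties[ties > 1]
    v_expected <- (n * (n - 1) * (2 * n + 5) -
                     sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    expect_equal(mk$var_S, v_expected)
    if (mk$S != 0 && v_expected > 0) {
      expect_equal(mk$z, (mk$S - sign(mk$S)) / sqrt(v_expected))
      expect_equal(mk$p, 2 * pnorm(-abs(mk$z)))
    }
  }
})

test_that("Gi* matches a literal brute-force transcription on a plateau fixture", {
  w <- lattice_weights(5, 5, "rook")
  vals <- rep(1, 25)
  vals[c(7, 8, 12, 13)] <- 5  # seeded high plateau
  z <- gi_star_slice(vals, w)
  z_brute <- gi_star_bruteforce(vals, w)
  expect_lt(max(abs(z - z_brute)), 1e-10)
  expect_gt(z[12], 2)  # plateau interior is a hot spot
})

test_that("Gi* is affine invariant and zero on constant fields", {
  set.seed(17)
  w <- random_connected_weights(30, 0.15)
  y <- rnorm(30)
  z <- gi_star_slice(y, w)
  for (ab in list(c(2, 3), c(-7, 0.1), c(100, 42))) {
    expect_lt(max(abs(gi_star_slice(ab[1] + ab[2] * y, w) - z)), 1e-10)
  }
  expect_warning(zc <- gi_star_slice(rep(4, 30), w), "degenerate")
  expect_equal(unname(zc), rep(0, 30))
})

test_that("Gi* permutation distribution is approximately standard normal", {
  set.seed(55)
  w <- random_connected_weights(40, 0.12)
  y <- rgamma(40, 2)
  i0 <- 10L
  zs <- replicate(2000, gi_star_slice(sample(y), w)[i0])
  expect_lt(abs(mean(zs)), 0.05)
  expect_true(sd(zs) > 0.9 && sd(zs) < 1.1)
})

test_that("cube with window 0 reproduces per-year slices; identical years match", {
  sim <- simulate_panel(sim_config(grid_rows = 4, grid_cols = 4, T = 5,
                                   K = 1, seed = 31))
  cube <- gi_star_cube(sim$panel, sim$weights, temporal_window = 0)
  for (t in 1:5)
    expect_equal(cube$z[, t], gi_star_slice(sim$panel$response[, t], sim$weights))
  # T identical yearly fields give identical z columns
  p2 <- sim$panel
  p2$response <- matrix(sim$panel$response[, 1], 16, 5,
                        dimnames = dimnames(p2$response))
  cube2 <- gi_star_cube(p2, sim$weights)
  expect_equal(cube2$z, cube2$z[, c(1, 1, 1, 1, 1)], ignore_attr = TRUE)
})

test_that("window-1 cube matches brute-force space-time sums", {
  hp <- simulate_hotspot_panel()
  cube <- gi_star_cube(hp$panel, hp$weights, temporal_window = 1)
  y <- hp$panel$response
  N <- nrow(y); T <- ncol(y)
  ybar <- mean(y)
  s <- sqrt(mean(y^2) - ybar^2)
  for (cell in c(hp$blocks$centers$hot, hp$blocks$centers$cold, 50L)) {
    for (t in c(1L, 5L, 10L)) {
      ts <- intersect((t - 1):(t + 1), 1:T)
      J <- c(cell, hp$weights$neighbors[[cell]])
      tot <- 0; wsum <- 0
      for (j in J) for (u in ts) { tot <- tot + y[j, u]; wsum <- wsum + 1 }
      zb <- (tot - ybar * wsum) /
        (s * sqrt((N * T * wsum - wsum^2) / (N * T - 1)))
      expect_lt(abs(cube$z[cell, t] - zb), 1e-10)
    }
  }
})

test_that("significance bins follow the two-sided z cutoffs", {
  sim <- simulate_panel(sim_config(grid_rows = 4, grid_cols = 4, T = 4,
                                   K = 1, seed = 77))
  cube <- gi_star_cube(sim$panel, sim$weights)
  z <- cube$z; sig <- cube$significance
  expect_true(all(sig[abs(z) < 1.645] == "ns"))
  expect_true(all(sig[z >= 2.576] == "hot99"))
  expect_true(all(sig[z <= -1.96 & z > -2.576] == "cold95"))
})

test_that("classifier rules fire in the documented precedence", {
  T <- 10
  mk_up <- list(S = 30L, var_S = 125, z = 3.1, p = 0.002)
  mk_dn <- list(S = -30L, var_S = 125, z = -3.1, p = 0.002)
  mk_ns <- list(S = 2L, var_S = 125, z = 0.1, p = 0.92)
  none <- rep(FALSE, T)
  hot_all <- rep(TRUE, T)
  # hot in all 10 steps with significant increase: intensifying, not consecutive
  expect_equal(geotriad:::classify_one_series(hot_all, none, mk_up), "intensifying hot")
  expect_equal(geotriad:::classify_one_series(hot_all, none, mk_ns), "persistent hot")
  expect_equal(geotriad:::classify_one_series(hot_all, none, mk_dn), "diminishing hot")
  # hot only in the final year: new
  last_only <- c(rep(FALSE, 9), TRUE)
  expect_equal(geotriad:::classify_one_series(last_only, none, mk_up), "new hot")
  # unbroken run ending at T covering < 90%: consecutive
  run <- c(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(geotriad:::classify_one_series(run, none, mk_up), "consecutive hot")
  # gapped hot steps ending hot, never cold: sporadic
  gap <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(geotriad:::classify_one_series(gap, none, mk_ns), "sporadic hot")
  # final hot, gapped hot history, with an earlier cold step: oscillating
  osc_hot <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  osc_cold <- c(TRUE, TRUE, rep(FALSE, 8))
  expect_equal(geotriad:::classify_one_series(osc_hot, osc_cold, mk_up), "oscillating hot")
  # an unbroken final run with earlier cold steps is consecutive by precedence
  run_after_cold <- c(rep(FALSE, 7), TRUE, TRUE, TRUE)
  expect_equal(geotriad:::classify_one_series(run_after_cold, osc_cold, mk_up),
               "consecutive hot")
  # hot for the first 9 steps but not the last: persistent when the trend
  # is flat (sustained-presence rules precede historical), historical when
  # a significant trend keeps rules 3-5 from firing
  hist <- c(rep(TRUE, 9), FALSE)
  expect_equal(geotriad:::classify_one_series(hist, none, mk_ns), "persistent hot")
  expect_equal(geotriad:::classify_one_series(hist, none, mk_up), "historical hot")
  # mirrored cold categories (deepening cold = significantly decreasing z)
  expect_equal(geotriad:::classify_one_series(none, hot_all, mk_dn), "intensifying cold")
  expect_equal(geotriad:::classify_one_series(none, hot_all, mk_ns), "persistent cold")
  expect_equal(geotriad:::classify_one_series(none, run, mk_ns), "consecutive cold")
  expect_equal(geotriad:::classify_one_series(none, last_only, mk_ns), "new cold")
  # nothing significant anywhere: no pattern
  expect_equal(geotriad:::classify_one_series(none, none, mk_ns), "no pattern")
})

test_that("the deterministic preset classifies exactly as designed", {
  hp <- simulate_hotspot_panel()
  cube <- gi_star_cube(hp$panel, hp$weights)
  cls <- classify_emerging_pattern(cube)
  expect_true(all(cls$category[hp$blocks$hot] == "intensifying hot"))
  expect_true(all(cls$category[hp$blocks$new] == "new hot"))
  expect_true(all(cls$category[hp$blocks$cold] == "consecutive cold"))
  outside <- setdiff(seq_len(196), unlist(hp$blocks[c("hot", "new", "cold")]))
  expect_true(all(cls$category[outside] == "no pattern"))
})

test_that("classifier output is equivariant under area permutation", {
  hp <- simulate_hotspot_panel()
  cube <- gi_star_cube(hp$panel, hp$weights)
  cls <- classify_emerging_pattern(cube)
  set.seed(4)
  perm <- sample(196)
  inv <- order(perm)
  p2 <- hp$panel
  p2$response <- hp$panel$response[perm, ]
  p2$area_ids <- hp$panel$area_ids[perm]
  p2$region_of <- hp$panel$region_of[perm]
  p2$population <- hp$panel$population[perm, ]
  p2$land_area <- hp$panel$land_area[perm]
  w2 <- spatial_weights(lapply(hp$weights$neighbors[perm],
                               function(nb) inv[nb]),
                        ids = hp$weights$ids[perm])
  cls2 <- classify_emerging_pattern(gi_star_cube(p2, w2))
  expect_equal(cls2$category, cls$category[perm])
  expect_equal(cls2$area, cls$area[perm])
})

test_that("pattern summaries reproduce percentages from counts", {
  counts <- c("consecutive hot" = 257L, "intensifying hot" = 65L,
              "sporadic hot" = 58L, "new hot" = 50L, "persistent hot" = 20L,
              "diminishing hot" = 2L, "consecutive cold" = 120L)
  s <- summarize_patterns(counts, n_total = 2308L)
  expect_equal(s$n_patterned, 572L)
  expect_equal(s$pct_patterned_of_total, 24.78)
  expect_equal(s$hot$count, 452L)
  expect_equal(s$hot$pct_of_patterned, 79.02)
  expect_equal(s$cold$pct_of_patterned, 20.98)
  expect_equal(s$pct_of_patterned[["consecutive hot"]], 44.93)
  expect_equal(s$pct_of_patterned[["intensifying hot"]], 11.36)
  expect_equal(s$pct_of_patterned[["new hot"]], 8.74)
  # empty input
  e <- summarize_patterns(c("no pattern" = 10L))
  expect_equal(e$n_patterned, 0L)
  expect_equal(e$pct_patterned_of_total, 0)
})
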