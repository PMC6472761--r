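test_that("ranking selects top-m with documented tie handling", {
  v <- setNames(c(5, 3, 9, 1), c("p1", "p2", "p3", "p4"))
  out <- rank_and_select(v, 2)
  expect_equal(out$selected, c("p3", "p1"))
  expect_equal(out$ranking, c("p3", "p1", "p2", "p4"))
  # minimize direction
  expect_equal(rank_and_select(v, 1, "minimize")$selected, "p4")
  # ties broken by identifier
  ties <- setNames(rep(1, 4), c("b", "d", "a", "c"))
  expect_equal(rank_and_select(ties, 2)$selected, c("a", "b"))
  # m = n selects everyone
  expect_equal(sort(rank_and_select(v, 4)$selected), sort(names(v)))
  # study-sized intensity
  v203 <- setNames(rnorm(203), sprintf("p%03d", 1:203))
  expect_equal(rank_and_select(v203, 30)$intensity, 30 / 203)
  expect_equal(rank_and_select(v203, 30)$intensity, 0.148, tolerance = 1e-2)
})

test_that("selection gains reproduce the published gain rows from the printed
           breeding values", {
  sel <- soybean_reference("selection")
  means <- soybean_reference("trait_means")
  published <- list(
    FSTME = c(DM = 6.77, SW = 5.85, SY = 8.27),
    FMTME = c(DM = 7.21, SW = 5.55, SY = 15.03))
  for (model in names(published)) {
    for (tr in c("DM", "SW", "SY")) {
      vals <- sel[[tr]][sel$model == model]
      expect_length(vals, 30L)
      g <- gain_stats(vals, means$grand_mean[means$trait == tr])
      expect_lt(abs(g$gain_pct - published[[model]][[tr]]), 0.02)
    }
  }
  # mean of selected equal to overall mean gives zero gain
  expect_equal(gain_stats(c(10, 10), 10)$gain_abs, 0)
  expect_equal(gain_stats(c(10, 10), 10)$gain_pct, 0)
})

test_that("top-m selection maximizes the gain (exhaustive check)", {
  set.seed(4)
  v <- setNames(rnorm(12), sprintf("p%02d", 1:12))
  m <- 4
  best <- gain_stats(v[rank_and_select(v, m)$selected], 0)$gain_abs
  combos <- utils::combn(12, m)
  gains <- apply(combos, 2, function(ix) mean(v[ix]))
  expect_equal(best, max(gains), tolerance = 1e-12)
})

test_that("rank agreement is exact for identical rankings and matches the
           coincidence-index arithmetic", {
  v <- setNames(rnorm(203), sprintf("p%03d", 1:203))
  out <- rank_agreement(v, v, m = 30, n_boot = 50, seed = 1)
  expect_equal(out$spearman_rho, 1)
  expect_equal(out$overlap, 30L)
  expect_equal(out$coincidence, 1)
  # engineered overlap A = 18 at M = 30, b = 0.15 (C = 4.5)
  a <- setNames(seq(203, 1), sprintf("p%03d", 1:203))
  b <- a
  # top-30 of a is p001..p030; make b's top-30 = p001..p018 + p031..p042
  b[sprintf("p%03d", 19:30)] <- 0
  b[sprintf("p%03d", 31:42)] <- 300
  out2 <- rank_agreement(a, b, m = 30, b_intensity = 0.15, n_boot = 20,
                         seed = 1)
  expect_equal(out2$overlap, 18L)
  expect_equal(out2$chance, 4.5)
  expect_equal(out2$coincidence, 13.5 / 25.5, tolerance = 1e-12)
  # A = C exactly gives coincidence 0 (m = 10, b = 0.2, C = 2)
  b2 <- a
  b2[sprintf("p%03d", 3:10)] <- 0
  b2[sprintf("p%03d", 11:18)] <- 300
  out3 <- rank_agreement(a, b2, m = 10, b_intensity = 0.2, n_boot = 20,
                         seed = 1)
  expect_equal(out3$overlap, 2L)
  expect_equal(out3$coincidence, 0)
  expect_error(rank_agreement(a, a[-1], m = 5), "same progeny")
})

test_that("bootstrap interval covers the true rank correlation at the nominal
           rate", {
  rho <- 0.5
  true_s <- 6 / pi * asin(rho / 2)   # Spearman correlation of a bivariate normal
  n <- 80
  cover <- 0L
  n_sim <- 400L
  for (s in seq_len(n_sim)) {
    set.seed(9000 + s)
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    ids <- sprintf("p%02d", seq_len(n))
    out <- rank_agreement(setNames(z1, ids), setNames(z2, ids), m = 12,
                          n_boot = 499, seed = s)
    if (out$boot_ci[1] <= true_s && true_s <= out$boot_ci[2]) {
      cover <- cover + 1L
    }
  }
  expect_gte(cover / n_sim, 0.92)
  expect_lte(cover / n_sim, 0.98)
})

test_that("the additive genetic index ranks sensibly and is unit invariant", {
  set.seed(6)
  bv <- cbind(DM = rnorm(40, 150, 5), SW = rnorm(40, 19, 1),
              SY = rnorm(40, 21, 2))
  rownames(bv) <- sprintf("p%02d", 1:40)
  # single trait: AGI ranking equals the BLUP ranking for any positive weight
  one <- agi_scores(bv[, "DM", drop = FALSE], weights = 2.7)
  expect_equal(one$ranking,
               rank_and_select(setNames(bv[, "DM"], rownames(bv)), 40)$ranking)
  # standardized index is invariant to expressing SY in kilograms
  w <- c(DM = 0.08, SW = 0.07, SY = 0.16)
  bv_kg <- bv
  bv_kg[, "SY"] <- bv[, "SY"] / 1000
  expect_equal(agi_scores(bv, w)$ranking, agi_scores(bv_kg, w)$ranking)
  # equal weights on symmetric values tie
  sym <- cbind(a = c(1, 2), b = c(2, 1))
  rownames(sym) <- c("x", "y")
  ag <- agi_scores(sym, c(1, 1), scale = c(1, 1))
  expect_equal(ag$agi[["x"]], ag$agi[["y"]])
  expect_error(agi_scores(bv, c(1, -1, 1)), "positive")
})
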