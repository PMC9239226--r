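test_that("bray_curtis_matrix matches hand values and the loop oracle", {
  m <- rbind(S1 = c(6, 2), S2 = c(2, 2), S3 = c(6, 2))
  colnames(m) <- c("a", "b")
  bc <- bray_curtis_matrix(m)
  expect_equal(bc["S1", "S2"], 4 / 12, tolerance = 1e-12)
  expect_equal(bc["S1", "S3"], 0)
  expect_equal(diag(bc), setNames(rep(0, 3), rownames(m)))

  disj <- rbind(S1 = c(5, 0), S2 = c(0, 9)); colnames(disj) <- c("a", "b")
  expect_equal(bray_curtis_matrix(disj)["S1", "S2"], 1)

  withr::with_seed(8, {
    r <- matrix(runif(10 * 30, 0, 5), 10, 30,
                dimnames = list(paste0("S", 1:10), paste0("O", 1:30)))
  })
  bc2 <- bray_curtis_matrix(r)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    oracle[i, j] <- sum(abs(r[i, ] - r[j, ])) / sum(r[i, ] + r[j, ])
  }
  expect_equal(unname(bc2), oracle, tolerance = 1e-12)

  z <- rbind(S1 = c(0, 0), S2 = c(1, 2)); colnames(z) <- c("a", "b")
  expect_error(bray_curtis_matrix(z), "all-zero")
})

test_that("null model preserves richness, occupancy structure and seeds", {
  tb <- skewed_community(n = 8, seed = 10)
  nulls <- null_model_randomize(tb, 5, seed = 3)
  expect_length(nulls, 5)
  rich <- rowSums(tb$counts > 0)
  for (nm in nulls) {
    expect_equal(rowSums(nm > 0), rich)
    expect_equal(rowSums(nm), rowSums(tb$counts), tolerance = 1e-9)
  }
  expect_identical(null_model_randomize(tb, 5, seed = 3), nulls)
  expect_false(identical(null_model_randomize(tb, 5, seed = 4), nulls))

  # saturated occupancy: every sample contains every phylotype, so nulls must too
  full <- matrix(5L + rpois(40, 3), 5, 8,
                 dimnames = list(paste0("S", 1:5), paste0("O", 1:8)))
  ftb <- suppressMessages(community_table(full, "archaea"))
  for (nm in null_model_randomize(ftb, 3, seed = 1)) expect_true(all(nm > 0))
})

test_that("null occupancy matches the frequency-proportional sampling oracle", {
  withr::with_seed(20, {
    m <- matrix(rbinom(40, 1, 0.5) * rpois(40, 6), 5, 8,
                dimnames = list(paste0("S", 1:5), paste0("O", 1:8)))
    m[, 1] <- pmax(m[, 1], 1)   # no empty columns / rows
    m[1, ] <- pmax(m[1, ], 1)
  })
  tb <- suppressMessages(community_table(m, "fungi"))
  freq <- colSums(m > 0)
  rich <- rowSums(m > 0)

  n_draw <- 10000
  nulls <- null_model_randomize(tb, n_draw, seed = 6)
  occ <- Reduce(`+`, lapply(nulls, function(x) (x > 0) * 1)) / n_draw

  # oracle: an independent implementation of successive weighted sampling
  # without replacement (base R sample with prob), same marginal law
  oracle_occ <- withr::with_seed(7, {
    acc <- matrix(0, nrow(m), ncol(m))
    for (k in seq_len(n_draw)) {
      for (i in seq_len(nrow(m))) {
        chosen <- sample(seq_len(ncol(m)), rich[i], prob = freq)
        acc[i, chosen] <- acc[i, chosen] + 1
      }
    }
    acc / n_draw
  })
  expect_lt(max(abs(occ - oracle_occ)), 0.02)   # MC error at 10,000 draws
})

test_that("pairwise stochasticity ratio follows the two-branch formula", {
  ps <- rarebef:::pairwise_stochasticity
  expect_equal(ps(0.8, 0.2), 0.25)          # determinism drives similarity: E/C
  expect_equal(ps(0.1, 0.5), 0.5 / 0.9)     # drives dissimilarity: (1-E)/(1-C)
  expect_equal(ps(0.4, 0.4), 1)             # observed equals expectation
  expect_equal(ps(1, 1), 1)                 # degenerate pair defined as 1
  x <- withr::with_seed(3, runif(100)); y <- withr::with_seed(4, runif(100))
  expect_true(all(ps(x, y) >= 0 & ps(x, y) <= 1))
})

test_that("stochasticity_ratio aggregates and stays in [0, 1]", {
  tb <- skewed_community(n = 10, seed = 21)
  st <- stochasticity_ratio(tb, n_null = 50, seed = 2)
  expect_true(all(st$pairwise_st >= 0 & st$pairwise_st <= 1))
  expect_equal(st$ST, mean(st$pairwise_st))
  expect_true(all(st$C >= 0 & st$C <= 1 & st$E >= 0 & st$E <= 1))
  # reproducibility of the full result
  expect_equal(stochasticity_ratio(tb, n_null = 50, seed = 2)$ST, st$ST)
})

test_that("expected similarity is stable across seeds at n_null = 1000", {
  # community at a realistic richness scale (~63% occupancy, so membership
  # is genuinely re-drawn); per-pair Monte-Carlo error at n_null = 1000 must
  # stay within 0.01
  tb <- toy_community(15, 400, seed = 30, lambda = 1)
  e1 <- stochasticity_ratio(tb, n_null = 1000, seed = 1)$E
  e2 <- stochasticity_ratio(tb, n_null = 1000, seed = 2)$E
  expect_lt(max(abs(e1 - e2)), 0.01)
})

test_that("st_by_category bins correctly and recovers exact quadratics", {
  # 228 samples in 19 groups of exactly 12
  tb <- quiet(generate_dataset(small_sim_config(seed = 2)))$tables$bacteria
  ord <- withr::with_seed(1, runif(36))
  res <- st_by_category(tb, ord, n_groups = 6, n_null = 10, seed = 5)
  expect_equal(res$bins$n, rep(6, 6))
  expect_equal(rarebef:::bin_sizes(228, 19), rep(12, 19))
  # remainder goes to the last bins
  expect_equal(rarebef:::bin_sizes(230, 19), c(rep(12, 17), 13, 13))

  # quadratic recovery: feed engineered ST values straight into the trend fit
  m <- seq(0.1, 0.9, length.out = 12)
  stv <- 0.5 - 0.1 * m + 0.02 * m^2
  tr <- suppressWarnings(polynomial_trend(m, stv, degree = 2))
  expect_equal(unname(tr$coefficients), c(0.5, -0.1, 0.02), tolerance = 1e-8)

  expect_error(st_by_category(tb, ord, n_groups = 1, n_null = 5, seed = 1),
               "at least 2")
  expect_error(st_by_category(tb, ord, n_groups = 18, n_null = 5, seed = 1),
               "fewer than 3")
  # constant ordering: binning still works, trend flagged degenerate
  resc <- st_by_category(tb, rep(1, 36), n_groups = 6, n_null = 5, seed = 1)
  expect_true(resc$degenerate)
  expect_null(resc$trend)
})
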