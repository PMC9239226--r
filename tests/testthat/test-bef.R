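test_that("bef_regression recovers exact lines and z-scored slopes", {
  x <- seq(0, 1, length.out = 20)
  fit <- suppressWarnings(bef_regression(x, 2 * x + 1))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)

  fit2 <- suppressWarnings(bef_regression(x, -x))
  expect_equal(fit2$standardized_slope, -1, tolerance = 1e-12)
  # |standardized slope| = sqrt(R^2) for simple regression
  y <- withr::with_seed(1, x + rnorm(20, 0, 0.3))
  fit3 <- bef_regression(x, y)
  expect_equal(abs(fit3$standardized_slope), sqrt(fit3$r_squared), tolerance = 1e-12)

  expect_error(bef_regression(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("bef slope test holds its nominal type-I error", {
  hits <- withr::with_seed(99, {
    vapply(seq_len(1000), function(i) {
      bef_regression(rnorm(228), rnorm(228))$p_value < 0.05
    }, logical(1))
  })
  # binomial(1000, .05): 3 sigma band ~ [0.029, 0.071]
  expect_gt(mean(hits), 0.029)
  expect_lt(mean(hits), 0.071)
})

test_that("diversity-function Spearman matches the rank-then-Pearson oracle", {
  withr::with_seed(12, {
    div <- list(g1 = rnorm(228), g2 = rpois(228, 30))
    fn <- matrix(rnorm(228 * 3), 228, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  })
  res <- diversity_function_correlations(div, fn)
  for (i in 1:2) for (j in 1:3) {
    expect_equal(res$rho[i, j], cor(rank(div[[i]]), rank(fn[, j])),
                 tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(div[[i]], fn[, j], method = "spearman",
                                    exact = FALSE))
    expect_equal(res$p[i, j], ct$p.value, tolerance = 1e-9)
  }
  # monotone transform: rho = 1; reversed ranks: rho = -1
  mono <- diversity_function_correlations(list(d = div$g1),
                                          cbind(f = exp(div$g1)))
  expect_equal(mono$rho[1, 1], 1)
  anti <- diversity_function_correlations(list(d = div$g1),
                                          cbind(f = -div$g1))
  expect_equal(anti$rho[1, 1], -1)
  # constant vector: undefined, excluded from the mask
  con <- diversity_function_correlations(list(d = rep(1, 228)), fn)
  expect_true(all(is.na(con$rho)))
  expect_false(any(con$significant))
})

test_that("supporting_phylotypes flags positive significant correlations only", {
  n <- 228
  withr::with_seed(31, {
    driver <- runif(n)
    counts <- matrix(rpois(n * 4, 20), n, 4)
    counts[, 1] <- rpois(n, 20 + 60 * driver)       # positive supporter
    counts[, 2] <- rpois(n, 20 + 60 * (1 - driver)) # negative correlate
    counts[, 3] <- 15L                              # constant abundance
    dimnames(counts) <- list(sprintf("S%03d", 1:n), paste0("OTU", 1:4))
  })
  tb <- suppressMessages(community_table(counts, "bacteria"))
  cl <- classify_phylotypes(tb, threshold_scheme())
  fn <- cbind(f1 = driver)
  st <- quiet(supporting_phylotypes(tb, cl, fn))
  expect_true(st$supports["OTU1", "f1"])
  expect_gt(st$rho["OTU1", "f1"], 0)
  expect_lt(st$p["OTU1", "f1"], 0.01)
  expect_false(st$supports["OTU2", "f1"])   # negative, never supporting
  expect_lt(st$rho["OTU2", "f1"], 0)
  # perfect monotone phylotype: rho 1 (rel abundance must drive ranks)
  expect_false(st$supports["OTU3", "f1"] %in% TRUE)

  # fully constant relative abundances: undefined rho, supports all FALSE
  constm <- matrix(10L, n, 2, dimnames = list(sprintf("S%03d", 1:n), c("c1", "c2")))
  tbc <- suppressMessages(community_table(constm, "archaea"))
  stc <- quiet(supporting_phylotypes(tbc, classify_phylotypes(tbc), fn))
  expect_true(all(is.na(stc$rho)))
  expect_false(any(stc$supports))

  # prevalence filter
  sparse <- counts; sparse[, 4] <- 0L; sparse[1:5, 4] <- 3L
  tb2 <- suppressMessages(community_table(sparse, "bacteria"))
  st2 <- quiet(supporting_phylotypes(tb2, classify_phylotypes(tb2), fn,
                                     prevalence_min = 0.1))
  expect_false("OTU4" %in% rownames(st2$rho))
  expect_error(quiet(supporting_phylotypes(tb2, classify_phylotypes(tb2), fn,
                                           prevalence_min = 1.01)),
               "prevalence")
})

# crafted support table: 2 abundant phylotypes supporting functions 1-3,
# 8 rare phylotypes supporting function 1 only
crafted_support <- function() {
  ids <- c(paste0("A", 1:2), paste0("R", 1:8))
  phylo <- data.frame(phylotype_id = ids, group = "bacteria",
                      label = rep(c("abundant", "rare"), c(2, 8)),
                      stringsAsFactors = FALSE)
  rho <- matrix(-0.5, 10, 4, dimnames = list(ids, paste0("f", 1:4)))
  p <- matrix(0.5, 10, 4, dimnames = dimnames(rho))
  rho[1:2, 1:3] <- 0.8; p[1:2, 1:3] <- 1e-5
  rho[3:10, 1] <- 0.6;  p[3:10, 1] <- 1e-4
  rarebef:::new_support_table(phylo, rho, p, p_cut = 0.01)
}

test_that("support_summary matches the enumeration oracle", {
  st <- crafted_support()
  expect_equal(unname(st$n_functions_supported), c(3, 3, rep(1, 8)))
  sm <- support_summary(st, service_group = c(f1 = "np", f2 = "np",
                                              f3 = "ec", f4 = "ec"))
  pf <- sm$per_function
  # f1: 10 supporters, 2 abundant / 8 rare
  expect_equal(pf$n_supporting, c(10, 2, 2, 0))
  expect_equal(pf$prop_abundant, c(0.2, 1, 1, 0))
  expect_equal(pf$prop_rare, c(0.8, 0, 0, 0))
  expect_true(pf$empty[4])
  # service groups: np pools f1+f2 (12 events, 4 abundant), ec pools f3+f4
  expect_equal(sm$per_service_group$prop_abundant,
               c(4 / 12, 1))
  # per class: both abundant support >= 1, all rare support >= 1
  pc <- sm$per_class
  expect_equal(pc$prop_supporting[pc$label == "abundant"], 1)
  expect_equal(pc$prop_supporting[pc$label == "rare"], 1)
  # column-sum consistency: per_function n_supporting == colSums(supports)
  expect_equal(pf$n_supporting, unname(colSums(st$supports)))
})

test_that("saturated support gives proportions of one", {
  ids <- paste0("P", 1:5)
  phylo <- data.frame(phylotype_id = ids, group = "fungi",
                      label = rep(c("abundant", "rare"), c(2, 3)),
                      stringsAsFactors = FALSE)
  rho <- matrix(0.9, 5, 2, dimnames = list(ids, c("f1", "f2")))
  p <- matrix(1e-6, 5, 2, dimnames = dimnames(rho))
  st <- rarebef:::new_support_table(phylo, rho, p)
  sm <- support_summary(st)
  expect_true(all(sm$per_class$prop_supporting[sm$per_class$label != "intermediate"] == 1))
  expect_equal(sm$per_function$prop_rare + sm$per_function$prop_abundant,
               rep(1, 2))
})

test_that("compare_support_breadth matches rank-sum oracles", {
  # abundant all 5 functions, rare all 1 (n = 20 each): maximal separation
  ids <- c(paste0("A", 1:20), paste0("R", 1:20))
  phylo <- data.frame(phylotype_id = ids, group = "bacteria",
                      label = rep(c("abundant", "rare"), each = 20),
                      stringsAsFactors = FALSE)
  rho <- matrix(0, 40, 5, dimnames = list(ids, paste0("f", 1:5)))
  p <- matrix(1, 40, 5, dimnames = dimnames(rho))
  rho[1:20, ] <- 0.9; p[1:20, ] <- 1e-6          # abundant: 5 each
  rho[21:40, 1] <- 0.9; p[21:40, 1] <- 1e-6      # rare: 1 each
  st <- rarebef:::new_support_table(phylo, rho, p)
  res <- compare_support_breadth(st)
  expect_equal(res$mean_abundant, 5)
  expect_equal(res$mean_rare, 1)
  expect_lt(res$p_value, 1e-3)

  # tie-corrected normal approximation oracle on the same data
  a <- rep(5, 20); r <- rep(1, 20)
  all_v <- c(a, r); rk <- rank(all_v)
  W <- sum(rk[1:20]) - 20 * 21 / 2
  n1 <- 20; n2 <- 20; N <- 40
  ties <- table(all_v)
  sigma2 <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (W - n1 * n2 / 2 - 0.5) / sqrt(sigma2)   # continuity corrected
  expect_equal(res$statistic, W)
  expect_equal(res$p_value, 2 * pnorm(abs(z), lower.tail = FALSE),
               tolerance = 1e-9)

  # identical breadth distributions: no signal
  p2 <- p; rho2 <- rho
  rho2[, ] <- 0; p2[, ] <- 1
  rho2[, 1] <- 0.9; p2[, 1] <- 1e-6              # everyone supports exactly 1
  st2 <- rarebef:::new_support_table(phylo, rho2, p2)
  expect_gt(compare_support_breadth(st2)$p_value, 0.05)

  # empty class errors
  phylo3 <- phylo; phylo3$label <- "abundant"
  st3 <- rarebef:::new_support_table(phylo3, rho, p)
  expect_error(compare_support_breadth(st3), "each of the abundant and rare")
})
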