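# two-group fixture where a handful of rare phylotypes co-vary strongly
cooccurring_tables <- function(n = 228, seed = 17) {
  withr::with_seed(seed, {
    driver <- runif(n)
    mk <- function(group, p_extra) {
      m <- matrix(rpois(n * p_extra, 3), n, p_extra)
      # three strongly co-occurring taxa riding the same driver; mean counts
      # stay below 0.05% of the dataset pool so they classify as rare
      hub <- sapply(1:3, function(k) rpois(n, 2 + 40 * driver))
      m <- cbind(hub, m)
      # one big abundant background taxon keeps the others rare
      m <- cbind(rpois(n, 50000), m)
      dimnames(m) <- list(sprintf("S%03d", 1:n),
                          paste0(group, "_O", seq_len(ncol(m))))
      suppressMessages(community_table(m, group))
    }
    list(tables = list(bacteria = mk("bacteria", 20), fungi = mk("fungi", 20)),
         driver = driver)
  })
}

test_that("build_network finds perfect co-occurrences and honors thresholds", {
  fx <- cooccurring_tables()
  cls <- lapply(fx$tables, classify_phylotypes)
  net <- quiet(build_network(fx$tables, cls, "rare", prevalence_min = 0.2))
  expect_s3_class(net, "cooc_network")
  # the six hub taxa (3 per group) must be densely connected
  hubs <- c(paste0("bacteria|bacteria_O", 2:4), paste0("fungi|fungi_O", 2:4))
  deg <- net$nodes$degree[match(hubs, net$nodes$id)]
  expect_true(all(deg >= 3))
  # every edge satisfies the strict thresholds
  expect_true(all(abs(net$edges$rho) > 0.6))
  expect_true(all(net$edges$q < 0.001))
  # handshake lemma
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
})

test_that("edge mask uses strict inequalities", {
  rho <- matrix(c(NA, 0.6, 0.61, NA), 2, 2)
  q <- matrix(c(NA, 5e-4, 5e-4, NA), 2, 2)
  m <- rarebef:::edge_mask(rho, q)
  expect_false(m[2, 1])   # rho exactly 0.6: no edge
  expect_true(m[1, 2])
  q2 <- q; q2[1, 2] <- 0.001
  expect_false(rarebef:::edge_mask(rho, q2)[1, 2])  # q exactly 0.001: no edge
})

test_that("independent phylotypes yield empty networks", {
  zero_edges <- withr::with_seed(55, {
    vapply(1:15, function(r) {
      m <- matrix(rpois(228 * 50, 5), 228, 50,
                  dimnames = list(sprintf("S%03d", 1:228),
                                  sprintf("O%02d", 1:50)))
      tb <- suppressMessages(community_table(m, "protist"))
      cl <- classify_phylotypes(tb)   # 50 even taxa all classify as abundant
      net <- quiet(build_network(list(protist = tb), list(protist = cl),
                                 "abundant", prevalence_min = 0.2))
      nrow(net$edges) == 0
    }, logical(1))
  })
  expect_gte(mean(zero_edges), 0.95)
})

test_that("node support scores and display flags follow Pearson r", {
  fx <- cooccurring_tables()
  cls <- lapply(fx$tables, classify_phylotypes)
  net <- quiet(build_network(fx$tables, cls, "rare", prevalence_min = 0.2))
  mf <- fx$driver
  net <- node_support_scores(net, mf)
  # oracle: covariance formula on the stored abundance matrix
  j <- match("bacteria|bacteria_O2", colnames(net$abundance))
  x <- net$abundance[, j]
  r_oracle <- sum((x - mean(x)) * (mf - mean(mf))) /
    sqrt(sum((x - mean(x))^2) * sum((mf - mean(mf))^2))
  expect_equal(net$nodes$support_score[net$nodes$id == "bacteria|bacteria_O2"],
               r_oracle, tolerance = 1e-12)
  expect_true(all(net$nodes$displayed == (net$nodes$support_score > 0), na.rm = TRUE))

  # perfect correlation / anticorrelation
  netx <- net
  netx$abundance[, 1] <- mf
  netx$abundance[, 2] <- -mf
  netx <- node_support_scores(netx, mf)
  expect_equal(netx$nodes$support_score[1], 1, tolerance = 1e-12)
  expect_equal(netx$nodes$support_score[2], -1, tolerance = 1e-12)
  expect_false(netx$nodes$displayed[2])
})

test_that("degree_support_regression behaves on exact and null inputs", {
  fx <- cooccurring_tables()
  cls <- lapply(fx$tables, classify_phylotypes)
  net <- quiet(build_network(fx$tables, cls, "rare", prevalence_min = 0.2))
  net <- node_support_scores(net, fx$driver)
  # inject an exact linear relationship
  net$nodes$support_score <- 0.01 * net$nodes$degree + 1e-9
  net$nodes$displayed <- TRUE
  fit <- suppressWarnings(degree_support_regression(net))
  expect_equal(fit$slope, 0.01, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  net$nodes$support_score <- -0.01 * net$nodes$degree - 1e-9
  net$nodes$displayed <- TRUE
  expect_lt(suppressWarnings(degree_support_regression(net))$slope, 0)

  # support independent of degree: null p-values behave
  nulls <- withr::with_seed(77, {
    vapply(1:50, function(r) {
      net$nodes$support_score <- runif(nrow(net$nodes), 0.01, 1)
      net$nodes$displayed <- TRUE
      degree_support_regression(net)$p_value > 0.05
    }, logical(1))
  })
  expect_gte(mean(nulls), 0.8)   # nominal 95%, wide MC band at 50 reps
})

test_that("network export writes GraphML, GEXF and TSVs", {
  fx <- cooccurring_tables(n = 120)
  cls <- lapply(fx$tables, classify_phylotypes)
  net <- quiet(build_network(fx$tables, cls, "rare", prevalence_min = 0.2))
  net <- node_support_scores(net, fx$driver[1:120])
  dir <- withr::local_tempdir()
  paths <- write_network(net, file.path(dir, "net"))
  expect_true(all(file.exists(paths)))
  g2 <- igraph::read_graph(paths[1], format = "graphml")
  expect_equal(igraph::gorder(g2), nrow(net$nodes))
  expect_equal(igraph::gsize(g2), nrow(net$edges))
  gexf <- readLines(paths[2])
  expect_true(any(grepl("<gexf", gexf)))
  expect_equal(sum(grepl("<node id=", gexf)), nrow(net$nodes))
})
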