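# Small fixture builders shared across tests. Everything is generated in
# code; no binary fixtures.

toy_counts <- function(n = 6, p = 10, seed = 42, lambda = 8) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * p, lambda), n, p,
                dimnames = list(sprintf("S%02d", seq_len(n)),
                                sprintf("OTU%03d", seq_len(p))))
    m
  })
}

toy_community <- function(n = 6, p = 10, seed = 42, group = "bacteria", ...) {
  suppressMessages(community_table(toy_counts(n, p, seed, ...), group = group))
}

# skewed community where classification produces all three classes
skewed_community <- function(n = 12, seed = 1, group = "bacteria") {
  withr::with_seed(seed, {
    p <- 60
    base <- c(4000, 2500, rep(30, 8), rep(2, 50))   # abundant (>0.5%) /
    # intermediate (~0.44%) / rare (~0.03%) tiers of the dataset pool
    m <- t(sapply(seq_len(n), function(i) rpois(p, base)))
    dimnames(m) <- list(sprintf("S%02d", seq_len(n)),
                        sprintf("OTU%03d", seq_len(p)))
    suppressMessages(community_table(m, group = group))
  })
}

toy_function_table <- function(n = 8, seed = 3) {
  fdef <- default_functions()
  withr::with_seed(seed, {
    vals <- matrix(runif(n * nrow(fdef), 1, 10), n, nrow(fdef),
                   dimnames = list(sprintf("S%02d", seq_len(n)), fdef$function_id))
    function_table(vals,
                   service_group = setNames(fdef$service_group, fdef$function_id),
                   sign = setNames(fdef$sign, fdef$function_id))
  })
}

toy_metadata <- function(n = 10, seed = 5) {
  withr::with_seed(seed, {
    sample_metadata(data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      latitude = sort(runif(n, 18, 49)),
      crop = rep(c("maize", "rice"), length.out = n),
      MAT = runif(n, 5, 25), pH = runif(n, 5, 8),
      total_C = runif(n, 5, 30), clay = runif(n, 10, 40),
      CEC = runif(n, 5, 25), stringsAsFactors = FALSE))
  })
}

# small full synthetic config for pipeline-level tests
small_sim_config <- function(seed = 1, ...) {
  simulation_config(n_samples = 36,
                    group_depths = c(archaea = 1500, bacteria = 2000,
                                     fungi = 1800, protist = 1200),
                    n_otus = c(archaea = 150, bacteria = 250,
                               fungi = 200, protist = 150),
                    seed = seed, ...)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
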