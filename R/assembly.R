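# accept a community_table or a plain sample x taxon abundance matrix
as_abundance_matrix <- function(x) {
  if (inherits(x, "community_table")) return(x$counts)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a community_table or a numeric matrix")
}

#' Abundance-weighted Bray-Curtis dissimilarity matrix
#'
#' BC(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk), the abundance-
#' weighted index; computed through vegan.
#'
#' @param x a [community_table()] or a numeric sample x taxon matrix
#'   (real-valued abundances allowed).
#' @return Symmetric matrix with zero diagonal, entries in \[0, 1\].
#' @export
bray_curtis_matrix <- function(x) {
  m <- as_abundance_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("Bray-Curtis undefined for all-zero samples: ",
         paste(rownames(m)[rs == 0], collapse = ", "))
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

# One null community realization under the fixed-richness,
# occurrence-frequency / regional-abundance algorithm:
#   * each null sample keeps its observed richness S_i;
#   * which phylotypes are present is drawn without replacement with
#     probability proportional to occurrence frequency across samples
#     (weighted sampling via exponential keys, equivalent in distribution to
#     successive draws without replacement);
#   * abundances of the drawn phylotypes are proportional to the regional
#     (dataset-level) relative abundances, rescaled to the sample's total.
# Consumes RNG state; callers seed via withr::with_seed.
null_realization <- function(m, freq, regional, rich, totals) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p, dimnames = dimnames(m))
  pos <- which(freq > 0)
  w <- freq[pos]
  for (i in seq_len(n)) {
    s <- rich[i]
    if (s == 0) next
    keys <- stats::rexp(length(pos)) / w
    chosen <- pos[order(keys)[seq_len(s)]]
    a <- regional[chosen]
    out[i, chosen] <- a / sum(a) * totals[i]
  }
  out
}

#' Generate null-model randomizations of a community table
#'
#' Materializes `n_null` randomized communities (see the algorithm described
#' in [stochasticity_ratio()]); intended for inspection and testing. For
#' large tables use [stochasticity_ratio()], which streams the nulls instead
#' of storing them.
#'
#' @param table a [community_table()] or abundance matrix.
#' @param n_null number of randomizations.
#' @param seed integer seed; identical seed, identical stream.
#' @return List of `n_null` abundance matrices.
#' @export
null_model_randomize <- function(table, n_null, seed) {
  stopifnot(n_null >= 1)
  m <- as_abundance_matrix(table)
  freq <- colSums(m > 0)
  regional <- colSums(m) / sum(m)
  rich <- rowSums(m > 0)
  totals <- rowSums(m)
  withr::with_seed(seed, {
    lapply(seq_len(n_null), function(k) null_realization(m, freq, regional, rich, totals))
  })
}

# equal-size contiguous rank bins; remainder samples go to the last bins
bin_sizes <- function(n, n_groups) {
  if (n_groups < 2) stop("need at least 2 groups")
  base <- n %/% n_groups
  if (base < 3) stop("bins would have fewer than 3 samples")
  sizes <- rep(base, n_groups)
  extra <- n - base * n_groups
  if (extra > 0) {
    sizes[(n_groups - extra + 1):n_groups] <- base + 1
    message(extra, " remainder sample(s) assigned to the last bins")
  }
  sizes
}

# two-branch per-pair stochasticity given observed and expected similarity
pairwise_stochasticity <- function(C, E) {
  st <- ifelse(C >= E, E / C, (1 - E) / (1 - C))
  # degenerate pairs (C = E at a boundary) are fully stochastic by definition
  st[C == E] <- 1
  st
}

#' Stochasticity ratio of community assembly
#'
#' Null-model statistic quantifying how close observed pairwise community
#' similarity is to its null expectation. Observed similarity is
#' C = 1 - Bray-Curtis; the expected similarity E is the mean similarity over
#' `n_null` randomized communities that preserve each sample's richness,
#' draw phylotype membership proportionally to occurrence frequency, and
#' fill abundances proportionally to regional relative abundances. Per pair,
#' when C >= E determinism drives similarity and the ratio is E/C; when
#' C < E determinism drives dissimilarity and the ratio is (1-E)/(1-C); both
#' branches lie in \[0, 1\], with 1 meaning indistinguishable from stochastic
#' assembly. ST is the mean over pairs. The unbounded plain ratio E/C is
#' also reported for reference.
#'
#' @param table a [community_table()] or abundance matrix, >= 3 samples.
#' @param n_null number of randomizations (default 1000).
#' @param seed integer seed.
#' @return Object of class `stochasticity_result`: `sample_ids`, `C`, `E`,
#'   `pairwise_st`, `ST`, `ST_plain`, `n_null`, `seed`.
#' @export
stochasticity_ratio <- function(table, n_null = 1000, seed) {
  m <- as_abundance_matrix(table)
  if (nrow(m) < 3) stop("need at least 3 samples")
  C <- 1 - bray_curtis_matrix(m)
  freq <- colSums(m > 0)
  regional <- colSums(m) / sum(m)
  rich <- rowSums(m > 0)
  totals <- rowSums(m)
  Esum <- matrix(0, nrow(m), nrow(m))
  withr::with_seed(seed, {
    for (k in seq_len(n_null)) {
      nullm <- null_realization(m, freq, regional, rich, totals)
      Esum <- Esum + (1 - as.matrix(vegan::vegdist(nullm, method = "bray")))
    }
  })
  E <- Esum / n_null
  ut <- upper.tri(C)
  st <- pairwise_stochasticity(C[ut], E[ut])
  plain <- E[ut] / C[ut]
  structure(list(sample_ids = rownames(m), C = C, E = E,
                 pairwise_st = st, ST = mean(st), ST_plain = mean(plain),
                 n_null = n_null, seed = seed),
            class = "stochasticity_result")
}

#' @export
print.stochasticity_result <- function(x, ...) {
  cat(sprintf("<stochasticity_result> %d samples, %d nulls: ST = %.3f\n",
              length(x$sample_ids), x$n_null, x$ST))
  invisible(x)
}

#' Stochasticity ratio across categories of an ordering variable
#'
#' Samples are ranked by `ordering` (e.g. multifunctionality or
#' multidiversity), split into `n_groups` contiguous equal-size rank bins
#' (any remainder goes to the last bins), ST is computed within each bin, and
#' a second-order polynomial is fit to ST against the bin-mean ordering
#' value.
#'
#' @param table a [community_table()] or abundance matrix.
#' @param ordering per-sample ordering variable, aligned with `table`.
#' @param n_groups number of bins (default 19).
#' @param n_null randomizations per bin.
#' @param seed master seed; per-bin seeds are derived deterministically.
#' @param degree polynomial degree for the trend (default 2).
#' @return List with `bins` (data frame: bin, n, mean_ordering, ST) and
#'   `trend` (a [polynomial_trend()] fit, or NULL if degenerate, with the
#'   degeneracy flagged).
#' @export
st_by_category <- function(table, ordering, n_groups = 19, n_null = 1000,
                           seed, degree = 2) {
  m <- as_abundance_matrix(table)
  n <- nrow(m)
  if (length(ordering) != n) stop("ordering misaligned with table")
  sizes <- bin_sizes(n, n_groups)
  ord <- order(ordering)        # stable: ties keep original order
  stops <- cumsum(sizes)
  starts <- c(1, utils::head(stops, -1) + 1)
  bins <- do.call(rbind, lapply(seq_len(n_groups), function(b) {
    idx <- ord[starts[b]:stops[b]]
    sub <- m[idx, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    st <- stochasticity_ratio(sub, n_null = n_null,
                              seed = derive_seed(seed, b))
    data.frame(bin = b, n = length(idx),
               mean_ordering = mean(ordering[idx]), ST = st$ST)
  }))
  trend <- NULL
  degenerate <- stats::sd(bins$mean_ordering) == 0
  if (!degenerate && nrow(bins) > degree + 1) {
    trend <- polynomial_trend(bins$mean_ordering, bins$ST, degree = degree)
  }
  list(bins = bins, trend = trend, degenerate = degenerate)
}
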