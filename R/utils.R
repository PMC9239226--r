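# Internal numeric helpers shared across modules.

# Column-wise Spearman correlations between two matrices, with two-sided
# p-values from the asymptotic t approximation (the same approximation
# cor.test(method = "spearman", exact = FALSE) uses). Ties get midranks.
# Returns list(rho, p); columns of X vs columns of Y.
spearman_matrix <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  rx <- apply(X, 2, rank)
  ry <- apply(Y, 2, rank)
  rho <- suppressWarnings(stats::cor(rx, ry))
  # constant columns give sd = 0 -> NA, kept as NA (undefined)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

# Pearson analogue of spearman_matrix.
pearson_matrix <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  r <- suppressWarnings(stats::cor(X, Y))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.na(r) & abs(r) >= 1] <- 0
  list(r = r, p = p)
}

# Deterministic derived seeds: a fixed keyed scheme so every stage/window is
# independently reproducible from one master seed. Kept below 2^31.
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), is.numeric(key))
  as.integer((abs(master) * 7919 + key * 104729 + 12345) %% 2147483647L)
}

# 32-bit FNV-1a hash of a string, reported as hex; used for config hashes in
# provenance headers. Arithmetic stays below 2^53 (bitwXor cannot take
# unsigned 32-bit values, so the xor touches the low byte directly and the
# multiply is split into 16-bit halves).
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * prime + ((hi16 * prime) %% 65536) * 65536) %% 4294967296
  }
  lo16 <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo16) / 65536), as.integer(lo16))
}

# Write a data frame as TSV with '# key: value' provenance comment lines.
write_tsv_provenance <- function(df, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_provenance <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Pool one abundance class across organism groups
#'
#' Concatenates the class-label subsets of several groups' tables into one
#' real-valued sample x phylotype matrix. Each group's counts are first
#' converted to within-group per-sample relative abundance, so unequal
#' sequencing depths across groups cannot fabricate structure; column names
#' are prefixed with the group. This pooled matrix is what the network and
#' assembly stages operate on.
#'
#' @param tables named list of [community_table()]s, samples aligned.
#' @param classes matching named list of [abundance_classes()].
#' @param label class label to pool.
#' @return Numeric matrix, samples x pooled phylotypes.
#' @export
pool_class_matrix <- function(tables, classes, label) {
  stopifnot(identical(names(tables), names(classes)))
  mats <- lapply(names(tables), function(g) {
    rel <- relative_abundance(tables[[g]], "per_sample")
    keep <- classes[[g]]$label == label
    m <- rel[, keep, drop = FALSE]
    if (ncol(m)) colnames(m) <- paste(g, colnames(m), sep = "|")
    m
  })
  out <- do.call(cbind, mats)
  if (is.null(out) || ncol(out) == 0) {
    stop("no '", label, "' phylotypes in any group")
  }
  out
}
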