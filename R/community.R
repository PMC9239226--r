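#' Organism groups handled by the pipeline
#'
#' @return Character vector of the four belowground organism groups.
#' @export
organism_groups <- function() c("archaea", "bacteria", "fungi", "protist")

#' Construct a community count table
#'
#' A `community_table` holds a non-negative integer count matrix with samples
#' in rows and phylotypes (OTUs) in columns, plus the organism group it
#' belongs to. Duplicate sample or phylotype identifiers are rejected, and
#' phylotypes that were never observed are dropped on construction (they carry
#' no information for richness or composition) unless `drop_empty = FALSE`,
#' which is used after rarefaction so that classification sets stay stable.
#'
#' @param counts numeric matrix or data frame, samples x phylotypes, with
#'   row and column names.
#' @param group one of [organism_groups()].
#' @param drop_empty drop all-zero phylotype columns (default `TRUE`).
#' @return An object of class `community_table` with elements `counts`
#'   (integer-valued matrix) and `group`.
#' @export
community_table <- function(counts, group, drop_empty = TRUE) {
  group <- match.arg(group, organism_groups())
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (samples x phylotypes)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry sample ids (rownames) and phylotype ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated phylotype ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (anyNA(counts) || any(!is.finite(counts))) stop("counts contain missing or non-finite values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  counts <- round(counts)
  if (drop_empty) {
    keep <- colSums(counts) > 0
    if (!all(keep)) {
      message(sum(!keep), " all-zero phylotype column(s) dropped")
      counts <- counts[, keep, drop = FALSE]
    }
  }
  if (ncol(counts) == 0L) stop("community table has no observed phylotypes")
  structure(list(counts = counts, group = group), class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> %s: %d samples x %d phylotypes, %s reads\n",
              x$group, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @rdname community_table
#' @param x a `community_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname community_table
#' @export
phylotype_ids <- function(x) colnames(x$counts)

#' Read a community table from TSV or BIOM
#'
#' TSV files carry a header row of phylotype ids and sample ids in the first
#' column (samples in rows by default; set `samples_in_rows = FALSE` for the
#' transposed convention). BIOM files (JSON 1.0 or HDF5 2.x) are read through
#' the biomformat package; BIOM stores observations (phylotypes) in rows, so
#' the matrix is transposed on import.
#'
#' @param path file path.
#' @param group one of [organism_groups()].
#' @param format `"tsv"` or `"biom"`.
#' @param samples_in_rows for TSV input, whether samples are rows.
#' @return A validated [community_table()]; a message reports the dimensions.
#' @export
read_community_table <- function(path, group, format = c("tsv", "biom"),
                                 samples_in_rows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                            stringsAsFactors = FALSE, comment.char = "#")
    bad <- !vapply(df, is.numeric, logical(1))
    if (any(bad)) {
      # locate the first non-numeric cell so the error names the row
      col <- which(bad)[1]
      vals <- suppressWarnings(as.numeric(df[[col]]))
      row <- rownames(df)[which(is.na(vals) & !is.na(df[[col]]))[1]]
      stop(sprintf("malformed community table '%s': non-numeric value in row '%s'",
                   path, row))
    }
    m <- as.matrix(df)
    if (!samples_in_rows) m <- t(m)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM input requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- t(as(biomformat::biom_data(b), "matrix"))
  }
  out <- community_table(m, group = group)
  message(sprintf("read %s community table: %d samples x %d phylotypes",
                  group, nrow(out$counts), ncol(out$counts)))
  out
}

#' Write a community table to TSV or BIOM
#'
#' @param table a [community_table()].
#' @param path destination file.
#' @param format `"tsv"` (samples in rows) or `"biom"` (BIOM 1.0 JSON).
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "community_table"))
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(table$counts), table$counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM output requires the 'biomformat' package")
    }
    biomformat::write_biom(biomformat::make_biom(t(table$counts)), path)
  }
  invisible(path)
}

#' Rarefy a community table to an even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw) down to `depth`, the standard "resampled to a minimum
#' number of sequences" normalization. Phylotype columns are retained even if
#' they end up all-zero, so abundance-class assignments computed before or
#' after rarefaction refer to the same column set.
#'
#' @param table a [community_table()].
#' @param depth target reads per sample; every sample must have at least this
#'   many reads.
#' @param seed integer seed; identical seeds give identical output. The
#'   global RNG state is left untouched.
#' @return A `community_table` whose rows all sum to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "community_table"), depth > 0)
  totals <- rowSums(table$counts)
  short <- totals < depth
  if (any(short)) {
    stop("samples with fewer than ", depth, " reads: ",
         paste(rownames(table$counts)[short], collapse = ", "))
  }
  counts <- table$counts
  out <- withr::with_seed(seed, {
    t(apply(counts, 1, function(x) {
      total <- sum(x)
      if (total == depth) return(x)
      picked <- sample(rep.int(seq_along(x), x), depth)
      tabulate(picked, nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(counts)
  community_table(out, group = table$group, drop_empty = FALSE)
}

#' Relative abundances of a community table
#'
#' @param table a [community_table()].
#' @param level `"per_sample"`: each sample's counts divided by its row total
#'   (rows sum to 1); `"dataset"`: one value per phylotype, its total count
#'   divided by the grand total (sums to 1). The dataset level is the scale on
#'   which abundant/rare classification operates.
#' @return A matrix (`per_sample`) or named vector (`dataset`).
#' @export
relative_abundance <- function(table, level = c("per_sample", "dataset")) {
  level <- match.arg(level)
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  if (sum(counts) == 0) stop("community table is empty")
  if (level == "per_sample") {
    rs <- rowSums(counts)
    if (any(rs == 0)) stop("per-sample relative abundance undefined for all-zero samples: ",
                           paste(rownames(counts)[rs == 0], collapse = ", "))
    sweep(counts, 1, rs, "/")
  } else {
    colSums(counts) / sum(counts)
  }
}
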