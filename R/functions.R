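#' The default 16-function set
#'
#' Sixteen soil ecosystem functions in four ecosystem-service groups:
#' nutrient provisioning (sugar-, chitin- and P-cycle enzyme activities,
#' dissolved organic C/N/P, microbial biomass C/N), element cycling
#' (available S, Fe, Cu, Zn, Mn), pathogen control (relative abundance of
#' fungal plant pathogens, entering analyses with a negative sign so that
#' *reduced* pathogen load counts as higher functioning), and plant-microbe
#' symbiosis (mycorrhizal fungal abundance).
#'
#' @return A data frame with columns `function_id`, `service_group`
#'   and `sign` (+1 or -1).
#' @export
default_functions <- function() {
  data.frame(
    function_id = c("beta_glucosidase", "saccharase", "n_acetylglucosaminidase",
                    "phosphatase", "dissolved_organic_C", "dissolved_organic_N",
                    "dissolved_organic_P", "microbial_biomass_C",
                    "microbial_biomass_N",
                    "available_S", "available_Fe", "available_Cu",
                    "available_Zn", "available_Mn",
                    "plant_pathogen_abundance",
                    "mycorrhizal_abundance"),
    service_group = c(rep("nutrient_provisioning", 9),
                      rep("element_cycling", 5),
                      "pathogen_control",
                      "symbiosis"),
    sign = c(rep(1, 14), -1, 1),
    stringsAsFactors = FALSE
  )
}

#' Construct an ecosystem-function table
#'
#' @param values numeric matrix, samples x functions, with row and column
#'   names; no missing values.
#' @param service_group named character vector mapping every function to an
#'   ecosystem-service group.
#' @param sign named numeric vector of +1/-1 per function; -1 marks functions
#'   (e.g. plant-pathogen abundance) that are inverted before standardization.
#'   Defaults to +1 everywhere.
#' @return An object of class `function_table`.
#' @export
function_table <- function(values, service_group, sign = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids (rownames) and function ids (colnames)")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicated sample or function ids")
  }
  if (anyNA(values) || any(!is.finite(values))) stop("function values contain missing or non-finite entries")
  fids <- colnames(values)
  if (is.null(sign)) sign <- stats::setNames(rep(1, length(fids)), fids)
  miss <- setdiff(fids, names(service_group))
  if (length(miss)) stop("functions without a service group: ", paste(miss, collapse = ", "))
  miss <- setdiff(fids, names(sign))
  if (length(miss)) stop("functions without a sign: ", paste(miss, collapse = ", "))
  service_group <- service_group[fids]
  sign <- sign[fids]
  if (!all(sign %in% c(-1, 1))) stop("signs must be +1 or -1")
  structure(list(values = values, service_group = service_group, sign = sign),
            class = "function_table")
}

#' @export
print.function_table <- function(x, ...) {
  cat(sprintf("<function_table> %d samples x %d functions (%d service groups, %d inverted)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$service_group)), sum(x$sign < 0)))
  invisible(x)
}

#' Read / write function tables with a YAML annotation sidecar
#'
#' The values live in a CSV (first column `sample_id`); the per-function
#' `service_group` and `sign` annotations live in a YAML sidecar of the form
#' `function_id: {service_group: ..., sign: ...}`.
#'
#' @param path CSV file of function values.
#' @param annotations path to the YAML sidecar.
#' @return A [function_table()].
#' @export
read_function_table <- function(path, annotations) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  ann <- yaml::read_yaml(annotations)
  sg <- vapply(ann, function(a) a$service_group, character(1))
  sg <- stats::setNames(sg, names(ann))
  sn <- vapply(ann, function(a) as.numeric(a$sign %||% 1), numeric(1))
  sn <- stats::setNames(sn, names(ann))
  function_table(as.matrix(df), service_group = sg, sign = sn)
}

#' @rdname read_function_table
#' @param ft a [function_table()].
#' @export
write_function_table <- function(ft, path, annotations) {
  stopifnot(inherits(ft, "function_table"))
  df <- data.frame(sample_id = rownames(ft$values), ft$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  ann <- lapply(colnames(ft$values), function(f) {
    list(service_group = unname(ft$service_group[f]), sign = unname(ft$sign[f]))
  })
  names(ann) <- colnames(ft$values)
  yaml::write_yaml(ann, annotations)
  invisible(path)
}

#' Construct a sample metadata table
#'
#' @param df data frame with columns `sample_id`, `latitude`, `crop`
#'   (`maize`/`rice`), `MAT` (degC), `pH`, `total_C` (g/kg), `clay` (%),
#'   `CEC` (cmol/kg).
#' @return An object of class `sample_metadata` (a validated data frame).
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "latitude", "crop", "MAT", "pH", "total_C", "clay", "CEC")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in metadata")
  if (anyNA(df$latitude) || any(!is.finite(df$latitude))) stop("latitude must be finite")
  if (!all(df$crop %in% c("maize", "rice"))) stop("crop must be 'maize' or 'rice'")
  df <- df[, need]
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @rdname sample_metadata
#' @param path CSV path.
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(utils::read.csv(path, check.names = FALSE,
                                  stringsAsFactors = FALSE))
}

#' @rdname sample_metadata
#' @param md a `sample_metadata` object.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.csv(as.data.frame(md), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align community tables, functions and metadata on shared samples
#'
#' Reorders every component to the intersection of sample ids, erroring if
#' the intersection is empty.
#'
#' @param tables named list of [community_table()]s.
#' @param functions a [function_table()].
#' @param metadata a [sample_metadata()].
#' @return List with aligned `tables`, `functions`, `metadata`.
#' @export
align_samples <- function(tables, functions, metadata) {
  ids <- Reduce(intersect, c(lapply(tables, sample_ids),
                             list(rownames(functions$values), metadata$sample_id)))
  if (length(ids) == 0) stop("no samples shared across inputs")
  tables <- lapply(tables, function(tb) {
    tb$counts <- tb$counts[ids, , drop = FALSE]
    tb
  })
  functions$values <- functions$values[ids, , drop = FALSE]
  metadata <- metadata[match(ids, metadata$sample_id), ]
  list(tables = tables, functions = functions, metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
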