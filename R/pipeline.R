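#' Pipeline configuration
#'
#' One configuration object drives the whole analysis. Either `input_dir`
#' (a directory in the [write_dataset()] layout) or `simulation` (a
#' [simulation_config()]) must be given. Defaults mirror the survey
#' design: 0.5%/0.05% thresholds, |rho| > 0.6 with q < 0.001
#' network edges, 1,000 null randomizations, window sizes 30 and 40, and 19
#' rank bins.
#'
#' @param input_dir directory holding community/function/metadata files, or
#'   NULL to simulate.
#' @param simulation a [simulation_config()], or NULL to read files.
#' @param scheme a [threshold_scheme()].
#' @param mf_method which multifunctionality index drives the BEF, ST and
#'   window stages: `"averaging"`, `"weighted"` or `"multidimensional"`.
#' @param rho_min,q_max network edge thresholds.
#' @param network_prevalence,support_prevalence occupancy filters.
#' @param n_null null-model randomizations (default 1,000; reduce for
#'   quick runs).
#' @param n_groups rank bins for the ST-by-category stage.
#' @param window_sizes moving-window lengths.
#' @param window_n_null randomizations per window (smaller than `n_null`
#'   because 388 windows are evaluated).
#' @param seed master seed; stage seeds are derived from it by a fixed keyed
#'   scheme so every stage is independently reproducible.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulation = NULL,
                            scheme = threshold_scheme(),
                            mf_method = c("averaging", "weighted", "multidimensional"),
                            rho_min = 0.6, q_max = 0.001,
                            network_prevalence = 0.2, support_prevalence = 0.1,
                            n_null = 1000, n_groups = 19,
                            window_sizes = c(30, 40), window_n_null = 100,
                            seed = 1) {
  mf_method <- match.arg(mf_method)
  if (is.null(input_dir) && is.null(simulation)) {
    stop("config needs either an input directory or a simulation block")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input directory does not exist: ", input_dir)
  }
  structure(list(input_dir = input_dir, simulation = simulation,
                 scheme = scheme, mf_method = mf_method,
                 rho_min = rho_min, q_max = q_max,
                 network_prevalence = network_prevalence,
                 support_prevalence = support_prevalence,
                 n_null = n_null, n_groups = n_groups,
                 window_sizes = window_sizes, window_n_null = window_n_null,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; a `simulation`
#' block (if present) mirrors [simulation_config()], a `scheme` block takes
#' `abundant_min`/`rare_max`/`name`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) {
    args <- y$simulation
    for (nm in c("group_depths", "n_otus")) {
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    }
    if (!is.null(args$latitude_range)) args$latitude_range <- unlist(args$latitude_range)
    do.call(simulation_config, args)
  }
  scheme <- if (!is.null(y$scheme)) do.call(threshold_scheme, y$scheme) else threshold_scheme()
  args <- y[setdiff(names(y), c("simulation", "scheme"))]
  if (!is.null(args$window_sizes)) args$window_sizes <- unlist(args$window_sizes)
  do.call(pipeline_config, c(args, list(simulation = sim, scheme = scheme)))
}

config_hash <- function(config) {
  fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, force = TRUE,
                         digits = NA))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> partition -> diversity ->
#' multifunctionality -> BEF/support -> networks -> assembly -> moving
#' window, writing every result as TSV (plus GraphML/GEXF for networks)
#' under `out_dir`. Every output carries `# key: value` provenance header
#' lines (package version, master seed, config hash). Stage failures abort
#' with the failing stage named.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(package = paste0("rarebef ", as.character(utils::packageVersion("rarebef"))),
               seed = config$seed, config_hash = config_hash(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ds <- stage("input", {
    if (!is.null(config$simulation)) {
      d <- generate_dataset(config$simulation)
      write_dataset(d, file.path(out_dir, "dataset"))
      d
    } else {
      read_dataset(config$input_dir)
    }
  })
  aligned <- align_samples(ds$tables, ds$functions, ds$metadata)
  tables <- aligned$tables
  message("pipeline: ", nrow(aligned$metadata), " samples, groups: ",
          paste(sprintf("%s(%d)", names(tables),
                        vapply(tables, function(t) ncol(t$counts), 1L)),
                collapse = ", "))

  classes <- stage("partition", {
    cl <- lapply(tables, classify_phylotypes, scheme = config$scheme)
    write_tsv_provenance(do.call(rbind, lapply(cl, classification_frame)),
                         file.path(out_dir, "classification.tsv"), prov)
    cl
  })

  div <- stage("diversity", {
    d <- diversity_table(tables, classes)
    write_tsv_provenance(data.frame(sample_id = d$sample_ids, d$richness,
                                    multidiversity = d$multidiversity,
                                    check.names = FALSE),
                         file.path(out_dir, "diversity.tsv"), prov)
    d
  })

  mf <- stage("multifunctionality", {
    m <- multifunctionality(aligned$functions)
    write_tsv_provenance(data.frame(sample_id = m$sample_ids,
                                    averaging = m$averaging,
                                    weighted = m$weighted,
                                    multidimensional = m$multidimensional),
                         file.path(out_dir, "multifunctionality.tsv"), prov)
    write_tsv_provenance(data.frame(axis = seq_along(m$eigenvalues),
                                    eigenvalue = m$eigenvalues),
                         file.path(out_dir, "pcoa_eigenvalues.tsv"), prov)
    m
  })
  mf_vec <- stats::setNames(mf[[config$mf_method]], mf$sample_ids)

  bef <- stage("bef", {
    fits <- lapply(c(rare = "rare", abundant = "abundant"), function(lab) {
      bef_regression(div$multidiversity[, lab], mf_vec)
    })
    write_tsv_provenance(
      data.frame(subcommunity = names(fits),
                 slope = vapply(fits, `[[`, 1, "slope"),
                 standardized_slope = vapply(fits, `[[`, 1, "standardized_slope"),
                 r_squared = vapply(fits, `[[`, 1, "r_squared"),
                 p_value = vapply(fits, `[[`, 1, "p_value"),
                 n = vapply(fits, `[[`, 1, "n")),
      file.path(out_dir, "bef_regressions.tsv"), prov)
    divlist <- stats::setNames(
      lapply(colnames(div$richness), function(cn) div$richness[, cn]),
      colnames(div$richness))
    corr <- diversity_function_correlations(divlist, mf$standardized_functions)
    long <- expand.grid(diversity = rownames(corr$rho),
                        function_id = colnames(corr$rho),
                        stringsAsFactors = FALSE)
    long$rho <- as.vector(corr$rho)
    long$p <- as.vector(corr$p)
    long$significant <- as.vector(corr$significant)
    write_tsv_provenance(long, file.path(out_dir, "diversity_function_correlations.tsv"),
                         prov)
    list(regressions = fits, correlations = corr)
  })

  support <- stage("support", {
    sts <- lapply(names(tables), function(g) {
      suppressMessages(supporting_phylotypes(tables[[g]], classes[[g]],
                                             mf$standardized_functions,
                                             prevalence_min = config$support_prevalence))
    })
    st <- combine_support_tables(sts)
    smry <- support_summary(st, aligned$functions$service_group)
    breadth <- tryCatch(compare_support_breadth(st), error = function(e) NULL)
    write_tsv_provenance(data.frame(st$phylotypes,
                                    n_functions_supported = st$n_functions_supported),
                         file.path(out_dir, "support_phylotypes.tsv"), prov)
    write_tsv_provenance(smry$per_function,
                         file.path(out_dir, "support_per_function.tsv"), prov)
    write_tsv_provenance(smry$per_class,
                         file.path(out_dir, "support_per_class.tsv"), prov)
    list(table = st, summary = smry, breadth = breadth)
  })

  nets <- stage("network", {
    lapply(c(abundant = "abundant", rare = "rare"), function(lab) {
      net <- tryCatch(
        suppressMessages(build_network(tables, classes, lab,
                                       prevalence_min = config$network_prevalence,
                                       rho_min = config$rho_min,
                                       q_max = config$q_max)),
        error = function(e) NULL)
      if (is.null(net)) return(NULL)
      net <- node_support_scores(net, mf_vec)
      write_network(net, file.path(out_dir, paste0("network_", lab)))
      reg <- tryCatch(degree_support_regression(net), error = function(e) NULL)
      list(network = net, degree_regression = reg)
    })
  })

  assembly <- stage("assembly", {
    out <- lapply(c(rare = "rare", abundant = "abundant"), function(lab) {
      pooled <- pool_class_matrix(tables, classes, lab)
      st <- stochasticity_ratio(pooled, n_null = config$n_null,
                                seed = derive_seed(config$seed, match(lab, c("rare", "abundant"))))
      by_mf <- st_by_category(pooled, mf_vec, n_groups = config$n_groups,
                              n_null = config$n_null,
                              seed = derive_seed(config$seed, 10 + match(lab, c("rare", "abundant"))))
      by_md <- st_by_category(pooled, div$multidiversity[, lab],
                              n_groups = config$n_groups, n_null = config$n_null,
                              seed = derive_seed(config$seed, 20 + match(lab, c("rare", "abundant"))))
      list(st = st, by_multifunctionality = by_mf, by_multidiversity = by_md)
    })
    for (lab in names(out)) {
      write_tsv_provenance(out[[lab]]$by_multifunctionality$bins,
                           file.path(out_dir, paste0("st_by_multifunctionality_", lab, ".tsv")),
                           prov)
      write_tsv_provenance(out[[lab]]$by_multidiversity$bins,
                           file.path(out_dir, paste0("st_by_multidiversity_", lab, ".tsv")),
                           prov)
    }
    write_tsv_provenance(
      data.frame(subcommunity = names(out),
                 ST = vapply(out, function(o) o$st$ST, 1),
                 ST_plain = vapply(out, function(o) o$st$ST_plain, 1),
                 n_null = config$n_null),
      file.path(out_dir, "stochasticity.tsv"), prov)
    out
  })

  windows <- stage("window", {
    pooled_rare <- pool_class_matrix(tables, classes, "rare")
    res <- lapply(config$window_sizes, function(w) {
      ws <- make_windows(aligned$metadata, w)
      wr <- window_bef_st(ws,
                          stats::setNames(div$multidiversity[, "rare"], div$sample_ids),
                          mf_vec, pooled_rare,
                          n_null = config$window_n_null,
                          seed = derive_seed(config$seed, 100 + w))
      write_tsv_provenance(wr$per_window,
                           file.path(out_dir, sprintf("window_%d.tsv", w)), prov)
      wr
    })
    names(res) <- paste0("w", config$window_sizes)
    res
  })

  invisible(list(dataset = ds, classes = classes, diversity = div,
                 multifunctionality = mf, bef = bef, support = support,
                 networks = nets, assembly = assembly, windows = windows,
                 provenance = prov))
}
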