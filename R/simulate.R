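#' Configuration for the synthetic survey generator
#'
#' The defaults emulate the design of a 228-field multitrophic soil survey:
#' 114 maize and 114 rice fields along a latitude gradient (18.30-48.35
#' degrees N), four organism groups rarefied to fixed depths (archaea
#' 36,880; bacteria 27,712; fungi 30,369; protists 5,393 reads), heavily
#' right-skewed lognormal regional abundance profiles in which most
#' phylotypes are rare, and 16 ecosystem functions in four service groups
#' with one inverted (pathogen-abundance) function.
#'
#' Mechanisms and their knobs:
#' * `beta_env` - strength of deterministic (latitude) filtering of
#'   community composition. Each phylotype has a latitude optimum with a
#'   Gaussian response of width `niche_breadth`; abundant regional taxa
#'   (regional share >= `generalist_min`) are habitat generalists whose
#'   filter is damped by `generalist_damp`, so their abundance varies along
#'   the gradient but their occupancy stays broad. `beta_env = 0` gives
#'   purely stochastic assembly.
#' * `occupancy`, `overdispersion_sd` - latitude-independent patchiness
#'   (Bernoulli presence thinning) and lognormal compositional noise; these
#'   supply realistic, environmentally unstructured variation (without them
#'   abundant-subcommunity richness would be degenerate).
#' * `beta_rare`, `beta_abundant` - linear effect of the realized rare /
#'   abundant multidiversity on every function's mean (units: standardized
#'   function scale per unit multidiversity, both in \[0, 1\]).
#' * `env_function_effect` - optional direct latitude effect on functions
#'   (0 by default, so functions respond to the environment only through
#'   diversity).
#' * `noise_sd` - per-function Gaussian noise on the latent scale.
#'
#' @param n_samples number of fields (default 228, split evenly
#'   maize/rice).
#' @param group_depths named vector of per-group rarefaction depths.
#' @param n_otus named vector of per-group regional pool sizes.
#' @param lognormal_meanlog,lognormal_sdlog shape of the regional
#'   log-abundance distribution.
#' @param beta_rare,beta_abundant,beta_env,env_function_effect,noise_sd
#'   effect sizes, see above.
#' @param occupancy,overdispersion_sd,niche_breadth,generalist_min,generalist_damp
#'   compositional noise and filtering controls, see above.
#' @param latitude_range sampled latitude span in decimal degrees.
#' @param seed integer master seed; identical seed, identical dataset.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 228,
                              group_depths = c(archaea = 36880, bacteria = 27712,
                                               fungi = 30369, protist = 5393),
                              n_otus = c(archaea = 2000, bacteria = 4000,
                                         fungi = 2500, protist = 2000),
                              lognormal_meanlog = 0,
                              lognormal_sdlog = 2.2,
                              beta_rare = 0.8,
                              beta_abundant = 0,
                              beta_env = 2,
                              env_function_effect = 0,
                              noise_sd = 0.3,
                              occupancy = 0.95,
                              overdispersion_sd = 0.25,
                              niche_breadth = 10,
                              generalist_min = 0.005,
                              generalist_damp = 0.15,
                              latitude_range = c(18.30, 48.35),
                              seed = 1) {
  if (is.null(names(group_depths)) || !all(names(group_depths) %in% organism_groups())) {
    stop("group_depths must be named with organism groups")
  }
  if (!identical(sort(names(group_depths)), sort(names(n_otus)))) {
    stop("group_depths and n_otus must name the same groups")
  }
  if (any(group_depths <= 0) || any(n_otus <= 0) || n_samples < 4) {
    stop("counts and depths must be positive, n_samples >= 4")
  }
  stopifnot(is.finite(beta_rare), is.finite(beta_abundant), is.finite(beta_env),
            noise_sd >= 0, occupancy > 0, occupancy <= 1)
  structure(list(n_samples = n_samples, group_depths = group_depths,
                 n_otus = n_otus, lognormal_meanlog = lognormal_meanlog,
                 lognormal_sdlog = lognormal_sdlog, beta_rare = beta_rare,
                 beta_abundant = beta_abundant, beta_env = beta_env,
                 env_function_effect = env_function_effect,
                 noise_sd = noise_sd, occupancy = occupancy,
                 overdispersion_sd = overdispersion_sd,
                 niche_breadth = niche_breadth, generalist_min = generalist_min,
                 generalist_damp = generalist_damp,
                 latitude_range = latitude_range, seed = seed),
            class = "simulation_config")
}

# min-max standardize with a neutral fallback for constant vectors (used
# only inside the generator, where a degenerate subcommunity must not abort
# data generation)
safe_std <- function(x) {
  if (max(x) == min(x)) {
    warning("constant richness vector in generator; contributing 0.5")
    return(rep(0.5, length(x)))
  }
  (x - min(x)) / (max(x) - min(x))
}

#' Generate a synthetic multitrophic survey dataset
#'
#' Draws the full dataset described by a [simulation_config()]: per-group
#' community tables (every sample at its group's depth), a 16-function
#' table, sample metadata along the latitude gradient, and a truth record
#' holding the generating parameters and the realized latent diversity
#' signals for parameter-recovery scoring. The function signal is built from
#' the *realized* standardized richness of the generated rare and abundant
#' subcommunities (classified with the default 0.5%/0.05% scheme), so
#' recovery targets are exact in expectation.
#'
#' @param config a [simulation_config()].
#' @return Object of class `synthetic_dataset` with elements `tables`,
#'   `functions`, `metadata`, `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  groups <- names(config$group_depths)
  n <- config$n_samples
  withr::with_seed(config$seed, {
    lat <- sort(stats::runif(n, config$latitude_range[1], config$latitude_range[2]))
    ids <- sprintf("S%03d", seq_len(n))
    crop <- rep(c("maize", "rice"), length.out = n)
    metadata <- sample_metadata(data.frame(
      sample_id = ids, latitude = lat, crop = crop,
      MAT = 28 - 0.65 * (lat - 18) + stats::rnorm(n, 0, 0.8),
      pH = 5.3 + 0.055 * (lat - 18) + stats::rnorm(n, 0, 0.3),
      total_C = exp(stats::rnorm(n, log(12), 0.4)),
      clay = stats::runif(n, 8, 45),
      CEC = 4 + 0.4 * stats::runif(n, 8, 45) + stats::rnorm(n, 0, 1),
      stringsAsFactors = FALSE))

    tables <- lapply(groups, function(g) {
      N <- config$n_otus[[g]]
      a <- stats::rlnorm(N, config$lognormal_meanlog, config$lognormal_sdlog)
      share <- a / sum(a)
      opt <- stats::runif(N, config$latitude_range[1], config$latitude_range[2])
      # generalist abundant taxa feel only a damped latitude filter
      beta_i <- config$beta_env *
        ifelse(share >= config$generalist_min, config$generalist_damp, 1)
      D2 <- outer(lat, opt, "-")^2
      logw <- -sweep(D2, 2, beta_i / (2 * config$niche_breadth^2), "*")
      eps <- matrix(stats::rnorm(n * N, 0, config$overdispersion_sd), n, N)
      mask <- matrix(stats::rbinom(n * N, 1, config$occupancy), n, N)
      Praw <- sweep(exp(logw + eps), 2, share, "*")
      P <- Praw * mask
      # occupancy dropout redistributes mass only within its own block
      # (generalists among generalists, the tail among the tail): letting a
      # dropped generalist's percent-level share flow into the rare tail
      # would couple abundant richness negatively to rare richness, a
      # compositional artifact the generated world must not contain
      gen <- share >= config$generalist_min
      for (block in list(gen, !gen)) {
        if (!any(block)) next
        raw_tot <- rowSums(Praw[, block, drop = FALSE])
        msk_tot <- rowSums(P[, block, drop = FALSE])
        dead <- msk_tot == 0 & raw_tot > 0
        if (any(dead)) {        # whole block masked out: keep it unmasked
          P[dead, block] <- Praw[dead, block, drop = FALSE]
          msk_tot[dead] <- raw_tot[dead]
        }
        ok <- msk_tot > 0
        P[ok, block] <- P[ok, block, drop = FALSE] * (raw_tot[ok] / msk_tot[ok])
      }
      counts <- t(apply(P, 1, function(p) {
        stats::rmultinom(1, config$group_depths[[g]], p)[, 1]
      }))
      dimnames(counts) <- list(ids, sprintf("%s_OTU%05d", g, seq_len(N)))
      suppressMessages(community_table(counts, group = g))
    })
    names(tables) <- groups

    classes <- lapply(tables, classify_phylotypes, scheme = threshold_scheme())
    rich_of <- function(lab) {
      lapply(groups, function(g) {
        richness(suppressWarnings(subset_community(tables[[g]], classes[[g]], lab)))
      })
    }
    md_rare <- rowMeans(vapply(rich_of("rare"), safe_std, numeric(n)))
    md_abund <- rowMeans(vapply(rich_of("abundant"), safe_std, numeric(n)))
    env_std <- safe_std(lat)

    lp <- config$beta_rare * md_rare + config$beta_abundant * md_abund +
      config$env_function_effect * env_std
    fdef <- default_functions()
    scale01 <- function(y) (y - min(y)) / max(max(y) - min(y), .Machine$double.eps)
    base <- c(120, 90, 45, 160, 80, 25, 8, 300, 40, 30, 60, 2, 3, 15, 0, 0)
    range_ <- c(140, 110, 60, 180, 90, 30, 10, 350, 50, 35, 70, 3, 4, 20, 0, 0)
    vals <- matrix(NA_real_, n, nrow(fdef), dimnames = list(ids, fdef$function_id))
    for (j in seq_len(nrow(fdef))) {
      y <- lp + stats::rnorm(n, 0, config$noise_sd)
      vals[, j] <- if (fdef$function_id[j] == "plant_pathogen_abundance") {
        0.08 - 0.06 * scale01(y)      # high latent functioning = low pathogen load
      } else if (fdef$function_id[j] == "mycorrhizal_abundance") {
        0.001 + 0.05 * scale01(y)
      } else {
        base[j] + range_[j] * scale01(y)
      }
    }
    functions <- function_table(vals,
                                service_group = stats::setNames(fdef$service_group,
                                                                fdef$function_id),
                                sign = stats::setNames(fdef$sign, fdef$function_id))

    truth <- list(beta_rare = config$beta_rare,
                  beta_abundant = config$beta_abundant,
                  beta_env = config$beta_env,
                  env_function_effect = config$env_function_effect,
                  noise_sd = config$noise_sd,
                  seed = config$seed,
                  md_rare = stats::setNames(md_rare, ids),
                  md_abundant = stats::setNames(md_abund, ids))
    structure(list(tables = tables, functions = functions,
                   metadata = metadata, truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples, groups: %s; 16-fn table: %s\n",
              nrow(x$metadata), paste(names(x$tables), collapse = ", "),
              paste(dim(x$functions$values), collapse = " x ")))
  invisible(x)
}

#' Write / read a synthetic dataset as plain-text files
#'
#' Emits one TSV community table per group (`community_<group>.tsv`),
#' `functions.csv` + `functions.yml` (values and service-group/sign
#' annotations), `metadata.csv`, and `truth.yml`; [read_dataset()]
#' reconstructs the in-memory object (minus the config).
#'
#' @param ds a [generate_dataset()] result.
#' @param dir destination directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  for (g in names(ds$tables)) {
    write_community_table(ds$tables[[g]], file.path(dir, paste0("community_", g, ".tsv")))
  }
  write_function_table(ds$functions, file.path(dir, "functions.csv"),
                       file.path(dir, "functions.yml"))
  write_sample_metadata(ds$metadata, file.path(dir, "metadata.csv"))
  truth <- ds$truth
  truth$md_rare <- as.list(truth$md_rare)
  truth$md_abundant <- as.list(truth$md_abundant)
  yaml::write_yaml(truth, file.path(dir, "truth.yml"), precision = 15)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  paths <- list.files(dir, pattern = "^community_.*\\.tsv$", full.names = TRUE)
  if (!length(paths)) stop("no community tables found in ", dir)
  groups <- sub("^community_(.*)\\.tsv$", "\\1", basename(paths))
  tables <- stats::setNames(lapply(seq_along(paths), function(i) {
    suppressMessages(read_community_table(paths[i], group = groups[i]))
  }), groups)
  truth <- NULL
  if (file.exists(file.path(dir, "truth.yml"))) {
    truth <- yaml::read_yaml(file.path(dir, "truth.yml"))
    truth$md_rare <- unlist(truth$md_rare)
    truth$md_abundant <- unlist(truth$md_abundant)
  }
  structure(list(tables = tables,
                 functions = read_function_table(file.path(dir, "functions.csv"),
                                                 file.path(dir, "functions.yml")),
                 metadata = read_sample_metadata(file.path(dir, "metadata.csv")),
                 truth = truth, config = NULL),
            class = "synthetic_dataset")
}
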