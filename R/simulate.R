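#' Configuration for a replicate flux simulation
#'
#' @param conditions data.frame of (carbon, nitrogen) pairs, usually from
#'   [condition_grid()].
#' @param replicates replicates per condition (each with freshly sampled
#'   impurities).
#' @param k_C,k_N number of carbon / nitrogen impurities per replicate.
#' @param primary_uptake,impurity_uptake,oxygen_uptake exchange lower bounds
#'   passed to [growth_environment()]; `nitrogen_uptake` overrides the
#'   nitrogen primary bound for excess-uptake scenarios (default: same as
#'   `primary_uptake`).
#' @param nitrogen_uptake optional distinct uptake bound for the nitrogen
#'   primary source (excess-C/excess-N scenarios set one side to -1000).
#' @param viability_threshold biomass cutoff; observations at or below it
#'   are dropped (default 0.558, the genome-scale reference value; pass
#'   a value computed by [compute_viability_threshold()] for other models).
#' @param flux_min if `TRUE`, run [minimize_total_flux()] after each biomass
#'   maximization and record the parsimonious fluxes.
#' @param noise_sd standard deviation of optional Gaussian measurement noise
#'   added to recorded internal fluxes (default 0 = off; FBA itself is
#'   deterministic and all stochasticity comes from impurity sampling).
#' @param seed integer seed for impurity sampling (and noise, if enabled).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(conditions, replicates = 100, k_C = 1, k_N = 1,
                              primary_uptake = -20, impurity_uptake = -0.2,
                              oxygen_uptake = -18.5, nitrogen_uptake = NULL,
                              viability_threshold = 0.558, flux_min = FALSE,
                              noise_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(conditions),
            all(c("carbon", "nitrogen") %in% names(conditions)),
            replicates >= 1, is.finite(viability_threshold))
  structure(list(conditions = conditions, replicates = as.integer(replicates),
                 k_C = as.integer(k_C), k_N = as.integer(k_N),
                 primary_uptake = primary_uptake,
                 impurity_uptake = impurity_uptake,
                 oxygen_uptake = oxygen_uptake,
                 nitrogen_uptake = if (is.null(nitrogen_uptake)) primary_uptake
                                   else nitrogen_uptake,
                 viability_threshold = viability_threshold,
                 flux_min = isTRUE(flux_min), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate labeled internal-flux datasets over a condition grid
#'
#' For every (carbon, nitrogen) condition and replicate: sample impurities,
#' apply the environment to the model, maximize biomass (optionally followed
#' by total-flux minimization), and record the internal-reaction fluxes.
#' Observations whose biomass does not exceed the viability threshold —
#' including infeasible solves, recorded as biomass 0 — are dropped and
#' counted in the attached log.
#'
#' @param model a [metabolic_model()].
#' @param pool a [substrate_pool()] supplying the impurity candidates.
#' @param config a [simulation_config()].
#' @param partition optional precomputed [classify_reactions()] result.
#' @return An object of class `flux_dataset`: list with `X` (viable
#'   observations x internal reactions), `carbon`, `nitrogen`, `biomass`,
#'   `replicate`, `impurities` (list of per-observation impurity draws) and
#'   `internal_ids`; attribute `log` records total, viable and dropped
#'   counts.
#' @export
run_simulation <- function(model, pool, config, partition = NULL) {
  if (is.null(partition)) partition <- classify_reactions(model)
  internal <- partition$internal_ids
  conds <- config$conditions
  n_total <- nrow(conds) * config$replicates

  X <- matrix(NA_real_, n_total, length(internal),
              dimnames = list(NULL, internal))
  carbon <- character(n_total); nitrogen <- character(n_total)
  biomass <- numeric(n_total); replicate <- integer(n_total)
  impurities <- vector("list", n_total)

  row <- 0L
  with_seed(config$seed, for (ci in seq_len(nrow(conds))) {
    for (rep_i in seq_len(config$replicates)) {
      row <- row + 1L
      cs <- conds$carbon[ci]; ns <- conds$nitrogen[ci]
      imp <- sample_impurities(pool, config$k_C, config$k_N,
                               exclude = c(cs, ns))
      env <- growth_environment(cs, ns,
                                impurities_C = imp$impurities_C,
                                impurities_N = imp$impurities_N,
                                primary_uptake = config$primary_uptake,
                                impurity_uptake = config$impurity_uptake,
                                oxygen_uptake = config$oxygen_uptake,
                                nitrogen_uptake = config$nitrogen_uptake)
      bounded <- apply_environment(model, env, pool)
      sol <- solve_fba(bounded)
      if (sol$status == "optimal" && config$flux_min)
        sol <- minimize_total_flux(bounded, sol$biomass)
      carbon[row] <- cs; nitrogen[row] <- ns; replicate[row] <- rep_i
      impurities[[row]] <- imp
      if (sol$status == "optimal") {
        biomass[row] <- sol$biomass
        X[row, ] <- sol$fluxes[internal]
      } else {
        biomass[row] <- 0
      }
    }
  })
  if (config$noise_sd > 0)
    X <- X + with_seed(config$seed + 1L,
                       matrix(stats::rnorm(length(X), 0, config$noise_sd),
                              nrow(X), ncol(X)))

  viable <- biomass > config$viability_threshold & !is.na(X[, 1])
  log <- list(n_total = n_total, n_viable = sum(viable),
              n_dropped = n_total - sum(viable),
              viability_threshold = config$viability_threshold)
  structure(list(X = X[viable, , drop = FALSE],
                 carbon = carbon[viable], nitrogen = nitrogen[viable],
                 biomass = biomass[viable], replicate = replicate[viable],
                 impurities = impurities[viable],
                 internal_ids = internal),
            class = "flux_dataset", log = log)
}

#' @export
print.flux_dataset <- function(x, ...) {
  cat("<flux_dataset> ", nrow(x$X), " observations x ", ncol(x$X),
      " internal reactions\n", sep = "")
  lg <- attr(x, "log")
  if (!is.null(lg))
    cat("  viable ", lg$n_viable, "/", lg$n_total, " (threshold ",
        lg$viability_threshold, ")\n", sep = "")
  invisible(x)
}

subset_flux_dataset <- function(dataset, idx) {
  structure(list(X = dataset$X[idx, , drop = FALSE],
                 carbon = dataset$carbon[idx], nitrogen = dataset$nitrogen[idx],
                 biomass = dataset$biomass[idx],
                 replicate = dataset$replicate[idx],
                 impurities = dataset$impurities[idx],
                 internal_ids = dataset$internal_ids),
            class = "flux_dataset")
}

#' Stratified train/test split of a flux dataset
#'
#' Splits by (carbon, nitrogen) condition so every class is represented on
#' both sides even at small training sizes. Half the data (by default)
#' forms the test set; the training set is drawn from the remainder, down-
#' sampled per stratum to `train_size` total observations when requested.
#'
#' @param dataset a `flux_dataset`.
#' @param test_fraction fraction of each stratum held out for testing.
#' @param train_size optional total training-set size (taken as evenly as
#'   possible across strata); default: the full remaining half.
#' @param seed integer seed for the stratified draw.
#' @return List with elements `train` and `test`, both `flux_dataset`s.
#' @export
split_train_test <- function(dataset, test_fraction = 0.5, train_size = NULL,
                             seed = 1L) {
  n <- nrow(dataset$X)
  cond <- paste(dataset$carbon, dataset$nitrogen, sep = "|")
  shuffle <- function(v) if (length(v) <= 1L) v else sample(v)
  test_idx <- integer(0)
  pool_idx <- integer(0)
  with_seed(seed, for (g in unique(cond)) {
    idx <- shuffle(which(cond == g))
    k <- round(length(idx) * test_fraction)
    test_idx <- c(test_idx, idx[seq_len(k)])
    pool_idx <- c(pool_idx, idx[setdiff(seq_along(idx), seq_len(k))])
  })
  if (is.null(train_size)) {
    train_idx <- pool_idx
  } else {
    if (train_size > length(pool_idx))
      stop("train_size = ", train_size, " exceeds the ", length(pool_idx),
           " observations available after the test split")
    # round-robin across strata: take one observation per stratum in turn
    by_g <- split(pool_idx, cond[pool_idx])
    by_g <- with_seed(seed + 1L, lapply(by_g, shuffle))
    train_idx <- integer(0)
    r <- 1L
    while (length(train_idx) < train_size) {
      for (g in names(by_g)) {
        if (length(train_idx) >= train_size) break
        if (length(by_g[[g]]) >= r) train_idx <- c(train_idx, by_g[[g]][r])
      }
      r <- r + 1L
    }
  }
  list(train = subset_flux_dataset(dataset, sort(train_idx)),
       test = subset_flux_dataset(dataset, sort(test_idx)))
}
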