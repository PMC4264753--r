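#' Substrate pool of candidate carbon and nitrogen sources
#'
#' Maps substrate identifiers to the exchange reactions through which they
#' enter the model. The genome-scale reference pool (174 carbon and 78
#' nitrogen sources) is supplied by the user as a two-column TSV; toy pools
#' are emitted by [generate_toy_model()].
#'
#' @param carbon,nitrogen named character vectors: names are substrate ids,
#'   values the corresponding exchange reaction ids. An unnamed vector is
#'   taken to name itself.
#' @return An object of class `substrate_pool`.
#' @export
substrate_pool <- function(carbon, nitrogen) {
  fix <- function(x) {
    x <- vapply(x, as.character, "")
    if (is.null(names(x)) || any(names(x) == "")) names(x) <- x
    x
  }
  carbon <- fix(carbon); nitrogen <- fix(nitrogen)
  if (!length(carbon) || !length(nitrogen))
    stop("both carbon and nitrogen pools must be non-empty")
  structure(list(carbon = carbon, nitrogen = nitrogen),
            class = "substrate_pool")
}

#' Read a substrate pool from a two-column TSV (substrate id, role C or N)
#'
#' @param path TSV file with columns `substrate` (or `exchange`) and `role`.
#' @return A [substrate_pool()].
#' @export
read_substrate_pool <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("substrate", "role") %in% names(tab)))
    stop("substrate pool file needs columns 'substrate' and 'role'")
  ex <- if ("exchange" %in% names(tab)) tab$exchange else tab$substrate
  role <- toupper(tab$role)
  if (!all(role %in% c("C", "N")))
    stop("role column must contain only 'C' or 'N'")
  substrate_pool(carbon = stats::setNames(ex[role == "C"], tab$substrate[role == "C"]),
                 nitrogen = stats::setNames(ex[role == "N"], tab$substrate[role == "N"]))
}

#' Construct a growth environment
#'
#' A growth environment is a primary carbon source, a primary nitrogen
#' source, optional impurity sets, and the uptake bounds applied to their
#' exchange reactions. Uptake bounds are lower bounds on exchange flux, so
#' they are negative; the defaults are the conventional -20 mmol/gDW/hr for
#' primary sources, 1/100th of that (-0.2) for impurities, and -18.5 for
#' oxygen.
#'
#' @param carbon_source,nitrogen_source substrate ids.
#' @param impurities_C,impurities_N character vectors of impurity substrate
#'   ids; must not contain the primary sources.
#' @param primary_uptake,impurity_uptake,oxygen_uptake exchange lower bounds
#'   (mmol/gDW/hr, negative = uptake).
#' @param nitrogen_uptake optional distinct bound for the nitrogen primary;
#'   defaults to `primary_uptake`. Excess-carbon conditions set
#'   `primary_uptake = -1000` with `nitrogen_uptake = -20`, and vice versa.
#' @return An object of class `growth_environment`.
#' @export
growth_environment <- function(carbon_source, nitrogen_source,
                               impurities_C = character(0),
                               impurities_N = character(0),
                               primary_uptake = -20,
                               impurity_uptake = -0.2,
                               oxygen_uptake = -18.5,
                               nitrogen_uptake = NULL) {
  if (is.null(nitrogen_uptake)) nitrogen_uptake <- primary_uptake
  primaries <- c(carbon_source, nitrogen_source)
  clash <- intersect(c(impurities_C, impurities_N), primaries)
  if (length(clash))
    stop("impurity set overlaps the primary sources: ",
         paste(clash, collapse = ", "))
  stopifnot(primary_uptake <= 0, impurity_uptake <= 0, nitrogen_uptake <= 0)
  structure(list(carbon_source = carbon_source,
                 nitrogen_source = nitrogen_source,
                 impurities_C = as.character(impurities_C),
                 impurities_N = as.character(impurities_N),
                 primary_uptake = primary_uptake,
                 nitrogen_uptake = nitrogen_uptake,
                 impurity_uptake = impurity_uptake,
                 oxygen_uptake = oxygen_uptake),
            class = "growth_environment")
}

#' Sample random impurities from a substrate pool
#'
#' Draws `k_C` carbon and `k_N` nitrogen substrates uniformly without
#' replacement, excluding the primary sources (a duplicate would silently
#' raise the primary's uptake bound). Uses the current R random stream;
#' seed it with [set.seed()] for reproducibility.
#'
#' @param pool a [substrate_pool()].
#' @param k_C,k_N number of carbon / nitrogen impurities.
#' @param exclude substrate ids never to sample (normally the primaries).
#' @return List with `impurities_C` and `impurities_N`.
#' @export
sample_impurities <- function(pool, k_C, k_N, exclude = character(0)) {
  avail_C <- setdiff(names(pool$carbon), exclude)
  avail_N <- setdiff(names(pool$nitrogen), exclude)
  if (k_C > length(avail_C))
    stop("carbon pool exhausted: ", k_C, " impurities requested from ",
         length(avail_C), " available substrates")
  if (k_N > length(avail_N))
    stop("nitrogen pool exhausted: ", k_N, " impurities requested from ",
         length(avail_N), " available substrates")
  list(impurities_C = if (k_C > 0) sample(avail_C, k_C) else character(0),
       impurities_N = if (k_N > 0) sample(avail_N, k_N) else character(0))
}

#' Apply a growth environment to a model's exchange bounds
#'
#' Returns a new model in which every carbon/nitrogen-source exchange in the
#' pool is first closed (lower bound 0), then the primary sources are opened
#' at `primary_uptake`, the impurities at `impurity_uptake`, and the oxygen
#' exchange (`EX_o2_e`, when the model has one) at `oxygen_uptake`. Only
#' lower bounds of pool/oxygen exchange reactions change: the stoichiometry,
#' upper bounds, objective, and every other bound (ions, maintenance flux)
#' are untouched.
#'
#' @param model a [metabolic_model()].
#' @param env a [growth_environment()].
#' @param pool the [substrate_pool()] naming all candidate C/N exchanges.
#' @param oxygen_exchange id of the oxygen exchange reaction, if any.
#' @return A new [metabolic_model()] with updated bounds.
#' @export
apply_environment <- function(model, env, pool, oxygen_exchange = "EX_o2_e") {
  all_sub <- c(pool$carbon, pool$nitrogen)
  resolve <- function(ids) {
    ex <- all_sub[ids]
    missing <- ids[is.na(ex) | !(ex %in% model$reaction_ids)]
    if (length(missing))
      stop("substrate id(s) not resolvable to an exchange reaction: ",
           paste(missing, collapse = ", "))
    ex
  }
  lb <- model$lower_bounds
  pool_ex <- intersect(all_sub, model$reaction_ids)
  if (!length(pool_ex)) stop("no pool substrate resolves to a model reaction")
  lb[pool_ex] <- 0
  lb[resolve(env$carbon_source)] <- env$primary_uptake
  lb[resolve(env$nitrogen_source)] <- env$nitrogen_uptake
  imp <- c(env$impurities_C, env$impurities_N)
  if (length(imp)) lb[resolve(imp)] <- env$impurity_uptake
  if (!is.null(oxygen_exchange) && oxygen_exchange %in% model$reaction_ids)
    lb[oxygen_exchange] <- env$oxygen_uptake
  out <- model
  out$lower_bounds <- lb
  out
}

#' All pairwise carbon x nitrogen growth conditions
#'
#' Full Cartesian product in stable order: carbon varies fastest within each
#' nitrogen source.
#'
#' @param carbon_list,nitrogen_list substrate id vectors.
#' @return A data.frame with columns `carbon` and `nitrogen`.
#' @export
condition_grid <- function(carbon_list, nitrogen_list) {
  if (!length(carbon_list) || !length(nitrogen_list))
    stop("substrate lists must be non-empty")
  expand.grid(carbon = as.character(carbon_list),
              nitrogen = as.character(nitrogen_list),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}
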