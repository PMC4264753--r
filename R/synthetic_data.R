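#' Specification of a synthetic toy metabolic network
#'
#' The toy generator emulates the structural features that make inverse
#' environment prediction possible in a genome-scale model: every substrate
#' enters through its own exchange and transport reaction, runs down a
#' private linear pathway, and converges on a shared core (a TCA-like hub)
#' that produces the carbon and nitrogen precursors consumed by biomass.
#' The `overlap` knob controls how much of each pathway is shared between
#' substrates of the same role: at 0 the pathways are fully private (every
#' substrate leaves a unique internal flux signature), at 1 all substrates
#' of a role share one pathway (their internal signatures are identical and
#' the substrate identity is irrecoverable from internal fluxes).
#'
#' @param n_carbon,n_nitrogen number of carbon / nitrogen substrates (>= 2).
#' @param pathway_length reactions per substrate entry pathway (>= 1).
#' @param overlap fraction of each pathway shared within a role, in [0, 1].
#'   The shared tail has `round(overlap * pathway_length)` reactions; at
#'   full overlap the transport step feeds the shared pathway directly
#'   (as phosphotransferase-style transporters do).
#' @param core_size number of shared core reactions downstream of the
#'   precursors (split between the carbon and nitrogen branches).
#' @param seed integer recorded in the spec for provenance of derived
#'   fixtures.
#' @return An object of class `toy_network_spec`.
#' @export
toy_network_spec <- function(n_carbon = 3, n_nitrogen = 3, pathway_length = 3,
                             overlap = 0, core_size = 4, seed = 1L) {
  if (n_carbon < 2 || n_nitrogen < 2)
    stop("need at least 2 substrates per role")
  if (pathway_length < 1) stop("pathway_length must be >= 1")
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  if (core_size < 0) stop("core_size must be >= 0")
  structure(list(n_carbon = as.integer(n_carbon),
                 n_nitrogen = as.integer(n_nitrogen),
                 pathway_length = as.integer(pathway_length),
                 overlap = overlap, core_size = as.integer(core_size),
                 seed = as.integer(seed)),
            class = "toy_network_spec")
}

toy_substrates <- function(spec) {
  list(carbon = paste0("cs", seq_len(spec$n_carbon)),
       nitrogen = paste0("ns", seq_len(spec$n_nitrogen)))
}

toy_shared_len <- function(spec) as.integer(round(spec$overlap * spec$pathway_length))

#' Generate a toy metabolic model and its substrate pool
#'
#' Builds the network described by a [toy_network_spec()]: per substrate one
#' exchange reaction (`EX_<id>_e`), one transport reaction (subsystem
#' `"Transport"`), and a private internal pathway feeding the role's shared
#' tail; a core chain converts the carbon and nitrogen precursors into the
#' final biomass inputs, and the biomass reaction consumes one unit of
#' each. All stoichiometric coefficients are +/-1 so optimal fluxes have
#' closed forms ([toy_ground_truth()]).
#'
#' @param spec a [toy_network_spec()].
#' @return List with `model` (a [metabolic_model()]), `pool` (a
#'   [substrate_pool()]) and `manifest` (structural counts: exchange,
#'   transport, internal reactions, and the private pathway reactions of
#'   every substrate).
#' @export
generate_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_network_spec"))
  s <- toy_shared_len(spec)
  h <- spec$pathway_length - s
  subs <- toy_substrates(spec)

  mets <- character(0)
  rxn <- list()  # each: list(id, coef = named numeric, lb, ub, obj, sub)
  add_rxn <- function(id, coef, lb = 0, ub = 1000, obj = 0, sub = "") {
    rxn[[length(rxn) + 1L]] <<- list(id = id, coef = coef, lb = lb, ub = ub,
                                     obj = obj, sub = sub)
    mets <<- union(mets, names(coef))
  }

  pathway_reactions <- list()
  for (role in c("carbon", "nitrogen")) {
    r <- substr(role, 1, 1)
    prec <- paste0(r, "prec_c")
    # shared tail: hub -> ... -> precursor
    hub <- if (s > 0) paste0(r, "_sh0_c") else prec
    if (s > 0) {
      chain <- c(paste0(r, "_sh", seq_len(s) - 1L, "_c"), prec)
      for (t in seq_len(s))
        add_rxn(paste0("SH_", r, t),
                stats::setNames(c(-1, 1), c(chain[t], chain[t + 1L])))
    }
    for (id in subs[[role]]) {
      ex_met <- paste0(id, "_e")
      add_rxn(paste0("EX_", ex_met), stats::setNames(-1, ex_met))
      entry <- if (h > 0) paste0(id, "_c") else hub
      add_rxn(paste0("T_", id), stats::setNames(c(-1, 1), c(ex_met, entry)),
              sub = "Transport")
      priv <- character(0)
      if (h > 0) {
        chain <- c(paste0(id, "_c"),
                   if (h > 1) paste0(id, "_m", seq_len(h - 1L), "_c"), hub)
        for (t in seq_len(h)) {
          rid <- paste0("P_", id, "_", t)
          add_rxn(rid, stats::setNames(c(-1, 1), c(chain[t], chain[t + 1L])))
          priv <- c(priv, rid)
        }
      }
      pathway_reactions[[id]] <- priv
    }
  }

  nc <- as.integer(ceiling(spec$core_size / 2))
  nn <- spec$core_size - nc
  core_chain <- function(r, len) {
    prec <- paste0(r, "prec_c"); fin <- paste0(r, "fin_c")
    if (len == 0) return(prec)
    chain <- c(prec, if (len > 1) paste0(r, "_k", seq_len(len - 1L), "_c"), fin)
    for (t in seq_len(len))
      add_rxn(paste0("CORE_", r, t),
              stats::setNames(c(-1, 1), c(chain[t], chain[t + 1L])))
    fin
  }
  cfin <- core_chain("c", nc)
  nfin <- core_chain("n", nn)
  add_rxn("BIOMASS", stats::setNames(c(-1, -1), c(cfin, nfin)), obj = 1,
          sub = "Biomass")

  ids <- vapply(rxn, `[[`, "", "id")
  S <- Matrix::sparseMatrix(
    i = unlist(lapply(rxn, function(r) match(names(r$coef), mets))),
    j = rep(seq_along(rxn), vapply(rxn, function(r) length(r$coef), 0L)),
    x = unlist(lapply(rxn, `[[`, "coef")),
    dims = c(length(mets), length(rxn)), dimnames = list(mets, ids))
  model <- metabolic_model(
    id = sprintf("toy_%dC_%dN_L%d_ov%g", spec$n_carbon, spec$n_nitrogen,
                 spec$pathway_length, spec$overlap),
    S = S,
    lower_bounds = vapply(rxn, `[[`, 0, "lb"),
    upper_bounds = vapply(rxn, `[[`, 0, "ub"),
    objective_coeffs = vapply(rxn, `[[`, 0, "obj"),
    subsystem = vapply(rxn, `[[`, "", "sub"))

  pool <- substrate_pool(
    carbon = stats::setNames(paste0("EX_", subs$carbon, "_e"), subs$carbon),
    nitrogen = stats::setNames(paste0("EX_", subs$nitrogen, "_e"), subs$nitrogen))
  manifest <- list(n_exchange = spec$n_carbon + spec$n_nitrogen,
                   n_auxiliary_exchange = 0L,
                   n_transport = spec$n_carbon + spec$n_nitrogen,
                   n_internal = length(ids) - 2L * (spec$n_carbon + spec$n_nitrogen) - 1L,
                   pathway_reactions = pathway_reactions,
                   spec = spec)
  list(model = model, pool = pool, manifest = manifest)
}

#' Closed-form optimal fluxes for a zero-overlap toy network
#'
#' With fully private pathways and unit stoichiometry, the optimum of the
#' toy FBA problem is available in closed form: biomass equals the smaller
#' of the total carbon and total nitrogen supply, every pathway on the
#' limiting side saturates its uptake bound, and the non-limiting side
#' carries `biomass` total flux (uniquely attributed only when a single
#' substrate of that role is open; with several, the split is degenerate
#' and those entries are `NA`).
#'
#' @param spec a [toy_network_spec()] with `overlap = 0`.
#' @param env a [growth_environment()] over the toy substrate pool.
#' @return List with `biomass` and `fluxes` (named over all toy reactions;
#'   `NA` marks degenerate alternate-optima entries).
#' @export
toy_ground_truth <- function(spec, env) {
  stopifnot(inherits(spec, "toy_network_spec"))
  if (toy_shared_len(spec) > 0)
    stop("closed-form ground truth is only available at overlap 0")
  subs <- toy_substrates(spec)
  toy <- generate_toy_model(spec)
  uptake <- function(role) {
    prim <- env[[paste0(role, "_source")]]
    imp <- env[[paste0("impurities_", toupper(substr(role, 1, 1)))]]
    u <- stats::setNames(rep(0, length(subs[[role]])), subs[[role]])
    u[prim] <- if (role == "carbon") abs(env$primary_uptake)
               else abs(env$nitrogen_uptake)
    u[imp] <- abs(env$impurity_uptake)
    u
  }
  uC <- uptake("carbon"); uN <- uptake("nitrogen")
  biomass <- min(sum(uC), sum(uN))

  fluxes <- stats::setNames(rep(0, length(toy$model$reaction_ids)),
                            toy$model$reaction_ids)
  side_fluxes <- function(u, limiting, role) {
    active <- names(u)[u > 0]
    for (id in active) {
      f <- if (limiting) u[[id]]
           else if (length(active) == 1L) biomass
           else NA_real_
      fluxes[paste0("EX_", id, "_e")] <<- -f
      fluxes[paste0("T_", id)] <<- f
      fluxes[toy$manifest$pathway_reactions[[id]]] <<- f
    }
  }
  side_fluxes(uC, sum(uC) <= sum(uN), "carbon")
  side_fluxes(uN, sum(uN) <= sum(uC), "nitrogen")
  core <- grep("^CORE_", toy$model$reaction_ids, value = TRUE)
  fluxes[core] <- biomass
  fluxes["BIOMASS"] <- biomass
  list(biomass = biomass, fluxes = fluxes)
}
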