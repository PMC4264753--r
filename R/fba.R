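#' Solve a flux balance problem
#'
#' Maximizes the biomass objective `c'v` over the steady-state flux cone
#' `{v : S v = 0, lb <= v <= ub}`. The solution is a vertex of the feasible
#' polytope; for a fixed model the solver is deterministic, so all
#' replicate-to-replicate variation in a simulation comes from the sampled
#' growth environments, never from the solver. Alternate optima exist in
#' genome-scale models; [minimize_total_flux()] provides the parsimonious
#' canonicalization.
#'
#' @param model a [metabolic_model()].
#' @return An object of class `flux_solution`: list with `fluxes` (named
#'   numeric, mmol/gDW/hr), `biomass` (objective value) and `status`
#'   (`"optimal"` or `"infeasible"`).
#' @export
solve_fba <- function(model) {
  n_mets <- length(model$metabolite_ids)
  res <- solve_lp(obj = model$objective_coeffs,
                  A = model$S, rhs = rep(0, n_mets),
                  lb = model$lower_bounds, ub = model$upper_bounds,
                  maximize = TRUE)
  if (res$status != "optimal")
    return(structure(list(fluxes = NULL, biomass = NA_real_,
                          status = res$status), class = "flux_solution"))
  structure(list(fluxes = res$x, biomass = res$value, status = "optimal"),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status)
  if (x$status == "optimal") cat("  biomass:", format(x$biomass))
  cat("\n")
  invisible(x)
}

#' Minimize total absolute flux at fixed optimal biomass
#'
#' Secondary (parsimonious) optimization: minimizes `sum(|v_i|)` subject to
#' mass balance, the model bounds, and the biomass flux pinned to
#' `biomass_star`. Implemented as an LP over split positive/negative flux
#' components `v = p - q`, `p, q >= 0`. Futile cycles that do not
#' contribute to biomass are driven to zero.
#'
#' @param model a [metabolic_model()].
#' @param biomass_star the biomass value to hold fixed, normally the
#'   objective value of a prior [solve_fba()] call.
#' @param biomass_tol absolute tolerance of the two-sided biomass equality.
#' @return A `flux_solution` whose `biomass` is `biomass_star` within
#'   `biomass_tol` and whose `fluxes` minimize the L1 norm.
#' @export
minimize_total_flux <- function(model, biomass_star, biomass_tol = 1e-9) {
  stopifnot(is.numeric(biomass_star), length(biomass_star) == 1L)
  n <- length(model$reaction_ids)
  lb <- model$lower_bounds
  ub <- model$upper_bounds

  # split v = p - q: p in [0, max(ub,0)], q in [0, max(-lb,0)]
  p_ub <- pmax(ub, 0)
  q_ub <- pmax(-lb, 0)
  # preserve strictly positive lower bounds (forced fluxes, e.g. maintenance)
  p_lb <- pmax(lb, 0)
  q_lb <- pmax(-ub, 0)

  S <- as.matrix(model$S)
  A_bal <- cbind(S, -S)
  c_obj <- model$objective_coeffs
  A_bio <- c(c_obj, -c_obj)
  A <- rbind(A_bal, A_bio)
  rhs <- c(rep(0, nrow(S)), biomass_star)

  obj <- rep(1, 2L * n)
  res <- solve_lp(obj = obj, A = A, rhs = rhs,
                  lb = c(p_lb, q_lb), ub = c(p_ub, q_ub),
                  maximize = FALSE)
  if (res$status != "optimal") {
    chk <- solve_fba(model)
    if (chk$status != "optimal")
      stop("flux minimization infeasible: the model itself has no feasible flux state")
    if (chk$biomass + biomass_tol < biomass_star)
      stop("flux minimization infeasible: biomass_star = ", biomass_star,
           " exceeds the attainable optimum ", chk$biomass)
    stop("flux minimization failed within tolerance at biomass_star = ",
         biomass_star)
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- model$reaction_ids
  structure(list(fluxes = v, biomass = sum(model$objective_coeffs * v),
                 status = "optimal", total_flux = sum(abs(v))),
            class = "flux_solution")
}

#' Viability threshold from reference biomass values
#'
#' The cutoff below which a simulated observation is considered non-growing:
#' `mean(b) - k_sd * sd(b)` over a reference set of biomass values (sample
#' standard deviation).
#'
#' @param biomass_values numeric vector of biomass values (at least 2).
#' @param k_sd number of standard deviations below the mean (default 3).
#' @return The threshold value.
#' @export
compute_viability_threshold <- function(biomass_values, k_sd = 3) {
  biomass_values <- as.numeric(biomass_values)
  if (length(biomass_values) < 2L)
    stop("need at least 2 biomass values to compute a viability threshold")
  mean(biomass_values) - k_sd * stats::sd(biomass_values)
}
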