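# Small models built in code, plus an exhaustive FBA oracle.

# linear chain: EX_A (uptake) -> transport -> internal conversion -> biomass
make_chain_model <- function(uptake = -10) {
  S <- matrix(0, 3, 4,
              dimnames = list(c("A_e", "A_c", "B_c"),
                              c("EX_A_e", "T_A", "R1", "BIOMASS")))
  S["A_e", "EX_A_e"] <- -1
  S["A_e", "T_A"] <- -1; S["A_c", "T_A"] <- 1
  S["A_c", "R1"] <- -1;  S["B_c", "R1"] <- 1
  S["B_c", "BIOMASS"] <- -1
  metabolic_model("chain", S,
                  lower_bounds = c(uptake, 0, 0, 0),
                  upper_bounds = rep(1000, 4),
                  objective_coeffs = c(0, 0, 0, 1),
                  subsystem = c("", "Transport", "", ""))
}

# two redundant routes A_c -> B_c: direct (1 reaction) and via X_c (2)
make_parallel_paths_model <- function(uptake = -10) {
  mets <- c("A_e", "A_c", "X_c", "B_c")
  rxns <- c("EX_A_e", "T_A", "SHORT", "LONG1", "LONG2", "BIOMASS")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["A_e", "EX_A_e"] <- -1
  S["A_e", "T_A"] <- -1; S["A_c", "T_A"] <- 1
  S["A_c", "SHORT"] <- -1; S["B_c", "SHORT"] <- 1
  S["A_c", "LONG1"] <- -1; S["X_c", "LONG1"] <- 1
  S["X_c", "LONG2"] <- -1; S["B_c", "LONG2"] <- 1
  S["B_c", "BIOMASS"] <- -1
  metabolic_model("parallel", S,
                  lower_bounds = c(uptake, rep(0, 5)),
                  upper_bounds = rep(1000, 6),
                  objective_coeffs = c(rep(0, 5), 1),
                  subsystem = c("", "Transport", rep("", 4)))
}

# chain plus a 2-reaction futile cycle B_c <-> C_c that cannot aid biomass
make_cycle_model <- function(uptake = -10) {
  mets <- c("A_e", "A_c", "B_c", "C_c")
  rxns <- c("EX_A_e", "T_A", "R1", "CYC_F", "CYC_R", "BIOMASS")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["A_e", "EX_A_e"] <- -1
  S["A_e", "T_A"] <- -1; S["A_c", "T_A"] <- 1
  S["A_c", "R1"] <- -1; S["B_c", "R1"] <- 1
  S["B_c", "CYC_F"] <- -1; S["C_c", "CYC_F"] <- 1
  S["C_c", "CYC_R"] <- -1; S["B_c", "CYC_R"] <- 1
  S["B_c", "BIOMASS"] <- -1
  metabolic_model("cycle", S,
                  lower_bounds = c(uptake, rep(0, 5)),
                  upper_bounds = rep(1000, 6),
                  objective_coeffs = c(rep(0, 5), 1),
                  subsystem = c("", "Transport", rep("", 4)))
}

# Exhaustive oracle: enumerate candidate vertices of {S v = 0, lb<=v<=ub}
# by pinning every size-d subset of variables (d = n - rank(S)) to a bound
# and solving the equality system for the rest; returns the best feasible
# objective. Only for models with <= 10 reactions.
enumerate_fba_oracle <- function(model, tol = 1e-8) {
  S <- as.matrix(model$S)
  n <- ncol(S)
  stopifnot(n <= 10)
  lb <- model$lower_bounds; ub <- model$upper_bounds
  obj <- model$objective_coeffs
  d <- n - qr(S)$rank
  check <- function(v) {
    max(abs(S %*% v)) < tol &&
      all(v >= lb - tol) && all(v <= ub + tol)
  }
  best <- -Inf; best_v <- NULL
  consider <- function(v) {
    if (check(v)) {
      val <- sum(obj * v)
      if (val > best) { best <<- val; best_v <<- v }
    }
  }
  if (d == 0) {
    v <- tryCatch(as.numeric(qr.solve(S, rep(0, nrow(S)))),
                  error = function(e) NULL)
    if (!is.null(v)) consider(v)
  } else {
    for (fix in utils::combn(n, d, simplify = FALSE)) {
      free <- setdiff(seq_len(n), fix)
      for (pat in seq_len(2^d) - 1L) {
        at_ub <- bitwAnd(pat, 2^(seq_len(d) - 1L)) > 0
        vfix <- ifelse(at_ub, ub[fix], lb[fix])
        rhs <- -S[, fix, drop = FALSE] %*% vfix
        vfree <- tryCatch(qr.solve(S[, free, drop = FALSE], rhs),
                          error = function(e) NULL)
        if (is.null(vfree)) next
        v <- numeric(n); v[fix] <- vfix; v[free] <- vfree
        consider(v)
      }
    }
  }
  list(value = best, fluxes = best_v)
}

quiet_glmnet <- function(expr) suppressWarnings(expr)

# deterministic synthetic feature set: one informative column, noise rest
make_separable <- function(n_per = 12, p_noise = 4, seed = 5) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n_per))
  f <- ifelse(y == "A", 1, -1) + stats::rnorm(2 * n_per, 0, 0.05)
  x <- cbind(f = f,
             matrix(stats::rnorm(2 * n_per * p_noise), ncol = p_noise,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(x = x, y = y)
}

# toy flux dataset with a single carbon-discriminating reaction plus a
# nitrogen-discriminating one, a shared column and pure noise
make_discriminating_dataset <- function(n_per = 30, seed = 4) {
  set.seed(seed)
  carbon <- rep(c("cs1", "cs2"), each = n_per)
  nitrogen <- rep(c("ns1", "ns2"), n_per)
  disc <- ifelse(carbon == "cs1", 10, 0) + stats::rnorm(2 * n_per, 0, 0.1)
  ndisc <- ifelse(nitrogen == "ns1", 8, 0) + stats::rnorm(2 * n_per, 0, 0.1)
  shared <- 10 + stats::rnorm(2 * n_per, 0, 0.1)
  noise <- stats::rnorm(2 * n_per)
  X <- cbind(disc = disc, ndisc = ndisc, shared = shared, noise = noise)
  structure(list(X = X, carbon = carbon, nitrogen = nitrogen,
                 biomass = rep(1, 2 * n_per),
                 replicate = seq_len(2 * n_per),
                 impurities = vector("list", 2 * n_per),
                 internal_ids = colnames(X)),
            class = "flux_dataset")
}

toy_3x3 <- function(overlap = 0, seed = 1L)
  generate_toy_model(toy_network_spec(3, 3, pathway_length = 3,
                                      overlap = overlap, core_size = 4,
                                      seed = seed))
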