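test_that("BiGG JSON round-trip preserves stoichiometry, bounds and classes", {
  toy <- toy_3x3()
  path <- withr::local_tempfile(fileext = ".json")
  write_bigg_json(toy$model, path)
  back <- read_bigg_json(path)
  expect_identical(back$reaction_ids, toy$model$reaction_ids)
  expect_identical(back$metabolite_ids, toy$model$metabolite_ids)
  expect_equal(as.matrix(back$S), as.matrix(toy$model$S))
  expect_equal(back$lower_bounds, toy$model$lower_bounds)
  expect_equal(back$upper_bounds, toy$model$upper_bounds)
  expect_equal(back$objective_coeffs, toy$model$objective_coeffs)
  expect_equal(back$subsystem, toy$model$subsystem)
  p1 <- classify_reactions(toy$model); p2 <- classify_reactions(back)
  expect_identical(p1, p2)
})

test_that("reading the same file twice yields structurally identical models", {
  path <- withr::local_tempfile(fileext = ".json")
  write_bigg_json(toy_3x3()$model, path)
  expect_identical(read_bigg_json(path), read_bigg_json(path))
})

test_that("corrupt or objective-free model files fail loudly, never partially", {
  toy <- toy_3x3()
  path <- withr::local_tempfile(fileext = ".json")
  write_bigg_json(toy$model, path)
  txt <- readLines(path)
  writeLines(txt[seq_len(length(txt) %/% 2)], path)
  expect_error(read_bigg_json(path), "failed to parse")

  no_obj <- toy$model
  no_obj$objective_coeffs[] <- 0
  path2 <- withr::local_tempfile(fileext = ".json")
  write_bigg_json(no_obj, path2)
  expect_error(read_bigg_json(path2), "objective")

  expect_error(load_model(file.path(tempdir(), "does_not_exist.json")),
               "not found")
})

test_that("SBML/FBC reader recovers species, bounds, objective and subsystems", {
  path <- system.file("extdata", "toy_chain_fbc.xml", package = "fluxinvert")
  m <- read_sbml_model(path)
  expect_equal(length(m$metabolite_ids), 3L)
  expect_equal(length(m$reaction_ids), 4L)
  expect_equal(unname(m$lower_bounds["EX_A_e"]), -10)
  expect_equal(unname(m$subsystem["T_A"]), "Transport")
  expect_equal(names(which(m$objective_coeffs != 0)), "BIOMASS")
  # equivalent to the chain model built in code
  ref <- make_chain_model(uptake = -10)
  expect_equal(as.matrix(m$S)[ref$metabolite_ids, ref$reaction_ids],
               as.matrix(ref$S))
  sol <- solve_fba(m)
  expect_equal(sol$biomass, 10)
})

test_that("reaction partition is exhaustive, disjoint, and order-independent", {
  toy <- toy_3x3()
  p <- classify_reactions(toy$model)
  all_ids <- c(p$exchange_ids, p$transport_ids, p$internal_ids, p$biomass_id)
  expect_setequal(all_ids, toy$model$reaction_ids)
  expect_equal(length(all_ids), length(toy$model$reaction_ids))  # disjoint
  expect_equal(length(p$exchange_ids), toy$manifest$n_exchange)
  expect_equal(length(p$transport_ids), toy$manifest$n_transport)
  expect_equal(length(p$internal_ids), toy$manifest$n_internal)

  # permuting reaction order changes nothing but listing order
  perm <- rev(seq_along(toy$model$reaction_ids))
  shuffled <- metabolic_model("perm", toy$model$S[, perm],
                              toy$model$lower_bounds[perm],
                              toy$model$upper_bounds[perm],
                              toy$model$objective_coeffs[perm],
                              toy$model$subsystem[perm])
  p2 <- classify_reactions(shuffled)
  expect_setequal(p2$exchange_ids, p$exchange_ids)
  expect_setequal(p2$transport_ids, p$transport_ids)
  expect_setequal(p2$internal_ids, p$internal_ids)
  expect_identical(p2$biomass_id, p$biomass_id)
  # idempotence
  expect_identical(classify_reactions(toy$model), p)
})

test_that("classification rules: boundary reactions, cross-compartment movers, biomass", {
  m <- make_chain_model()
  # single-metabolite boundary reaction named like a BiGG glucose exchange
  colnames(m$S)[1] <- "EX_glc__D_e"
  m2 <- metabolic_model("m2", m$S,
                        stats::setNames(m$lower_bounds, colnames(m$S)),
                        stats::setNames(m$upper_bounds, colnames(m$S)),
                        stats::setNames(m$objective_coeffs, colnames(m$S)),
                        stats::setNames(m$subsystem, colnames(m$S)))
  p <- classify_reactions(m2)
  expect_true("EX_glc__D_e" %in% p$exchange_ids)
  # T_A moves species A between _e and _c: transport even without annotation
  m3 <- m2; m3$subsystem[] <- ""
  p3 <- classify_reactions(m3)
  expect_true("T_A" %in% p3$transport_ids)

  # with neither annotation nor compartment movement: internal = rest
  S <- matrix(0, 2, 3, dimnames = list(c("A_c", "B_c"),
                                       c("EX_A_c", "R1", "BIOMASS")))
  S["A_c", "EX_A_c"] <- -1
  S["A_c", "R1"] <- -1; S["B_c", "R1"] <- 1
  S["B_c", "BIOMASS"] <- -1
  m4 <- metabolic_model("m4", S, c(-5, 0, 0), rep(1000, 3), c(0, 0, 1))
  p4 <- classify_reactions(m4)
  expect_length(p4$transport_ids, 0)
  expect_equal(length(p4$internal_ids),
               length(m4$reaction_ids) - length(p4$exchange_ids) - 1L)
})

test_that("ambiguous or absent biomass objectives are refused", {
  m <- make_chain_model()
  both <- m; both$objective_coeffs[c("R1", "BIOMASS")] <- 1
  expect_error(classify_reactions(both), "several")
  none <- m; none$objective_coeffs[] <- 0
  expect_error(classify_reactions(none), "no objective")
})
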