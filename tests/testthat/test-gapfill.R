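test_that("an already-feasible target yields a single zero-addition solution", {
  m <- chain_model(uptake = 10)
  db <- reaction_db(data.frame(id = "U1", equation = "q[c] -> r[c]"))
  rep <- gapfill(m, db, epsilon = 1)
  expect_length(rep$solutions, 1)
  expect_length(rep$solutions[[1]]$added, 0)
  expect_gte(rep$solutions[[1]]$objective, 1)
})

test_that("gap filling recovers a planted gap hidden among 50 decoys", {
  gen <- GEN
  pg <- plant_gaps(gen, k = 1, seed = 31)
  gapped <- apply_medium(pg$model, gen$media$rich)
  expect_lt(solve_fba(gapped)$objective_value, 1e-9)

  db <- generate_universal_db(gen$model, pg$removed, n_decoys = 50, seed = 13)
  expect_equal(nrow(db$rxns), 51)
  rep <- gapfill(gapped, db, n_iter = 2, epsilon = 1)
  expect_gte(length(rep$solutions), 1)
  expect_setequal(rep$solutions[[1]]$added, paste0("U_", pg$removed))
  expect_gte(rep$solutions[[1]]$objective, 1)

  # applying the solution restores growth
  fixed <- apply_gapfill(gapped, db, rep$solutions[[1]]$added)
  expect_gte(solve_fba(fixed)$objective_value, 1)
})

test_that("solutions are minimal (exhaustive subset check) and iterations are distinct with non-decreasing size", {
  # two parallel two-step routes to the target, both broken at one step;
  # a tiny db with the two genuine fixes and decoys
  m <- model_from_equations(list(
    list(id = "EX_a", eq = "a[e] <=>", lb = -10),
    list(id = "T_a", eq = "a[e] -> a[c]"),
    list(id = "r1b", eq = "p[c] -> z[c]"),
    list(id = "r2b", eq = "q[c] -> z[c]"),
    list(id = "target", eq = "z[c] ->")
  ), objective = "target")
  db <- reaction_db(data.frame(
    id = c("fix1", "fix2", "dec1", "dec2", "dec3", "dec4"),
    equation = c("a[c] -> p[c]", "a[c] -> q[c]",
                 "d1[c] -> d2[c]", "d3[c] <=> d4[c]",
                 "d5[c] -> d6[c]", "d7[c] -> d8[c]")))
  rep <- gapfill(m, db, target = "target", n_iter = 4, epsilon = 1)
  expect_gte(length(rep$solutions), 2)
  sizes <- vapply(rep$solutions, function(s) length(s$added), integer(1))
  expect_true(all(diff(sizes) >= 0))
  sets <- lapply(rep$solutions, function(s) sort(s$added))
  expect_equal(length(unique(sets)), length(sets))
  expect_setequal(unlist(sets[1:2]), c("fix1", "fix2"))

  # exhaustive minimality oracle: no strictly smaller subset restores flux
  best_size <- sizes[1]
  ids <- db$rxns$id
  for (k in 0:(best_size - 1)) {
    combos <- if (k == 0) list(character(0)) else
      utils::combn(ids, k, simplify = FALSE)
    for (set in combos) {
      m2 <- apply_gapfill(m, db, set)
      sol <- solve_fba(m2, "target")
      expect_lt(ifelse(sol$status == "optimal", sol$objective_value, 0), 1)
    }
  }
})

test_that("reaction-level cuts force disjoint alternate solutions", {
  m <- model_from_equations(list(
    list(id = "EX_a", eq = "a[e] <=>", lb = -10),
    list(id = "T_a", eq = "a[e] -> a[c]"),
    list(id = "target", eq = "z[c] ->")
  ), objective = "target")
  db <- reaction_db(data.frame(
    id = c("route1", "route2"),
    equation = c("a[c] -> z[c]", "a[c] <=> z[c]")))
  rep <- gapfill(m, db, target = "target", n_iter = 3, cut = "reaction")
  expect_length(rep$solutions, 2)
  expect_length(intersect(rep$solutions[[1]]$added, rep$solutions[[2]]$added), 0)
})

test_that("the transport/exchange augmentation opens uptake routes for isolated metabolites", {
  m <- model_from_equations(list(
    list(id = "conv", eq = "w[c] -> z[c]"),
    list(id = "target", eq = "z[c] ->")
  ), objective = "target")
  # nothing produces w: infeasible without an uptake route
  expect_lt(solve_fba(m, "target")$objective_value, 1e-9)
  db0 <- reaction_db(data.frame(id = character(0), equation = character(0)))
  aug <- build_transport_exchange_db(m, db0)
  # one exchange + one transport per base id
  expect_setequal(aug$rxns$id, c("GFX_EX_w", "GFX_T_w", "GFX_EX_z", "GFX_T_z"))
  rep <- gapfill(m, aug, target = "target", n_iter = 1, epsilon = 1)
  expect_length(rep$solutions, 1)
  # minimal repair is an exchange plus a transport (w-side or z-side route)
  expect_length(rep$solutions[[1]]$added, 2)
  fixed <- apply_gapfill(m, aug, rep$solutions[[1]]$added)
  expect_gte(solve_fba(fixed, "target")$objective_value, 1)

  # metabolites already covered are not duplicated
  m2 <- chain_model()
  aug2 <- build_transport_exchange_db(m2, db0)
  expect_false(any(grepl("GFX_EX_a$|GFX_T_a$", aug2$rxns$id)))
  expect_true("GFX_EX_b" %in% aug2$rxns$id)
})

test_that("solution filtering rejects reversed irreversible reactions and missing evidence", {
  m <- model_from_equations(list(
    list(id = "irrev", eq = "p[c] -> q[c]"),
    list(id = "target", eq = "q[c] ->")
  ), objective = "target")
  db <- reaction_db(data.frame(
    id = c("rev_of_irrev", "no_evid", "clean"),
    equation = c("q[c] -> p[c]", "a[c] -> q[c]", "b[c] -> q[c]"),
    evidence = c(TRUE, FALSE, TRUE)))
  rep <- structure(list(solutions = list(
    list(added = "rev_of_irrev", objective = 1, iteration = 1L),
    list(added = "no_evid", objective = 1, iteration = 2L),
    list(added = "clean", objective = 1, iteration = 3L),
    list(added = character(0), objective = 1, iteration = 4L)
  ), frequency = table(character(0)), n_iter = 4L, epsilon = 1,
  cut = "solution", verdicts = NULL), class = "gapfill_report")
  out <- filter_solutions(rep, m, db)
  expect_identical(out$verdicts$accepted, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(out$verdicts$reason[1], "irreversible_reverse")
  expect_identical(out$verdicts$reason[2], "no_organism_evidence")

  # generator-planted verdicts on a real report: planted reactions carry
  # evidence, so the recovery solution is accepted
  pg <- plant_gaps(GEN, k = 1, seed = 8)
  dbg <- generate_universal_db(GEN$model, pg$removed, n_decoys = 10, seed = 8)
  repg <- gapfill(apply_medium(pg$model, GEN$media$rich), dbg, n_iter = 1)
  outg <- filter_solutions(repg, pg$model, dbg)
  expect_true(outg$verdicts$accepted[1])
})

test_that("universal databases round-trip through TSV", {
  pg <- plant_gaps(GEN, k = 2, seed = 21)
  db <- generate_universal_db(GEN$model, pg$removed, n_decoys = 15, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_db_tsv(db, path)
  db2 <- read_reaction_db_tsv(path)
  expect_identical(db2$rxns, db$rxns)
  expect_identical(db2$stoich, db$stoich)
})
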