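test_that("FBA finds chain optimum and respects internal bottlenecks", {
  expect_equal(solve_fba(chain_model(uptake = 10))$objective_value, 10,
               tolerance = 1e-9)
  expect_equal(solve_fba(chain_model(uptake = 10, internal_ub = 5))$objective_value,
               5, tolerance = 1e-9)
})

test_that("FBA reports infeasibility and unboundedness distinctly", {
  m <- model_from_equations(list(
    list(id = "force", eq = "a[c] -> b[c]", lb = 1, ub = 2),
    list(id = "dead", eq = "b[c] -> c[c]", lb = 0, ub = 0.1)
  ))
  # b must be consumed at >= 1 but dead caps at 0.1; also c accumulates
  expect_identical(solve_fba(m, "force")$status, "infeasible")

  loop <- model_from_equations(list(
    list(id = "f", eq = "a[c] -> b[c]", lb = -Inf, ub = Inf),
    list(id = "g", eq = "b[c] -> a[c]", lb = -Inf, ub = Inf)
  ))
  expect_identical(solve_fba(loop, "f")$status, "unbounded")
})

test_that("FBA optimum equals the vertex-enumeration oracle on random small networks", {
  set.seed(202)
  for (rep in 1:12) {
    net <- random_small_network(n_mets = sample(3:4, 1), n_rxns = sample(6:8, 1))
    jobj <- sample(nrow(net$model$rxns), 1)
    target <- net$model$rxns$id[jobj]
    sol <- solve_fba(net$model, target)
    expect_identical(sol$status, "optimal")
    obj <- numeric(nrow(net$model$rxns))
    obj[jobj] <- 1
    oracle <- lp_vertex_oracle(obj, net$S, net$lb, net$ub)
    expect_equal(sol$objective_value, oracle, tolerance = 1e-6)
  }
})

test_that("relaxing a bound never decreases the FBA optimum", {
  set.seed(303)
  for (rep in 1:5) {
    net <- random_small_network()
    target <- net$model$rxns$id[1]
    base <- solve_fba(net$model, target)$objective_value
    relaxed <- set_bounds(net$model, net$model$rxns$id[3], lb = -20, ub = 20)
    expect_gte(solve_fba(relaxed, target)$objective_value, base - 1e-8)
  }
})

test_that("FVA collapses a forced chain and splits parallel equivalent paths", {
  m <- chain_model(uptake = 10)
  fva <- run_fva(m)
  # every chain reaction is forced to carry the optimum (the exchange runs
  # at -10: uptake is negative flux)
  forced <- ifelse(fva$reaction == "EX_a", -10, 10)
  expect_equal(fva$min, forced, tolerance = 1e-6)
  expect_equal(fva$max, forced, tolerance = 1e-6)

  par <- model_from_equations(list(
    list(id = "EX_a", eq = "a[e] <=>", lb = -10),
    list(id = "T_a", eq = "a[e] -> a[c]"),
    list(id = "p1", eq = "a[c] -> b[c]"),
    list(id = "p2", eq = "a[c] -> b[c]"),
    list(id = "biomass", eq = "b[c] ->")
  ), objective = "biomass")
  fva2 <- run_fva(par)
  for (p in c("p1", "p2")) {
    expect_equal(fva2$min[fva2$reaction == p], 0, tolerance = 1e-6)
    expect_equal(fva2$max[fva2$reaction == p], 10, tolerance = 1e-6)
  }
})

test_that("FVA ranges at fraction 1 bracket the FBA fluxes", {
  m <- apply_medium(GEN$model, GEN$media$rich)
  fba <- solve_fba(m)
  fva <- run_fva(m)
  v <- fba$fluxes[fva$reaction]
  expect_true(all(fva$min <= v + 1e-6))
  expect_true(all(v <= fva$max + 1e-6))
  expect_true(all(fva$min <= fva$max + 1e-9))
  expect_error(run_fva(m, fraction = 2))
})

test_that("active-reaction counts exclude exactly the planted blocked reactions", {
  m <- apply_medium(GEN$model, GEN$media$rich)
  fva <- run_fva(m)
  expect_equal(count_active(fva), nrow(fva) - length(GEN$truth$blocked))
  blocked <- fva[fva$reaction %in% GEN$truth$blocked, ]
  expect_true(all(abs(blocked$min) < 1e-9 & abs(blocked$max) < 1e-9))
})

test_that("gene deletion disables exactly the reactions whose rules fail", {
  m <- model_from_equations(list(
    list(id = "EX_a", eq = "a[e] <=>", lb = -10),
    list(id = "T_a", eq = "a[e] -> a[c]"),
    list(id = "iso", eq = "a[c] -> b[c]", gpr = "g1 or g2"),
    list(id = "solo", eq = "b[c] -> c[c]", gpr = "g1"),
    list(id = "biomass", eq = "c[c] ->")
  ), objective = "biomass")
  ko <- delete_gene(m, "g1")
  expect_identical(attr(ko, "disabled"), "solo")  # isozyme g2 rescues "iso"
  expect_equal(ko$rxns$ub[ko$rxns$id == "solo"], 0)
  expect_equal(m$rxns$ub[m$rxns$id == "solo"], 1000)  # input untouched
  expect_error(delete_gene(m, "nope"), "unknown gene")

  # disabled sets across all genes of the synthetic model match the
  # independent rule evaluator
  gm <- GEN$model
  for (g in gm$genes$id[seq(1, nrow(gm$genes), by = 7)]) {
    ko <- delete_gene(gm, g)
    present <- setdiff(gm$genes$id, g)
    want <- gm$rxns$id[!vapply(gm$rxns$gpr, eval_rule_r, logical(1),
                               present = present)]
    expect_setequal(attr(ko, "disabled"), want)
  }
})

test_that("knockout optimum never exceeds wild type", {
  m <- apply_medium(GEN$model, GEN$media$rich)
  wt <- solve_fba(m)$objective_value
  for (g in GEN$model$genes$id[seq(1, nrow(GEN$model$genes), by = 11)]) {
    expect_lte(solve_fba(delete_gene(m, g))$objective_value, wt + 1e-6)
  }
})

test_that("essentiality screen matches brute-force re-solving and ground truth", {
  spec <- synthetic_spec(n_precursors = 3, chain_length = 3, n_parallel = 1,
                         n_blocked = 1, seed = 5)
  gen <- generate_source_model(spec)
  scr <- essentiality_screen(gen$model, medium = gen$media$rich)
  oracle <- essentiality_oracle(apply_medium(gen$model, gen$media$rich))
  expect_identical(setNames(scr$essential, scr$gene), oracle)
  expect_setequal(scr$gene[scr$essential], gen$truth$essential_genes)
  # a gene disabling nothing is never essential
  expect_true(all(!scr$essential[scr$n_disabled == 0]))
})
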