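one_test_battery <- function(target, medium = "med", threshold = 1e-6) {
  validation_battery(data.frame(id = "t1", target = target, medium = medium,
                                threshold = threshold))
}

test_that("a trivially producible target passes and removing its producer fails it", {
  m <- chain_model(uptake = 10)
  media <- list(med = medium_condition(data.frame(exchange = "EX_a", lb = -10,
                                                  ub = 1000)))
  out <- run_battery(m, one_test_battery("b[c]"), media)
  expect_identical(out$status, "pass")
  expect_equal(pass_fraction(out), 1)

  broken <- subset_reactions(m, setdiff(m$rxns$id, "conv"),
                             prune_mets = FALSE, prune_genes = FALSE)
  out2 <- run_battery(broken, one_test_battery("b[c]"), media)
  expect_identical(out2$status, "fail")
  expect_equal(pass_fraction(out2), 0)
})

test_that("an unresolvable target metabolite marks the test error, not fail", {
  m <- chain_model()
  media <- list(med = medium_condition("EX_a"))
  out <- run_battery(m, one_test_battery("ghost[c]"), media)
  expect_identical(out$status, "error")
  expect_true(is.na(pass_fraction(out)))
  expect_error(run_battery(m, one_test_battery("b[c]", medium = "nope"), media),
               "unknown media")
})

test_that("compartment-specific tests are skipped on collapsed models only", {
  bat <- validation_battery(data.frame(
    id = c("generic", "specific"),
    target = c("b[c]", "b[c]"),
    medium = "med",
    compartment_specific = c(FALSE, TRUE)))
  m <- chain_model()
  media <- list(med = medium_condition(data.frame(exchange = "EX_a", lb = -10,
                                                  ub = 1000)))
  full <- run_battery(m, bat, media, collapsed = FALSE)
  expect_identical(full$status, c("pass", "pass"))
  coll <- run_battery(m, bat, media, collapsed = TRUE)
  expect_identical(coll$status, c("pass", "skipped"))
  expect_equal(pass_fraction(coll), 1)  # fraction over applicable tests
})

test_that("the wild type passes its battery and gapped models fail exactly the dependent tests", {
  bat <- generate_test_battery(GEN)
  out <- run_battery(GEN$model, bat$battery, bat$media)
  expect_equal(pass_fraction(out), 1)

  pg <- plant_gaps(GEN, k = 3, seed = 19)
  out2 <- run_battery(pg$model, bat$battery, bat$media)
  failing <- out2$id[out2$status == "fail"]
  predicted <- names(Filter(function(d) any(pg$removed %in% d), bat$deps))
  expect_setequal(failing, predicted)

  # battery results are order-independent
  perm <- sample(nrow(bat$battery))
  shuffled <- validation_battery(as.data.frame(bat$battery)[perm, ])
  out3 <- run_battery(pg$model, shuffled, bat$media)
  expect_identical(out3$status[match(out2$id, out3$id)], out2$status)
})

test_that("diagnosis finds the single-reaction fixes and curation restores a perfect battery", {
  bat <- generate_test_battery(GEN)
  pg <- plant_gaps(GEN, k = 2, seed = 23)
  out <- run_battery(pg$model, bat$battery, bat$media)
  expect_lt(pass_fraction(out), 1)

  cand <- diagnose_failures(pg$model, out, GEN$model, pg$removed,
                            bat$battery, bat$media)
  expect_true(all(!is.na(cand$reactions)))
  expect_setequal(unique(unlist(strsplit(cand$reactions, ","))), pg$removed)
  expect_true(all(cand$n == 1))

  cured <- apply_curation(pg$model, cand, GEN$model)
  out2 <- run_battery(cured, bat$battery, bat$media)
  expect_equal(pass_fraction(out2), 1)
  # restoring again is an id collision
  expect_error(apply_curation(cured, cand, GEN$model), "already in model")
  # empty action list is the identity
  expect_identical(apply_curation(pg$model, character(0), GEN$model), pg$model)
})

test_that("a failure with no fix in the pool is flagged unresolvable", {
  bat <- generate_test_battery(GEN)
  pg <- plant_gaps(GEN, k = 1, seed = 29)
  out <- run_battery(pg$model, bat$battery, bat$media)
  # pool that cannot contain the fix
  cand <- diagnose_failures(pg$model, out, GEN$model,
                            removed = GEN$truth$blocked,
                            bat$battery, bat$media)
  expect_true(all(is.na(cand$reactions)))
  cur <- curate_model(pg$model, bat$battery, bat$media, GEN$model,
                      removed = GEN$truth$blocked)
  expect_gt(length(cur$unresolved), 0)
  expect_lt(pass_fraction(cur$outcome), 1)
})

test_that("the curation loop is monotone and terminates at 100% with a complete pool", {
  bat <- generate_test_battery(GEN)
  pg <- plant_gaps(GEN, k = 3, seed = 37)
  cur <- curate_model(pg$model, bat$battery, bat$media, GEN$model, pg$removed)
  expect_true(all(diff(cur$history) >= 0))
  expect_equal(pass_fraction(cur$outcome), 1)
  expect_setequal(cur$restored, pg$removed)
  expect_length(cur$unresolved, 0)
})

test_that("pair search repairs a test broken in two places", {
  m <- model_from_equations(list(
    list(id = "EX_a", eq = "a[e] <=>", lb = -10),
    list(id = "T_a", eq = "a[e] -> a[c]"),
    list(id = "s1", eq = "a[c] -> b[c]"),
    list(id = "s2", eq = "b[c] -> c[c]"),
    list(id = "DM_c", eq = "c[c] ->")
  ), objective = NA_character_)
  broken <- subset_reactions(m, setdiff(m$rxns$id, c("s1", "s2")),
                             prune_mets = FALSE)
  media <- list(med = medium_condition(data.frame(exchange = "EX_a", lb = -10,
                                                  ub = 1000)))
  bat <- one_test_battery("c[c]")
  out <- run_battery(broken, bat, media)
  expect_identical(out$status, "fail")
  cand <- diagnose_failures(broken, out, m, c("s1", "s2"), bat, media,
                            max_depth = 2)
  expect_identical(cand$n, 2L)
  expect_setequal(strsplit(cand$reactions, ",")[[1]], c("s1", "s2"))
})

test_that("batteries round-trip through TSV", {
  bat <- generate_test_battery(GEN)$battery
  path <- withr::local_tempfile(fileext = ".tsv")
  write_battery_tsv(bat, path)
  bat2 <- read_battery_tsv(path)
  expect_equal(as.data.frame(bat2), as.data.frame(bat))
})
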