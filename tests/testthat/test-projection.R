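identity_table <- function(model) {
  homology_table(data.frame(source_gene = model$genes$id,
                            target_gene = paste0("t_", model$genes$id)))
}

test_that("identity homology retains the full reaction set; empty table leaves only non-gene reactions", {
  src <- GEN$model
  pa <- project_model(src, identity_table(src), "A")
  expect_setequal(pa$model$rxns$id, src$rxns$id)
  expect_equal(pa$report$gene_ratio, 1)
  expect_equal(pa$report$reaction_ratio, 1)

  empty <- homology_table(data.frame(source_gene = character(0),
                                     target_gene = character(0)))
  pe <- project_model(src, empty, "A")
  expect_setequal(pe$model$rxns$id, src$rxns$id[!nzchar(src$rxns$gpr)])
  expect_equal(pe$report$gene_ratio, 0)
})

test_that("isozyme coverage rescues reactions; sole-gene losses remove them", {
  src <- model_from_equations(list(
    list(id = "EX_a", eq = "a[e] <=>", lb = -10),
    list(id = "T_a", eq = "a[e] -> a[c]"),
    list(id = "iso", eq = "a[c] -> b[c]", gpr = "gA or gB"),
    list(id = "solo", eq = "b[c] -> c[c]", gpr = "gA"),
    list(id = "biomass", eq = "c[c] ->")
  ), objective = "biomass")
  # gA unmapped, gB mapped
  h <- homology_table(data.frame(source_gene = "gB", target_gene = "tB"))
  p <- project_model(src, h, "A")
  expect_true("iso" %in% p$model$rxns$id)
  expect_false("solo" %in% p$model$rxns$id)
  expect_identical(p$model$rxns$gpr[p$model$rxns$id == "iso"], "tB")
})

test_that("approach B drops non-gene metabolic reactions that A keeps", {
  src <- model_from_equations(list(
    list(id = "EX_a", eq = "a[e] <=>", lb = -10),
    list(id = "T_a", eq = "a[e] -> a[c]"),
    list(id = "spont", eq = "a[c] -> b[c]"),          # non-gene, metabolic
    list(id = "enz", eq = "b[c] -> c[c]", gpr = "g1"),
    list(id = "DM_c", eq = "c[c] ->"),
    list(id = "biomass", eq = "c[c] ->", gpr = "")
  ), objective = "biomass")
  h <- homology_table(data.frame(source_gene = "g1", target_gene = "t1"))
  a <- project_model(src, h, "A")$model
  b <- project_model(src, h, "B")$model
  expect_true("spont" %in% a$rxns$id)
  expect_false("spont" %in% b$rxns$id)
  # transporters, demand, exchange, biomass all survive B
  expect_true(all(c("EX_a", "T_a", "DM_c", "biomass") %in% b$rxns$id))
})

test_that("model B is nested in model A and projection is monotone in the table", {
  src <- GEN$model
  set.seed(404)
  for (rate in c(0.3, 0.7, 0.9)) {
    h <- generate_homology_table(src, rate, seed = 100 + round(100 * rate))
    a <- project_model(src, h, "A")
    b <- project_model(src, h, "B")
    expect_true(all(b$model$rxns$id %in% a$model$rxns$id))
    expect_equal(a$report$gene_ratio,
                 length(Filter(length, h$map)) / nrow(src$genes))
    expect_equal(a$report$reaction_ratio,
                 length(a$report$retained) / nrow(src$rxns))

    # adding homologs never removes a retained reaction
    extra_genes <- setdiff(src$genes$id, names(h$map))
    if (length(extra_genes)) {
      add <- data.frame(source_gene = extra_genes[1],
                        target_gene = paste0("t_", extra_genes[1]))
      h2 <- homology_table(rbind(h$pairs[c("source_gene", "target_gene")], add))
      a2 <- project_model(src, h2, "A")
      expect_true(all(a$report$retained %in% a2$report$retained))
    }
  }
})

test_that("projected synthetic retention matches the generator's predicted sets", {
  src <- GEN$model
  h <- generate_homology_table(src, 0.6, seed = 77)
  mapped <- names(Filter(length, h$map))
  for (app in c("A", "B")) {
    p <- project_model(src, h, app)
    want <- vapply(seq_len(nrow(src$rxns)), function(j) {
      if (nzchar(src$rxns$gpr[j])) {
        eval_rule_r(src$rxns$gpr[j], mapped)
      } else if (app == "A") TRUE else {
        GEN$truth$kinds[[src$rxns$id[j]]] %in%
          c("transport", "demand", "sink", "exchange", "biomass")
      }
    }, logical(1))
    expect_setequal(p$model$rxns$id, src$rxns$id[want])
  }
})

test_that("homology tables round-trip through TSV", {
  h <- generate_homology_table(GEN$model, 0.5, seed = 9, species = "mouse")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_homology_tsv(h, path)
  h2 <- read_homology_tsv(path)
  expect_identical(h2$species, "mouse")
  expect_identical(h2$map, h$map)
})

test_that("compartment merge removes pure transports, keeps exchanges, merges duplicates by or-ing GPRs", {
  src <- model_from_equations(list(
    list(id = "EX_a", eq = "a[e] <=>", lb = -10),
    list(id = "T_a", eq = "a[e] -> a[c]"),
    list(id = "shuttle", eq = "a[c] -> a[m]"),        # vanishes on merge
    list(id = "conv_c", eq = "a[c] -> b[c]", gpr = "g1"),
    list(id = "conv_m", eq = "a[m] -> b[m]", gpr = "g2"),  # duplicate after merge
    list(id = "biomass", eq = "b[c] ->")
  ), objective = "biomass")
  flat <- decompartmentalize(src)
  expect_false("shuttle" %in% flat$rxns$id)
  expect_true("EX_a" %in% flat$rxns$id)
  expect_true("T_a" %in% flat$rxns$id)
  expect_true(is_collapsed(flat))
  expect_setequal(unique(flat$mets$comp), c("c", "e"))
  # conv_c and conv_m merged into one reaction enabled by either gene
  merged <- intersect(flat$rxns$id, c("conv_c", "conv_m"))
  expect_length(merged, 1)
  rule <- flat$rxns$gpr[flat$rxns$id == merged]
  expect_true(evaluate_gpr(rule, "g1"))
  expect_true(evaluate_gpr(rule, "g2"))
  expect_false(evaluate_gpr(rule, character(0)))

  # growth capability is preserved for the synthetic model, and the merged
  # model never has more dead ends
  flat2 <- decompartmentalize(GEN$model)
  expect_lte(length(count_dead_ends(flat2)), length(count_dead_ends(GEN$model)))
  z <- solve_fba(apply_medium(flat2, GEN$media$rich))$objective_value
  expect_gt(z, 0)
})

test_that("full merge without extracellular retention is available but loses exchanges", {
  flat <- decompartmentalize(GEN$model, keep_extracellular = FALSE)
  expect_identical(unique(flat$mets$comp), "c")
  expect_false(any(classify_reactions(flat) == "exchange"))
})
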