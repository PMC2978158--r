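test_that("the even-probability chi-square matches the published table cells", {
  # exactly printed cells reproduce at 5-decimal precision
  exact <- list(c(85, 133, 0.00115), c(35, 55, 0.03501), c(60, 37, 0.01953),
                c(13, 32, 0.00462), c(48, 48, 1.00000), c(12, 34, 0.00118),
                c(64, 103, 0.00255), c(6, 19, 0.00932), c(368, 437, 0.01502),
                c(7, 18, 0.02781))
  for (cell in exact) {
    expect_equal(round(chi_square_even(cell[1], cell[2])$p_value, 5), cell[3])
  }
  # remaining printed cells were rounded to 4 significant figures
  four_sig <- list(c(53, 45, 0.41900), c(19, 27, 0.23820), c(165, 189, 0.20210),
                   c(80, 91, 0.40020), c(11, 14, 0.54850), c(397, 422, 0.38240),
                   c(122, 98, 0.10560), c(40, 55, 0.12380), c(166, 182, 0.39110),
                   c(196, 162, 0.07234), c(87, 90, 0.82160), c(12, 13, 0.84150),
                   c(393, 443, 0.08376))
  for (cell in four_sig) {
    expect_equal(chi_square_even(cell[1], cell[2])$p_value, cell[3],
                 tolerance = 5e-4)
  }
})

test_that("the chi-square agrees with R's goodness-of-fit test without continuity correction", {
  set.seed(11)
  for (rep in 1:20) {
    a <- sample(0:200, 1); b <- sample(1:200, 1)
    got <- chi_square_even(a, b)
    ref <- suppressWarnings(stats::chisq.test(c(a, b), p = c(0.5, 0.5),
                                              correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("the chi-square is symmetric, monotone in imbalance, and handles edge counts", {
  for (k in c(0, 1, 7, 48)) {
    res <- chi_square_even(k, k)
    expect_equal(res$statistic, 0)
    expect_equal(res$p_value, 1)
  }
  expect_equal(chi_square_even(10, 30), chi_square_even(30, 10))
  total <- 100
  ps <- vapply(0:49, function(a) chi_square_even(a, total - a)$p_value, numeric(1))
  expect_true(all(diff(ps) > 0))  # p rises as counts approach balance
  expect_error(chi_square_even(-1, 3), "non-negative")
})

test_that("FVA comparison classifies capacity changes and demands matching universes", {
  fva <- function(ids, min, max) {
    structure(data.frame(reaction = ids, min = min, max = max,
                         subsystem = "S"), class = c("fva_result", "data.frame"))
  }
  wt <- fva(c("r1", "r2", "r3", "r4"), c(0, 0, 0, 0), c(10, 5, 2, 1e-12))
  ko <- fva(c("r1", "r2", "r3", "r4"), c(0, 0, 0, 0), c(0, 5 + 1e-9, 7, 2e-12))
  ch <- compare_fva(wt, ko)
  expect_identical(setNames(ch$status, ch$reaction),
                   c(r1 = "decreased", r2 = "unchanged", r3 = "increased",
                     r4 = "unchanged"))  # sub-tolerance jitter is no change
  expect_error(compare_fva(wt, fva("r1", 0, 1)), "different reaction sets")

  # statuses equal a direct recomputation on a synthetic knockout
  m <- apply_medium(GEN$model, GEN$media$rich)
  g <- GEN$truth$essential_genes[1]
  ko_m <- delete_gene(m, g)
  # knockout of an essential gene: keep the objective free so FVA stays feasible
  wt_fva <- run_fva(m, fraction = 0)
  ko_fva <- run_fva(ko_m, fraction = 0)
  ch2 <- compare_fva(wt_fva, ko_fva)
  d <- ko_fva$max[match(wt_fva$reaction, ko_fva$reaction)] - wt_fva$max
  tol <- pmax(1e-9, 1e-6 * pmax(abs(wt_fva$max), abs(ko_fva$max)))
  want <- ifelse(d < -tol, "decreased", ifelse(d > tol, "increased", "unchanged"))
  expect_identical(ch2$status, want)
})

test_that("subsystem shift tests count down/up per subsystem with Bonferroni-style significance", {
  ch <- data.frame(
    reaction = sprintf("r%d", 1:8),
    status = c("decreased", "increased", "increased", "unchanged",
               "decreased", "decreased", "increased", "increased"),
    subsystem = c("A", "A", "A", "A", "B", "B", "unassigned", ""))
  sh <- subsystem_shift_test(ch, alpha = 0.05, k = 10)
  expect_identical(sh$subsystem, c("A", "B"))
  expect_identical(sh$n_down, c(1L, 2L))
  expect_identical(sh$n_up, c(2L, 0L))
  expect_false(any(sh$significant))

  # all-unchanged input: every subsystem p = 1
  ch0 <- transform(ch, status = "unchanged")
  sh0 <- subsystem_shift_test(ch0)
  expect_true(all(sh0$p_value == 1))
  expect_false(any(sh0$significant))
})

test_that("published shift counts reproduce the reported significant metabolism subsections", {
  want <- c(PGM1 = 6L, FUT9 = 2L, SORD = 0L, DHCR7 = 7L)
  for (gname in names(want)) {
    sh <- published_knockout_shift(gname, alpha = 0.05, k = 10)
    expect_equal(count_significant_subsections(sh), unname(want[[gname]]))
  }
  # the LPL glycan shift is overwhelming
  lpl <- published_shift_counts()
  gly <- lpl[lpl$knockout == "LPL" & lpl$subsystem == "Glycan Metabolism", ]
  expect_lt(chi_square_even(gly$n_down, gly$n_up)$p_value, 1e-16)
})

test_that("knocking out a gene that disables nothing is a phenotypic fixed point", {
  spec <- synthetic_spec(n_precursors = 3, chain_length = 3, n_parallel = 0,
                         frac_isozyme = 0.5, n_blocked = 0, seed = 12)
  gen <- generate_source_model(spec)
  covered <- Filter(function(g)
    length(attr(delete_gene(gen$model, g), "disabled")) == 0,
    gen$model$genes$id)
  expect_gt(length(covered), 0)  # isozyme partners exist at this fraction
  kp <- knockout_phenotype(gen$model, gen$media$rich, covered[[1]])
  expect_true(all(kp$changes$status == "unchanged"))
  expect_false(any(kp$shift$significant))
})

test_that("knocking out a planted bottleneck shifts its own subsystem significantly", {
  spec <- synthetic_spec(n_precursors = 4, chain_length = 8, n_parallel = 0,
                         frac_isozyme = 0, frac_complex = 0, frac_nongene = 0,
                         n_blocked = 0, seed = 33)
  gen <- generate_source_model(spec)
  g <- gen$truth$chain_steps[[1]][[2]]$genes[1]
  own_sub <- unname(gen$truth$subsystems[gen$truth$chain_steps[[1]][[2]]$id])
  # essential-path knockout: compare capacity with the objective left free
  kp <- knockout_phenotype(gen$model, gen$media$rich, g, fraction = 0)
  dec <- kp$changes$reaction[kp$changes$status == "decreased"]
  # the broken chain, its transporters and biomass lose capacity; other
  # chains keep theirs through the precursor demand outlets
  expect_gt(length(dec), 0)
  expect_true(all(gen$truth$subsystems[dec] %in% c(own_sub, "Transporters", "Biomass")))
  own <- kp$shift[kp$shift$subsystem == own_sub, ]
  expect_gt(own$n_down, 0)
  expect_true(own$significant)
})

test_that("activity-profile trees pair the similar models and resolve identical profiles", {
  u <- sprintf("r%d", 1:20)
  base <- setNames(rep(TRUE, 20), u)
  p1 <- base
  p2 <- base; p2[19:20] <- FALSE             # 90% shared with p1
  p3 <- base; p3[3:20] <- FALSE              # 10% shared
  tree <- fva_distance_tree(list(mouse = p1, rat = p2, far = p3))
  sisters <- ape::extract.clade(tree, ape::getMRCA(tree, c("mouse", "rat")))$tip.label
  expect_setequal(sisters, c("mouse", "rat"))

  same <- fva_distance_tree(list(a = p1, b = p1, c = p1))
  expect_equal(sum(same$edge.length), 0)
  expect_error(fva_distance_tree(list(a = p1, b = p2)), "at least 3")

  # nested activity sets: closed-form Jaccard distances are reproduced by
  # average-linkage heights
  q1 <- setNames(c(rep(TRUE, 10), rep(FALSE, 10)), u)
  q2 <- setNames(c(rep(TRUE, 15), rep(FALSE, 5)), u)
  q3 <- setNames(rep(TRUE, 20), u)
  tr <- fva_distance_tree(list(s10 = q1, s15 = q2, s20 = q3))
  # closed-form Jaccard: d(s15,s20) = 0.25 is the closest pair, then s10
  # joins at the average of d(s10,s15) = 1/3 and d(s10,s20) = 1/2
  expect_setequal(ape::extract.clade(tr, ape::getMRCA(tr, c("s15", "s20")))$tip.label,
                  c("s15", "s20"))
  cop <- ape::cophenetic.phylo(tr)
  expect_equal(cop["s15", "s20"], 0.25, tolerance = 1e-9)
  expect_equal(cop["s10", "s15"], mean(c(1/3, 1/2)), tolerance = 1e-9)
})
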