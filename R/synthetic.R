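#' Specification for a synthetic source reconstruction
#'
#' Parameters of the seeded generator that emulates a curated,
#' compartmentalized source reconstruction: linear biosynthesis chains
#' feed a biomass reaction through exchange and transport steps, GPR rules
#' mix single genes, isozyme pairs (`or`) and complexes (`and`), a
#' fraction of reactions carries no gene association, and deliberately
#' blocked reaction pairs plant dead-end metabolites. Every structural
#' fact is recorded as ground truth so downstream operations can be tested
#' against construction rather than estimation.
#'
#' @param n_precursors number of biomass precursors (= biosynthesis
#'   chains).
#' @param chain_length conversion steps per chain.
#' @param compartments intracellular compartment codes used by the chains
#'   (the extracellular space `e` is always present).
#' @param frac_isozyme,frac_complex,frac_nongene fractions of conversion
#'   reactions with isozyme (`or`) rules, complex (`and`) rules, and no
#'   gene association; the remainder get single-gene rules.
#' @param n_parallel number of chains duplicated by a parallel isozyme
#'   path, making their genes non-essential.
#' @param n_blocked number of planted blocked reactions (each contributes
#'   two dead-end metabolites).
#' @param byproduct_every every this-many conversion steps also emit a
#'   byproduct with its own demand reaction (0 disables byproducts).
#' @param seed integer seed; the same spec yields byte-identical models.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_precursors = 10, chain_length = 8,
                           compartments = c("c", "m", "x"),
                           frac_isozyme = 0.2, frac_complex = 0.2,
                           frac_nongene = 0.15, n_parallel = 2,
                           n_blocked = 3, byproduct_every = 2, seed = 1) {
  stopifnot(n_precursors >= 1, chain_length >= 1,
            frac_isozyme >= 0, frac_complex >= 0, frac_nongene >= 0,
            frac_isozyme + frac_complex + frac_nongene <= 1,
            n_parallel >= 0, n_parallel <= n_precursors, n_blocked >= 0,
            "c" %in% compartments, !"e" %in% compartments)
  structure(list(n_precursors = n_precursors, chain_length = chain_length,
                 compartments = compartments, frac_isozyme = frac_isozyme,
                 frac_complex = frac_complex, frac_nongene = frac_nongene,
                 n_parallel = n_parallel, n_blocked = n_blocked,
                 byproduct_every = byproduct_every, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# run code under a fixed RNG seed without disturbing the global stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic source reconstruction with ground truth
#'
#' Builds the model described by a [synthetic_spec()]: per chain an
#' exchange reaction, an uptake transport, `chain_length` conversions
#' routed through random intracellular compartments (ending in the
#' cytosol), optional byproducts with demand outlets, and a single biomass
#' reaction consuming one unit of every precursor. Blocked reaction pairs
#' are appended as flux-dead appendices. The generated wild type always
#' grows on the recorded rich medium and its planted blocked reactions
#' have FVA range (0, 0).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `model` (a [metabolic_model()]), `truth` (ground
#'   truth: `essential_genes`, `chains`, `precursors`, `kinds`,
#'   `subsystems`, `blocked`, `dead_ends`, `duplicated_chains`,
#'   `battery_deps`), `media` (named list: `rich` plus one minimal medium
#'   per chain) and `spec`.
#' @export
generate_source_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, build_synthetic(spec))
}

major_subsystems <- function() {
  c("Amino Acid Metabolism", "Carbohydrate Metabolism",
    "Cofactor and Vitamin Metabolism", "Energy Metabolism",
    "Glycan Metabolism", "Lipid Metabolism", "Nucleotide Metabolism",
    "Other Amino Acids Metabolism", "Secondary Metabolites Metabolism")
}

build_synthetic <- function(spec) {
  P <- spec$n_precursors
  L <- spec$chain_length
  labels <- major_subsystems()

  rxn_rows <- list()
  stoich <- list()
  kinds <- character(0)
  gene_counter <- 0L
  new_gene <- function() {
    gene_counter <<- gene_counter + 1L
    sprintf("g%03d", gene_counter)
  }
  push <- function(id, stoi, lb, ub, gpr, subsystem, kind) {
    rxn_rows[[length(rxn_rows) + 1L]] <<- data.frame(
      id = id, lb = lb, ub = ub, gpr = gpr, subsystem = subsystem,
      stringsAsFactors = FALSE)
    stoich[[length(stoich) + 1L]] <<- stoi
    kinds[id] <<- kind
  }

  chains <- vector("list", P)
  chain_gprs <- vector("list", P)  # per step: list(rule, genes, category)
  precursors <- character(P)
  essential <- character(0)
  duplicated_chains <- if (spec$n_parallel > 0) seq_len(spec$n_parallel) else integer(0)

  draw_category <- function() {
    u <- stats::runif(1)
    if (u < spec$frac_isozyme) "isozyme"
    else if (u < spec$frac_isozyme + spec$frac_complex) "complex"
    else if (u < spec$frac_isozyme + spec$frac_complex + spec$frac_nongene) "nongene"
    else "single"
  }
  make_rule <- function(category) {
    switch(category,
           nongene = list(rule = "", genes = character(0)),
           single = { g <- new_gene(); list(rule = g, genes = g) },
           isozyme = { g <- c(new_gene(), new_gene())
                       list(rule = paste(g, collapse = " or "), genes = g) },
           complex = { g <- c(new_gene(), new_gene())
                       list(rule = paste(g, collapse = " and "), genes = g) })
  }

  for (i in seq_len(P)) {
    lab <- labels[((i - 1L) %% length(labels)) + 1L]
    ext <- sprintf("x%d_0[e]", i)
    cyt0 <- sprintf("x%d_0[c]", i)
    ex_id <- sprintf("EX_x%d_0", i)
    tr_id <- sprintf("T_x%d_0", i)
    push(ex_id, stats::setNames(-1, ext), -1000, 1000, "", "Transporters", "exchange")
    push(tr_id, stats::setNames(c(-1, 1), c(ext, cyt0)), -1000, 1000, "",
         "Transporters", "transport")
    chain_ids <- c(ex_id, tr_id)

    comps <- c("c", sample(spec$compartments, L - 1, replace = TRUE), "c")[seq_len(L + 1)]
    comps[L + 1] <- "c"  # precursor ends in the cytosol
    dup <- i %in% duplicated_chains
    steps <- vector("list", L)
    for (j in seq_len(L)) {
      from <- sprintf("x%d_%d[%s]", i, j - 1L, comps[j])
      to <- sprintf("x%d_%d[%s]", i, j, comps[j + 1L])
      s <- stats::setNames(c(-1, 1), c(from, to))
      cat_j <- draw_category()
      rule <- make_rule(cat_j)
      rid <- sprintf("R_%d_%d", i, j)
      if (spec$byproduct_every > 0 && j %% spec$byproduct_every == 0L) {
        bp <- sprintf("b%d_%d[%s]", i, j, comps[j + 1L])
        s <- c(s, stats::setNames(1, bp))
        push(sprintf("DM_b%d_%d", i, j), stats::setNames(-1, bp), 0, 1000, "",
             lab, "demand")
        chain_ids <- c(chain_ids, sprintf("DM_b%d_%d", i, j))
      }
      push(rid, s, 0, 1000, rule$rule, lab, "metabolic")
      chain_ids <- c(chain_ids, rid)
      steps[[j]] <- list(id = rid, category = cat_j, genes = rule$genes)
      if (dup) {
        alt <- make_rule(if (cat_j == "nongene") "nongene" else "single")
        aid <- sprintf("R_%d_%d_alt", i, j)
        push(aid, s, 0, 1000, alt$rule, lab, "metabolic")
        chain_ids <- c(chain_ids, aid)
      } else if (cat_j %in% c("single", "complex")) {
        essential <- c(essential, rule$genes)
      }
    }
    precursors[i] <- sprintf("x%d_%d[c]", i, L)
    # demand outlet per precursor: chains stay individually exercisable
    # (and FVA-active) even when biomass cannot run
    push(sprintf("DM_x%d_%d", i, L), stats::setNames(-1, precursors[i]),
         0, 1000, "", lab, "demand")
    chain_ids <- c(chain_ids, sprintf("DM_x%d_%d", i, L))
    chains[[i]] <- chain_ids
    chain_gprs[[i]] <- steps
  }

  # half-unit coefficients leave each chain headroom beyond biomass demand,
  # so precursor demands remain active at the fixed optimum
  biomass_stoich <- stats::setNames(rep(-0.5, P), precursors)
  push("biomass", biomass_stoich, 0, 1000, "", "Biomass", "biomass")

  blocked <- character(0)
  dead_ends <- character(0)
  for (b in seq_len(spec$n_blocked)) {
    lab <- labels[((b - 1L) %% length(labels)) + 1L]
    m1 <- sprintf("u%d_a[c]", b); m2 <- sprintf("u%d_b[c]", b)
    bid <- sprintf("BLK_%d", b)
    push(bid, stats::setNames(c(-1, 1), c(m1, m2)), 0, 1000, "", lab, "metabolic")
    blocked <- c(blocked, bid)
    dead_ends <- c(dead_ends, m1, m2)
  }

  rxns <- do.call(rbind, rxn_rows)
  met_ids <- sort(unique(unlist(lapply(stoich, names))))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(stoich)) {
    s <- stoich[[k]]
    ii <- c(ii, match(names(s), met_ids)); jj <- c(jj, rep(k, length(s)))
    xx <- c(xx, unname(s))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), nrow(rxns)))
  genes <- sprintf("g%03d", seq_len(gene_counter))
  model <- metabolic_model(
    genes = data.frame(id = genes, stringsAsFactors = FALSE),
    mets = data.frame(id = met_ids, stringsAsFactors = FALSE),
    rxns = rxns, S = S, objective = "biomass", id = "synthetic_source")

  ex_ids <- rxns$id[kinds[rxns$id] == "exchange"]
  media <- list(rich = medium_condition(ex_ids, id = "rich"))
  for (i in seq_len(P)) {
    media[[sprintf("min_%d", i)]] <- medium_condition(
      sprintf("EX_x%d_0", i), id = sprintf("min_%d", i), uptake = -10)
  }

  truth <- list(
    chains = stats::setNames(chains, sprintf("chain_%d", seq_len(P))),
    chain_steps = chain_gprs,
    precursors = precursors,
    essential_genes = sort(unique(essential)),
    kinds = kinds,
    subsystems = stats::setNames(rxns$subsystem, rxns$id),
    blocked = blocked,
    dead_ends = sort(dead_ends),
    duplicated_chains = duplicated_chains
  )
  list(model = model, truth = truth, media = media, spec = spec)
}

#' Generate a homology table with a given retention rate
#'
#' Each source gene is independently retained with probability `rate`;
#' retained genes map to one or two synthetic target-species ids. The
#' result is seed-deterministic.
#'
#' @param model the source [metabolic_model()].
#' @param rate per-gene retention probability in \[0, 1\].
#' @param species target species label.
#' @param seed integer seed.
#' @return a [homology_table()].
#' @export
generate_homology_table <- function(model, rate, species = "target", seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  with_local_seed(seed, {
    genes <- sort(model$genes$id)
    kept <- genes[stats::runif(length(genes)) < rate]
    n_t <- 1L + (stats::runif(length(kept)) < 0.3)
    rows <- list()
    for (k in seq_along(kept)) {
      rows[[k]] <- data.frame(
        source_gene = kept[k], species = species,
        target_gene = sprintf("t_%s_%d", kept[k], seq_len(n_t[k])),
        stringsAsFactors = FALSE)
    }
    pairs <- if (length(rows)) do.call(rbind, rows) else
      data.frame(source_gene = character(0), species = character(0),
                 target_gene = character(0), stringsAsFactors = FALSE)
    homology_table(pairs, species = species)
  })
}

#' Remove biomass-path reactions to create a growth-broken model
#'
#' Picks `k` distinct single-path chains and deletes one random interior
#' conversion from each, guaranteeing that the biomass optimum drops to
#' zero (every precursor is required). Chains with a parallel duplicate
#' path are never picked, so the removed set is exactly the minimal repair
#' set.
#'
#' @param generated a [generate_source_model()] result.
#' @param k number of reactions to remove.
#' @param seed integer seed.
#' @return list with `model` (the gapped [metabolic_model()]) and
#'   `removed` (reaction ids, one per broken chain).
#' @export
plant_gaps <- function(generated, k, seed = 1) {
  model <- generated$model
  truth <- generated$truth
  if (k == 0L) return(list(model = model, removed = character(0)))
  eligible <- setdiff(seq_along(truth$chains), truth$duplicated_chains)
  if (k > length(eligible)) {
    stop("cannot break growth with ", k, " removals: only ",
         length(eligible), " single-path chains available")
  }
  with_local_seed(seed, {
    pick <- sample(eligible, k)
    removed <- vapply(pick, function(i) {
      steps <- truth$chain_steps[[i]]
      steps[[sample(length(steps), 1)]]$id
    }, character(1))
    gapped <- subset_reactions(model, setdiff(model$rxns$id, removed),
                               prune_mets = FALSE, prune_genes = FALSE)
    list(model = gapped, removed = removed)
  })
}

#' Generate a universal reaction database around planted gaps
#'
#' Builds a [reaction_db()] containing the given model reactions (e.g. the
#' planted-gap removals, with their original equations, directionality and
#' an organism-evidence flag) hidden among decoy reactions over
#' disconnected metabolites, which can never restore producibility.
#'
#' @param model the source [metabolic_model()] the entries come from.
#' @param include reaction ids to include as genuine entries.
#' @param n_decoys number of decoy reactions.
#' @param seed integer seed.
#' @param decoy_evidence_rate fraction of decoys carrying the evidence
#'   flag.
#' @return a [reaction_db()].
#' @export
generate_universal_db <- function(model, include, n_decoys = 50, seed = 1,
                                  decoy_evidence_rate = 0.5) {
  j <- match(include, model$rxns$id)
  if (anyNA(j)) stop("unknown reaction(s): ", paste(include[is.na(j)], collapse = ", "))
  genuine <- data.frame(
    id = paste0("U_", model$rxns$id[j]),
    equation = vapply(j, function(jj) {
      col <- model$S[, jj]
      format_equation(col[col != 0], reversible = model$rxns$lb[jj] < 0)
    }, character(1)),
    reversible = model$rxns$lb[j] < 0,
    evidence = TRUE, source = "planted", stringsAsFactors = FALSE)
  with_local_seed(seed, {
    decoys <- if (n_decoys > 0) data.frame(
      id = sprintf("U_DEC_%03d", seq_len(n_decoys)),
      equation = sprintf("d%d_a[c] %s d%d_b[c]", seq_len(n_decoys),
                         ifelse(stats::runif(n_decoys) < 0.5, "->", "<=>"),
                         seq_len(n_decoys)),
      evidence = stats::runif(n_decoys) < decoy_evidence_rate,
      source = "decoy", stringsAsFactors = FALSE) else NULL
    if (!is.null(decoys)) decoys$reversible <- grepl("<=>", decoys$equation)
    reaction_db(rbind(genuine, decoys[, c("id", "equation", "reversible",
                                          "evidence", "source")]))
  })
}

#' Generate a validation battery from ground truth
#'
#' One producibility test per biomass precursor plus one per designated
#' mid-chain intermediate, each under the minimal medium that feeds only
#' its own chain. Intermediate tests whose target lives in a non-cytosolic
#' compartment are flagged compartment-specific. The dependency map (which
#' chain reactions each test needs) is returned alongside, so planted gaps
#' fail exactly the predicted tests.
#'
#' @param generated a [generate_source_model()] result.
#' @param intermediates also test the mid-chain intermediate of every
#'   chain.
#' @return list with `battery` (a [validation_battery()]), `media` (the
#'   named medium list the battery references) and `deps` (named list test
#'   id -> reaction ids it depends on).
#' @export
generate_test_battery <- function(generated, intermediates = TRUE) {
  truth <- generated$truth
  model <- generated$model
  P <- length(truth$chains)
  rows <- list()
  deps <- list()
  for (i in seq_len(P)) {
    tid <- sprintf("prod_precursor_%d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      id = tid, description = sprintf("produce biomass precursor of chain %d", i),
      target = truth$precursors[i], medium = sprintf("min_%d", i),
      compartment_specific = FALSE, threshold = 1e-6, stringsAsFactors = FALSE)
    deps[[tid]] <- truth$chains[[i]]
    if (intermediates) {
      steps <- truth$chain_steps[[i]]
      mid <- max(1L, length(steps) %/% 2L)
      mid_id <- steps[[mid]]$id
      s <- reaction_stoichiometry(model, mid_id)
      prods <- names(s)[s > 0]
      # the chain intermediate, not the byproduct: producing it must need
      # only the upstream steps, so the dependency map stays exact
      target <- prods[parse_met_ids(prods)$base == sprintf("x%d_%d", i, mid)]
      comp <- parse_met_ids(target)$comp
      tid2 <- sprintf("prod_intermediate_%d", i)
      rows[[length(rows) + 1L]] <- data.frame(
        id = tid2, description = sprintf("produce mid-chain intermediate of chain %d", i),
        target = target, medium = sprintf("min_%d", i),
        compartment_specific = comp != "c", threshold = 1e-6,
        stringsAsFactors = FALSE)
      step_ids <- vapply(steps[seq_len(mid)], `[[`, character(1), "id")
      upstream <- c(sprintf("EX_x%d_0", i), sprintf("T_x%d_0", i), step_ids)
      if (i %in% truth$duplicated_chains) {
        upstream <- c(upstream, paste0(step_ids, "_alt"))
      }
      deps[[tid2]] <- upstream
    }
  }
  battery <- validation_battery(do.call(rbind, rows))
  list(battery = battery, media = generated$media, deps = deps)
}
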