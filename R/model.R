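#' Construct a compartmentalized constraint-based metabolic model
#'
#' The central container of the package: a stoichiometric network over
#' compartmentalized metabolites with flux bounds, GPR rules, subsystem
#' labels, reaction kind tags and a single objective (typically the biomass
#' pseudo-reaction). The stoichiometric matrix `S` (metabolites x reactions)
#' is stored sparse; steady-state analysis solves `S v = 0` with
#' `lb <= v <= ub`.
#'
#' Metabolite ids use the `base[compartment]` convention, e.g. `glc[c]`;
#' compartment codes follow the usual eight-compartment dialect of curated
#' mammalian reconstructions (`c` cytoplasm, `e` extracellular, `m`
#' mitochondria, `g` Golgi, `l` lysosome, `r` endoplasmic reticulum, `x`
#' peroxisome, `n` nucleus), but any one-letter code is accepted.
#'
#' @param genes data.frame with columns `id` (unique, non-empty) and
#'   optionally `name`.
#' @param mets data.frame with column `id` (`base[comp]`); columns `base`
#'   and `comp` are derived when absent.
#' @param rxns data.frame with columns `id`, `lb`, `ub` and optionally
#'   `name`, `gpr` (rule string), `subsystem`, `kind`. Missing bounds
#'   default to (0, 1000) and missing `kind` is classified from the
#'   stoichiometry (see [classify_reactions()]).
#' @param S stoichiometric matrix, metabolites x reactions, any Matrix or
#'   base matrix type; dimnames are imposed from `mets$id` and `rxns$id`.
#' @param objective id of the objective reaction, or `NA` for none.
#' @param id model label.
#' @return an object of class `metabolic_model` with elements `genes`,
#'   `mets`, `rxns`, `S` (dgCMatrix), `gprs` (parsed rule per reaction) and
#'   `objective`.
#' @export
metabolic_model <- function(genes, mets, rxns, S, objective = NA_character_,
                            id = "model") {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(genes$id)) genes$id <- character(0)
  if (is.null(genes$name)) genes$name <- genes$id
  if (any(!nzchar(genes$id)) || anyNA(genes$id)) stop("gene ids must be non-empty")
  if (anyDuplicated(genes$id)) stop("duplicate gene ids: ",
    paste(unique(genes$id[duplicated(genes$id)]), collapse = ", "))

  if (is.null(mets$base) || is.null(mets$comp)) {
    parts <- parse_met_ids(mets$id)
    mets$base <- parts$base
    mets$comp <- parts$comp
  }
  if (is.null(mets$name)) mets$name <- mets$base
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids: ",
    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))

  if (is.null(rxns$name)) rxns$name <- rxns$id
  if (is.null(rxns$lb)) rxns$lb <- 0
  if (is.null(rxns$ub)) rxns$ub <- 1000
  if (is.null(rxns$gpr)) rxns$gpr <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  if (is.null(rxns$subsystem)) rxns$subsystem <- ""
  rxns$subsystem[is.na(rxns$subsystem)] <- ""
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids: ",
    paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (any(rxns$lb > rxns$ub)) stop("reaction lower bound exceeds upper bound: ",
    paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "))

  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(S) != nrow(mets) || ncol(S) != nrow(rxns)) {
    stop(sprintf("S is %d x %d but model has %d metabolites and %d reactions",
                 nrow(S), ncol(S), nrow(mets), nrow(rxns)))
  }
  dimnames(S) <- list(mets$id, rxns$id)

  gprs <- lapply(rxns$gpr, parse_gpr)
  names(gprs) <- rxns$id
  for (i in seq_along(gprs)) {
    bad <- setdiff(gpr_genes(gprs[[i]]), genes$id)
    if (length(bad)) stop(sprintf("reaction %s: GPR references unknown gene(s) %s",
                                  rxns$id[i], paste(bad, collapse = ", ")))
  }

  if (!is.na(objective) && !objective %in% rxns$id) {
    stop("objective reaction not in model: ", objective)
  }

  m <- structure(list(id = id, genes = genes,
                      mets = mets[, c("id", "base", "comp", "name")],
                      rxns = rxns, S = S, gprs = gprs, objective = objective),
                 class = "metabolic_model")
  if (is.null(rxns$kind)) {
    m$rxns$kind <- classify_reactions(m)
  } else {
    m$rxns$kind[is.na(m$rxns$kind)] <- classify_reactions(m)[is.na(m$rxns$kind)]
  }
  rownames(m$rxns) <- NULL
  rownames(m$mets) <- NULL
  rownames(m$genes) <- NULL
  m
}

parse_met_ids <- function(ids) {
  ok <- grepl("^(.*)\\[([a-z])\\]$", ids)
  if (any(!ok)) stop("metabolite id not in base[comp] form: ",
                     paste(ids[!ok], collapse = ", "))
  list(base = sub("^(.*)\\[([a-z])\\]$", "\\1", ids),
       comp = sub("^(.*)\\[([a-z])\\]$", "\\2", ids))
}

#' @export
print.metabolic_model <- function(x, ...) {
  n_gar <- sum(nzchar(x$rxns$gpr))
  cat(sprintf("<metabolic_model> %s\n", x$id))
  cat(sprintf("  %d metabolites in %d compartments (%s)\n",
              nrow(x$mets), length(unique(x$mets$comp)),
              paste(sort(unique(x$mets$comp)), collapse = ",")))
  cat(sprintf("  %d reactions (%d gene-associated, %d not), %d genes\n",
              nrow(x$rxns), n_gar, nrow(x$rxns) - n_gar, nrow(x$genes)))
  cat(sprintf("  objective: %s\n", x$objective))
  invisible(x)
}

#' Classify reactions by structural role
#'
#' Assigns every reaction one of the kind tags `exchange` (single
#' extracellular metabolite crossing the system boundary), `demand`
#' (irreversible sink for a single intracellular metabolite), `sink`
#' (reversible single-metabolite intracellular boundary reaction),
#' `transport` (the same base metabolites moved between compartments
#' without chemical change), `biomass` (the model objective) or `metabolic`
#' (everything else). The classification is total: every reaction with
#' non-empty stoichiometry receives exactly one tag.
#'
#' @param model a [metabolic_model()].
#' @return character vector of kind tags, one per reaction, in model order.
#' @export
classify_reactions <- function(model) {
  S <- model$S
  comp <- model$mets$comp
  base <- model$mets$base
  vapply(seq_len(ncol(S)), function(j) {
    idx <- which(S[, j] != 0)
    if (length(idx) == 0L) stop("reaction has empty stoichiometry: ", model$rxns$id[j])
    if (!is.na(model$objective) && model$rxns$id[j] == model$objective) return("biomass")
    coef <- S[idx, j]
    if (length(idx) == 1L) {
      if (comp[idx] == "e") return("exchange")
      if (model$rxns$lb[j] < 0) return("sink")
      return("demand")
    }
    cps <- unique(comp[idx])
    if (length(cps) >= 2L) {
      neg <- sort(rep(base[idx][coef < 0], times = round(abs(coef[coef < 0]))))
      pos <- sort(rep(base[idx][coef > 0], times = round(abs(coef[coef > 0]))))
      if (length(neg) == length(pos) && all(neg == pos)) return("transport")
    }
    "metabolic"
  }, character(1))
}

#' Retrieve a reaction's stoichiometry as a named vector
#'
#' @param model a [metabolic_model()].
#' @param rxn reaction id.
#' @return named numeric vector (metabolite id -> coefficient), substrates
#'   negative.
#' @export
reaction_stoichiometry <- function(model, rxn) {
  j <- match(rxn, model$rxns$id)
  if (is.na(j)) stop("unknown reaction: ", rxn)
  col <- model$S[, j]
  col[col != 0]
}

#' Subset a model to a set of reactions
#'
#' Keeps the given reactions, drops metabolites that are no longer
#' referenced (optional) and genes no longer referenced by any surviving
#' GPR (optional).
#'
#' @param model a [metabolic_model()].
#' @param keep character vector of reaction ids to retain.
#' @param prune_mets,prune_genes drop now-unreferenced metabolites / genes.
#' @return a new `metabolic_model`.
#' @export
subset_reactions <- function(model, keep, prune_mets = TRUE, prune_genes = TRUE) {
  missing <- setdiff(keep, model$rxns$id)
  if (length(missing)) stop("unknown reaction(s): ", paste(missing, collapse = ", "))
  jj <- which(model$rxns$id %in% keep)
  rxns <- model$rxns[jj, , drop = FALSE]
  S <- model$S[, jj, drop = FALSE]
  mets <- model$mets
  if (prune_mets) {
    used <- Matrix::rowSums(S != 0) > 0
    mets <- mets[used, , drop = FALSE]
    S <- S[used, , drop = FALSE]
  }
  genes <- model$genes
  if (prune_genes) {
    used_genes <- sort(unique(unlist(lapply(model$gprs[jj], gpr_genes))))
    genes <- genes[genes$id %in% used_genes, , drop = FALSE]
  }
  obj <- if (!is.na(model$objective) && model$objective %in% rxns$id) model$objective else NA_character_
  metabolic_model(genes, mets, rxns, S, objective = obj, id = model$id)
}

#' Add reactions (and any new metabolites/genes) to a model
#'
#' @param model a [metabolic_model()].
#' @param rxns data.frame of new reactions (`id`, `lb`, `ub`, optional
#'   `gpr`, `subsystem`, `kind`, `name`).
#' @param stoich list of named numeric vectors, one per new reaction,
#'   metabolite id -> coefficient. New metabolite ids are created on the
#'   fly; new gene ids referenced by the GPRs are added to the gene list.
#' @return a new `metabolic_model`.
#' @export
add_reactions <- function(model, rxns, stoich) {
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (nrow(rxns) == 0L) return(model)
  clash <- intersect(rxns$id, model$rxns$id)
  if (length(clash)) stop("reaction id(s) already in model: ", paste(clash, collapse = ", "))
  if (length(stoich) != nrow(rxns)) stop("stoich must have one entry per reaction")

  new_mets <- setdiff(unique(unlist(lapply(stoich, names))), model$mets$id)
  mets <- model$mets
  if (length(new_mets)) {
    parts <- parse_met_ids(new_mets)
    mets <- rbind(mets, data.frame(id = new_mets, base = parts$base,
                                   comp = parts$comp, name = parts$base,
                                   stringsAsFactors = FALSE))
  }
  gpr_col <- if (is.null(rxns$gpr)) rep("", nrow(rxns)) else ifelse(is.na(rxns$gpr), "", rxns$gpr)
  new_genes <- setdiff(unique(unlist(lapply(gpr_col, function(g) gpr_genes(parse_gpr(g))))),
                       model$genes$id)
  genes <- model$genes
  if (length(new_genes)) {
    genes <- rbind(genes, data.frame(id = new_genes, name = new_genes,
                                     stringsAsFactors = FALSE))
  }

  # assemble triplets for the appended block
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(stoich)) {
    s <- stoich[[k]]
    if (length(s) == 0L) stop("empty stoichiometry for reaction ", rxns$id[k])
    ii <- c(ii, match(names(s), mets$id))
    jj <- c(jj, rep(k, length(s)))
    xx <- c(xx, unname(s))
  }
  new_block <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                    dims = c(nrow(mets), nrow(rxns)))
  old_S <- model$S
  if (nrow(mets) > nrow(old_S)) {
    pad <- Matrix::Matrix(0, nrow(mets) - nrow(old_S), ncol(old_S), sparse = TRUE)
    old_S <- rbind(old_S, pad)
  }
  S <- cbind(old_S, new_block)

  all_rxns <- merge_rxn_frames(model$rxns, rxns)
  metabolic_model(genes, mets, all_rxns, S, objective = model$objective, id = model$id)
}

merge_rxn_frames <- function(a, b) {
  cols <- c("id", "name", "lb", "ub", "gpr", "subsystem", "kind")
  fill <- function(df) {
    if (is.null(df$name)) df$name <- df$id
    if (is.null(df$lb)) df$lb <- 0
    if (is.null(df$ub)) df$ub <- 1000
    if (is.null(df$gpr)) df$gpr <- ""
    if (is.null(df$subsystem)) df$subsystem <- ""
    if (is.null(df$kind)) df$kind <- NA_character_
    df[, cols]
  }
  rbind(fill(a), fill(b))
}

#' Set reaction bounds
#'
#' @param model a [metabolic_model()].
#' @param rxn reaction id(s).
#' @param lb,ub new bounds (recycled along `rxn`); `NULL` leaves a bound
#'   unchanged.
#' @return a new `metabolic_model`.
#' @export
set_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  j <- match(rxn, model$rxns$id)
  if (anyNA(j)) stop("unknown reaction(s): ", paste(rxn[is.na(j)], collapse = ", "))
  if (!is.null(lb)) model$rxns$lb[j] <- rep(lb, length.out = length(j))
  if (!is.null(ub)) model$rxns$ub[j] <- rep(ub, length.out = length(j))
  if (any(model$rxns$lb[j] > model$rxns$ub[j])) stop("lower bound exceeds upper bound")
  model
}

#' Medium conditions
#'
#' A medium is a set of exchange-reaction bounds: listed exchanges get the
#' stated (lower, upper) bounds, every unlisted exchange is closed for
#' uptake (lower = 0) and left open for secretion at the default bound.
#' Applying a medium twice is idempotent.
#'
#' @param exchanges data.frame with columns `exchange` (reaction id),
#'   `lb`, `ub`; or a character vector of exchange ids to open at
#'   `(uptake, secretion)`.
#' @param id medium label.
#' @param uptake,secretion default bounds used when `exchanges` is a plain
#'   character vector.
#' @return an object of class `medium_condition`.
#' @export
medium_condition <- function(exchanges, id = "medium", uptake = -1000, secretion = 1000) {
  if (is.character(exchanges)) {
    exchanges <- data.frame(exchange = exchanges,
                            lb = rep(uptake, length(exchanges)),
                            ub = rep(secretion, length(exchanges)),
                            stringsAsFactors = FALSE)
  }
  exchanges <- as.data.frame(exchanges, stringsAsFactors = FALSE)
  stopifnot(all(c("exchange", "lb", "ub") %in% names(exchanges)))
  if (anyDuplicated(exchanges$exchange)) stop("duplicate exchange ids in medium")
  structure(list(id = id, exchanges = exchanges), class = "medium_condition")
}

#' Apply a medium to a model
#'
#' Closes the uptake (lower) bound of every exchange reaction, then applies
#' the medium's listed bounds. Non-exchange reactions are untouched. An id
#' listed in the medium that is not an exchange reaction of the model is an
#' error.
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_condition()], or `NULL` for no change.
#' @param secretion default upper bound given to unlisted exchanges.
#' @return a new `metabolic_model` with medium bounds applied.
#' @export
apply_medium <- function(model, medium, secretion = 1000) {
  if (is.null(medium)) return(model)
  stopifnot(inherits(medium, "medium_condition"))
  ex <- model$rxns$id[model$rxns$kind == "exchange"]
  bad <- setdiff(medium$exchanges$exchange, ex)
  if (length(bad)) stop("medium lists non-exchange or unknown reaction(s): ",
                        paste(bad, collapse = ", "))
  model$rxns$lb[model$rxns$kind == "exchange"] <- 0
  model$rxns$ub[model$rxns$kind == "exchange"] <- secretion
  j <- match(medium$exchanges$exchange, model$rxns$id)
  model$rxns$lb[j] <- medium$exchanges$lb
  model$rxns$ub[j] <- medium$exchanges$ub
  model
}

#' Identify dead-end metabolites
#'
#' A metabolite is a dead end when, taking reaction reversibility into
#' account, it can only ever be produced or only ever be consumed — every
#' reaction touching it is then forced to zero flux at steady state. A
#' metabolite is "producible" if some reaction can increase it (positive
#' coefficient with a positive upper bound, or negative coefficient with a
#' negative lower bound), and symmetrically for "consumable".
#'
#' @param model a [metabolic_model()].
#' @return character vector of dead-end metabolite ids.
#' @export
count_dead_ends <- function(model) {
  S <- model$S
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  dead <- character(0)
  for (i in seq_len(nrow(S))) {
    row <- S[i, ]
    jj <- which(row != 0)
    can_produce <- any(row[jj] > 0 & ub[jj] > 0) || any(row[jj] < 0 & lb[jj] < 0)
    can_consume <- any(row[jj] < 0 & ub[jj] > 0) || any(row[jj] > 0 & lb[jj] < 0)
    if (!(can_produce && can_consume)) dead <- c(dead, model$mets$id[i])
  }
  dead
}

#' Merge intracellular compartments of a model
#'
#' Produces the non-compartmentalized variant of a reconstruction: all
#' intracellular compartments are merged into a single cytosolic
#' compartment while the extracellular space is kept, so that exchange
#' reactions and media remain meaningful. Metabolites are deduplicated by
#' base id; reactions whose stoichiometry cancels to nothing (pure
#' intracellular transport) are dropped; reactions that become duplicates
#' (identical stoichiometry and identical bounds) are merged, keeping the
#' union of their GPRs as an `or` — after compartment information is lost,
#' either enzyme suffices.
#'
#' @param model a [metabolic_model()].
#' @param keep_extracellular keep `e` as a separate compartment (default);
#'   `FALSE` merges everything into one compartment, which deletes all
#'   exchange reactions and is only useful for topological analyses.
#' @return a new `metabolic_model` with at most two compartments.
#' @export
decompartmentalize <- function(model, keep_extracellular = TRUE) {
  comp_of <- function(cp) if (keep_extracellular && cp == "e") "e" else "c"
  new_comp <- vapply(model$mets$comp, comp_of, character(1))
  new_id <- paste0(model$mets$base, "[", new_comp, "]")
  umets <- !duplicated(new_id)
  mets <- data.frame(id = new_id[umets], base = model$mets$base[umets],
                     comp = new_comp[umets], name = model$mets$name[umets],
                     stringsAsFactors = FALSE)

  # collapse S rows by merged metabolite id
  ridx <- match(new_id, mets$id)
  agg <- Matrix::sparseMatrix(i = ridx, j = seq_along(ridx), x = 1,
                              dims = c(nrow(mets), nrow(model$S)))
  S <- agg %*% model$S
  S <- Matrix::drop0(S)

  nonzero <- Matrix::colSums(S != 0) > 0
  keep_obj <- !is.na(model$objective) & model$rxns$id == model$objective
  keep <- nonzero | keep_obj
  if (!is.na(model$objective) && !nonzero[which(keep_obj)]) {
    stop("objective reaction cancels out under compartment merge")
  }
  S <- S[, keep, drop = FALSE]
  rxns <- model$rxns[keep, , drop = FALSE]

  # merge duplicates: identical stoichiometry and identical bounds
  sig <- vapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    paste(c(sprintf("%s:%g", mets$id[nz], col[nz]),
            sprintf("b:%g,%g", rxns$lb[j], rxns$ub[j])), collapse = ";")
  }, character(1))
  first <- !duplicated(sig)
  grp <- match(sig, sig[first])
  merged_gpr <- vapply(seq_len(sum(first)), function(g) {
    rules <- unique(rxns$gpr[grp == g])
    rules <- rules[nzchar(rules)]
    if (length(rules) == 0L) return("")
    if (length(rules) == 1L) return(rules)
    paste(sprintf("(%s)", rules), collapse = " or ")
  }, character(1))
  rxns2 <- rxns[first, , drop = FALSE]
  rxns2$gpr <- merged_gpr
  rxns2$kind <- NA_character_  # re-classify in the merged compartment layout
  S2 <- S[, first, drop = FALSE]

  used <- Matrix::rowSums(S2 != 0) > 0
  m <- metabolic_model(model$genes, mets[used, , drop = FALSE], rxns2,
                       S2[used, , drop = FALSE],
                       objective = model$objective,
                       id = paste0(model$id, "_collapsed"))
  m
}

#' Is a model compartment-collapsed?
#'
#' @param model a [metabolic_model()].
#' @return `TRUE` when at most one intracellular compartment remains.
#' @export
is_collapsed <- function(model) {
  length(setdiff(unique(model$mets$comp), "e")) <= 1L
}
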