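#' Run an FBA validation-test battery
#'
#' Each test is evaluated independently on a fresh copy of the model: the
#' test's medium is applied, the test objective is maximized, and the test
#' passes when the achieved flux reaches its threshold. When the target is
#' a metabolite id a temporary demand reaction is created for it and
#' removed afterwards, so tests never contaminate each other or the model.
#' A target metabolite absent from the model marks the test `error` (not
#' `fail`); tests flagged compartment-specific are skipped on collapsed
#' models and excluded from the pass fraction.
#'
#' @param model a [metabolic_model()].
#' @param battery a [validation_battery()].
#' @param media named list of [medium_condition()] objects referenced by
#'   the battery's `medium` column.
#' @param collapsed is the model compartment-collapsed? Defaults to
#'   [is_collapsed()] of the model.
#' @return an object of class `validation_outcome`: data.frame with
#'   columns `id`, `status` (`pass`/`fail`/`error`/`skipped`), `flux`;
#'   the battery pass fraction over applicable tests is in
#'   `attr(, "pass_fraction")`.
#' @export
run_battery <- function(model, battery, media = list(),
                        collapsed = is_collapsed(model)) {
  stopifnot(inherits(battery, "validation_battery"))
  missing_media <- setdiff(unique(battery$medium), names(media))
  if (length(missing_media)) stop("battery references unknown media: ",
                                  paste(missing_media, collapse = ", "))
  n <- nrow(battery)
  status <- character(n)
  flux <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (collapsed && battery$compartment_specific[i]) {
      status[i] <- "skipped"
      next
    }
    res <- run_one_test(model, battery$target[i], media[[battery$medium[i]]])
    if (is.na(res)) {
      status[i] <- "error"
    } else {
      flux[i] <- res
      status[i] <- if (res >= battery$threshold[i]) "pass" else "fail"
    }
  }
  out <- data.frame(id = battery$id, status = status, flux = flux,
                    stringsAsFactors = FALSE)
  applicable <- status %in% c("pass", "fail")
  attr(out, "pass_fraction") <- if (any(applicable)) {
    mean(status[applicable] == "pass")
  } else NA_real_
  class(out) <- c("validation_outcome", "data.frame")
  out
}

# maximize producibility of a target (reaction id or metabolite id) under a
# medium; returns achieved flux, or NA when the target cannot be resolved
run_one_test <- function(model, target, medium) {
  if (target %in% model$rxns$id) {
    m <- apply_medium(model, medium)
    obj <- target
  } else if (target %in% model$mets$id) {
    m <- add_reactions(model,
                       data.frame(id = ".test_demand", lb = 0, ub = 1000,
                                  stringsAsFactors = FALSE),
                       list(stats::setNames(-1, target)))
    m <- apply_medium(m, medium)
    obj <- ".test_demand"
  } else {
    return(NA_real_)
  }
  sol <- solve_fba(m, obj)
  if (sol$status != "optimal") 0 else sol$objective_value
}

#' Pass fraction of a battery outcome
#'
#' @param outcome a [run_battery()] result.
#' @return fraction of applicable tests passed, in \[0, 1\].
#' @export
pass_fraction <- function(outcome) attr(outcome, "pass_fraction")

#' Diagnose failing validation tests against a removed-reaction pool
#'
#' For every failing test, searches the pool of reactions removed during
#' projection for a minimal restoration that makes the test pass: first
#' single reactions, then (when no single fix exists) pairs, bounded by
#' `max_combinations`. This is the mechanical core of the iterative
#' curation loop in which removed reactions with independent evidence are
#' added back until the battery passes.
#'
#' @param model the current (projected) [metabolic_model()].
#' @param outcome a [run_battery()] result for `model`.
#' @param source the source model the removed reactions came from.
#' @param removed character vector of removed reaction ids (from the
#'   projection report).
#' @param battery,media the battery and media used for `outcome`.
#' @param max_depth restoration set size cap (1 or 2).
#' @param max_combinations cap on candidate pair evaluations per test.
#' @return data.frame of curation candidates: `test`, `reactions`
#'   (comma-joined restoration set), `n`; tests with no candidate appear
#'   with `reactions = NA` (unresolvable from the pool).
#' @export
diagnose_failures <- function(model, outcome, source, removed, battery, media,
                              max_depth = 2, max_combinations = 1e4) {
  stopifnot(inherits(outcome, "validation_outcome"))
  failing <- outcome$id[outcome$status == "fail"]
  rows <- list()
  for (tid in failing) {
    ti <- match(tid, battery$id)
    target <- battery$target[ti]
    medium <- media[[battery$medium[ti]]]
    threshold <- battery$threshold[ti]
    found <- NULL
    for (r in removed) {
      m2 <- restore_reactions(model, source, r)
      val <- run_one_test(m2, target, medium)
      if (!is.na(val) && val >= threshold) { found <- r; break }
    }
    if (is.null(found) && max_depth >= 2 && length(removed) >= 2) {
      combos <- utils::combn(removed, 2, simplify = FALSE)
      if (length(combos) > max_combinations) combos <- combos[seq_len(max_combinations)]
      for (pair in combos) {
        m2 <- restore_reactions(model, source, pair)
        val <- run_one_test(m2, target, medium)
        if (!is.na(val) && val >= threshold) { found <- pair; break }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      test = tid,
      reactions = if (is.null(found)) NA_character_ else paste(found, collapse = ","),
      n = if (is.null(found)) 0L else length(found),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(0), reactions = character(0), n = integer(0),
               stringsAsFactors = FALSE)
}

# restore reactions from the source model, with original stoichiometry,
# bounds, GPR and subsystem (GPR kept in the source namespace)
restore_reactions <- function(model, source, ids) {
  ids <- setdiff(ids, model$rxns$id)
  if (length(ids) == 0L) return(model)
  j <- match(ids, source$rxns$id)
  if (anyNA(j)) stop("reaction(s) not in source model: ",
                     paste(ids[is.na(j)], collapse = ", "))
  stoich <- lapply(j, function(jj) {
    col <- source$S[, jj]
    col[col != 0]
  })
  add_reactions(model, source$rxns[j, , drop = FALSE], stoich)
}

#' Apply curation actions to a model
#'
#' Restores the listed reactions from the source model with their original
#' bounds, stoichiometry and GPR. Restoring a reaction already present is
#' an error (id collision).
#'
#' @param model a [metabolic_model()].
#' @param actions a [diagnose_failures()] result, or a character vector of
#'   reaction ids.
#' @param source the source model.
#' @return a new `metabolic_model`.
#' @export
apply_curation <- function(model, actions, source) {
  ids <- if (is.character(actions)) actions else {
    good <- actions$reactions[!is.na(actions$reactions)]
    unique(unlist(strsplit(good, ",", fixed = TRUE)))
  }
  if (length(ids) == 0L) return(model)
  clash <- intersect(ids, model$rxns$id)
  if (length(clash)) stop("reaction(s) already in model: ",
                          paste(clash, collapse = ", "))
  restore_reactions(model, source, ids)
}

#' Iterative validation-and-curation loop
#'
#' Alternates [run_battery()], [diagnose_failures()] and [apply_curation()]
#' until the battery passes completely, no failing test can be fixed from
#' the removed pool, or `max_rounds` is reached. The pass fraction is
#' non-decreasing across rounds; on synthetic models with a complete pool
#' the loop terminates at 100%.
#'
#' @inheritParams diagnose_failures
#' @param max_rounds round cap.
#' @return list with the curated `model`, the final `outcome`, `restored`
#'   reaction ids, `unresolved` test ids and the per-round pass-fraction
#'   `history`.
#' @export
curate_model <- function(model, battery, media, source, removed,
                         max_rounds = 10, max_depth = 2) {
  restored <- character(0)
  history <- numeric(0)
  outcome <- run_battery(model, battery, media)
  history <- c(history, pass_fraction(outcome))
  for (round in seq_len(max_rounds)) {
    if (!any(outcome$status == "fail")) break
    pool <- setdiff(removed, restored)
    cand <- diagnose_failures(model, outcome, source, pool, battery, media,
                              max_depth = max_depth)
    ids <- unique(unlist(strsplit(cand$reactions[!is.na(cand$reactions)], ",",
                                  fixed = TRUE)))
    if (length(ids) == 0L) break
    model <- apply_curation(model, ids, source)
    restored <- c(restored, ids)
    outcome <- run_battery(model, battery, media)
    history <- c(history, pass_fraction(outcome))
  }
  list(model = model, outcome = outcome, restored = restored,
       unresolved = outcome$id[outcome$status == "fail"],
       history = history)
}
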