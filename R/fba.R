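#' Flux balance analysis
#'
#' Maximizes the flux through the objective reaction subject to
#' steady-state mass balance `S v = 0` and the reaction bounds
#' `lb <= v <= ub` — the standard FBA linear program. The returned status
#' distinguishes `optimal`, `infeasible`, `unbounded` and solver `error`.
#'
#' @param model a [metabolic_model()].
#' @param objective objective reaction id; defaults to the model objective.
#' @return an object of class `flux_solution`: list with `status`,
#'   `objective_value` and named flux vector `fluxes`.
#' @examples
#' \dontrun{
#' m <- generate_source_model(synthetic_spec(seed = 1))$model
#' solve_fba(m)$objective_value
#' }
#' @export
solve_fba <- function(model, objective = model$objective) {
  j <- match(objective, model$rxns$id)
  if (is.na(j)) stop("objective reaction not in model: ", objective)
  n <- nrow(model$rxns)
  obj <- numeric(n)
  obj[j] <- 1
  res <- lp_solve(obj, A_eq = model$S, b_eq = numeric(nrow(model$S)),
                  lb = model$rxns$lb, ub = model$rxns$ub, sense = "max")
  structure(list(status = res$status,
                 objective_value = res$objective,
                 objective = objective,
                 fluxes = stats::setNames(res$x, model$rxns$id)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s: objective %s = %s\n", x$status,
              x$objective, format(x$objective_value)))
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, finds the minimal and maximal flux attainable while
#' the objective is held at (a fraction of) its FBA optimum: two LPs per
#' reaction over the constraint set of [solve_fba()] plus
#' `v_obj >= fraction * Z*`. Reactions are processed in model order so
#' results are reproducible run to run.
#'
#' @param model a [metabolic_model()].
#' @param objective objective reaction id.
#' @param fraction fraction of the optimum the objective must retain, in
#'   \[0, 1\]; default 1 (flux ranges at maximal objective production). A
#'   small absolute slack (`slack`) is subtracted so that solver-tolerance
#'   jitter in `Z*` cannot make the fixation infeasible.
#' @param reactions reaction ids to scan (default: all).
#' @param slack absolute slack on the objective fixation.
#' @return an object of class `fva_result`: data.frame with columns
#'   `reaction`, `min`, `max`, `subsystem`, plus attributes `optimum`
#'   (reference FBA optimum) and `fraction`.
#' @export
run_fva <- function(model, objective = model$objective, fraction = 1.0,
                    reactions = NULL, slack = 1e-9) {
  stopifnot(fraction >= 0, fraction <= 1)
  fba <- solve_fba(model, objective)
  if (fba$status != "optimal") {
    stop("FVA requires an optimal FBA solution; status was ", fba$status)
  }
  if (is.null(reactions)) reactions <- model$rxns$id
  jj <- match(reactions, model$rxns$id)
  if (anyNA(jj)) stop("unknown reaction(s): ", paste(reactions[is.na(jj)], collapse = ", "))
  jobj <- match(objective, model$rxns$id)
  n <- nrow(model$rxns)

  # objective fixation as one inequality row: -v_obj <= -(fraction Z* - slack)
  floor_val <- fraction * fba$objective_value - slack
  A_ub <- matrix(0, 1, n)
  A_ub[1, jobj] <- -1
  b_ub <- -floor_val

  vmin <- vmax <- numeric(length(jj))
  for (k in seq_along(jj)) {
    obj <- numeric(n)
    obj[jj[k]] <- 1
    lo <- lp_solve(obj, A_eq = model$S, b_eq = numeric(nrow(model$S)),
                   A_ub = A_ub, b_ub = b_ub,
                   lb = model$rxns$lb, ub = model$rxns$ub, sense = "min")
    hi <- lp_solve(obj, A_eq = model$S, b_eq = numeric(nrow(model$S)),
                   A_ub = A_ub, b_ub = b_ub,
                   lb = model$rxns$lb, ub = model$rxns$ub, sense = "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal for reaction ", reactions[k])
    }
    vmin[k] <- lo$objective
    vmax[k] <- hi$objective
  }
  out <- data.frame(reaction = reactions, min = vmin, max = vmax,
                    subsystem = model$rxns$subsystem[jj],
                    stringsAsFactors = FALSE)
  attr(out, "optimum") <- fba$objective_value
  attr(out, "fraction") <- fraction
  class(out) <- c("fva_result", "data.frame")
  out
}

#' Count reactions with non-zero flux capacity
#'
#' A reaction is active when its FVA range leaves zero, i.e.
#' `max(|v_min|, |v_max|) > tol`. These are the non-zero-flux counts used
#' to compare draft reconstructions.
#'
#' @param fva an [run_fva()] result.
#' @param tol activity tolerance (default `1e-6`, well above LP
#'   feasibility noise).
#' @return integer count.
#' @export
count_active <- function(fva, tol = 1e-6) {
  sum(pmax(abs(fva$min), abs(fva$max)) > tol)
}

#' Write FVA results as TSV
#'
#' @param fva an [run_fva()] result.
#' @param path file path.
#' @export
write_fva_tsv <- function(fva, path) {
  utils::write.table(as.data.frame(fva)[, c("reaction", "min", "max", "subsystem")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a single-gene deletion
#'
#' Removes the gene from the GPR gene set and sets the bounds of every
#' reaction whose GPR now evaluates false to (0, 0); reactions covered by
#' an isozyme survive. The input model is unmodified.
#'
#' @param model a [metabolic_model()].
#' @param gene gene id present in the model.
#' @return a new `metabolic_model`; the ids of the disabled reactions are
#'   in `attr(, "disabled")`.
#' @export
delete_gene <- function(model, gene) {
  if (!gene %in% model$genes$id) stop("unknown gene: ", gene)
  present <- setdiff(model$genes$id, gene)
  affected <- which(vapply(model$gprs, function(g) gene %in% gpr_genes(g), logical(1)))
  disabled <- affected[!vapply(model$gprs[affected], evaluate_gpr, logical(1),
                               present = present)]
  out <- model
  out$rxns$lb[disabled] <- 0
  out$rxns$ub[disabled] <- 0
  attr(out, "disabled") <- model$rxns$id[disabled]
  out
}

#' Single-gene essentiality screen
#'
#' Deletes every gene in turn ([delete_gene()]) and re-optimizes biomass;
#' a gene is essential when the knockout optimum falls below the
#' essentiality threshold — "zero biomass production" up to solver
#' tolerance. Genes are screened in sorted order for reproducibility.
#'
#' @param model a [metabolic_model()].
#' @param medium optional [medium_condition()] applied before screening.
#' @param genes gene ids to screen (default: all model genes).
#' @param threshold essentiality cutoff on the knockout optimum
#'   (default `1e-6` flux units).
#' @return data.frame with one row per gene: `gene`, `n_disabled`
#'   (reactions shut by the deletion), `optimum`, `essential`; the
#'   wild-type optimum is in `attr(, "wildtype_optimum")`.
#' @export
essentiality_screen <- function(model, medium = NULL, genes = NULL,
                                threshold = 1e-6) {
  model <- apply_medium(model, medium)
  if (is.null(genes)) genes <- sort(model$genes$id)
  wt <- solve_fba(model)
  if (wt$status != "optimal" || wt$objective_value <= threshold) {
    stop("wild-type model does not grow under the given medium (status ",
         wt$status, ", objective ", format(wt$objective_value), ")")
  }
  n_disabled <- integer(length(genes))
  optimum <- numeric(length(genes))
  for (k in seq_along(genes)) {
    ko <- delete_gene(model, genes[k])
    dis <- attr(ko, "disabled")
    n_disabled[k] <- length(dis)
    if (length(dis) == 0L) {
      optimum[k] <- wt$objective_value  # nothing disabled: wild-type LP
    } else {
      sol <- solve_fba(ko)
      optimum[k] <- if (sol$status == "optimal") sol$objective_value else 0
    }
  }
  out <- data.frame(gene = genes, n_disabled = n_disabled, optimum = optimum,
                    essential = optimum < threshold, stringsAsFactors = FALSE)
  attr(out, "wildtype_optimum") <- wt$objective_value
  attr(out, "threshold") <- threshold
  out
}

#' Write deletion-screen results as TSV
#'
#' @param screen an [essentiality_screen()] result.
#' @param path file path.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
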