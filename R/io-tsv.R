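#' Parse and format reaction equation strings
#'
#' Equations use compartment-suffixed metabolite ids and either `->`
#' (irreversible) or `<=>` (reversible) arrows, e.g.
#' `"glc[e] + atp[c] -> g6p[c] + adp[c]"`. Coefficients other than 1 are
#' written before the metabolite (`"2 h[c]"`). One side may be empty, as in
#' exchange (`"glc[e] <=>"`) or demand (`"g6p[c] ->"`) reactions.
#'
#' @param eq equation string.
#' @return `parse_equation()`: list with `stoich` (named numeric vector,
#'   substrates negative) and `reversible` (logical).
#' @export
parse_equation <- function(eq) {
  eq <- trimws(eq)
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- if (rev) strsplit(eq, "<=>", fixed = TRUE)[[1]] else strsplit(eq, "->", fixed = TRUE)[[1]]
  if (!rev && !grepl("->", eq, fixed = TRUE)) stop("equation has no arrow: ", eq)
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      if (!nzchar(t)) stop("empty term in equation: ", eq)
      mm <- regmatches(t, regexec("^([0-9.]+)\\s+(.*)$", t))[[1]]
      if (length(mm) == 3L) {
        coef <- as.numeric(mm[2]); met <- mm[3]
      } else {
        coef <- 1; met <- t
      }
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- c(lhs, rhs)
  # a metabolite on both sides nets out
  stoich <- tapply(stoich, names(stoich), sum)
  stoich <- stoich[stoich != 0]
  list(stoich = stats::setNames(as.numeric(stoich), names(stoich)), reversible = rev)
}

#' @rdname parse_equation
#' @param stoich named numeric vector, substrates negative.
#' @param reversible use `<=>` instead of `->`.
#' @export
format_equation <- function(stoich, reversible = FALSE) {
  fmt_side <- function(s) {
    if (length(s) == 0L) return("")
    s <- s[order(names(s))]
    paste(ifelse(abs(s) == 1, names(s), sprintf("%g %s", abs(s), names(s))),
          collapse = " + ")
  }
  lhs <- fmt_side(stoich[stoich < 0])
  rhs <- fmt_side(stoich[stoich > 0])
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}

#' Read and write models as tab-separated reaction tables
#'
#' The tabular dialect carries one reaction per row with columns
#' `abbreviation`, `name`, `equation` (compartment-suffixed, see
#' [parse_equation()]), `lowbnd`, `upbnd`, `gpr`, `subsystem`, plus an
#' optional `objective` column (1 marks the objective reaction). Bounds
#' left empty default to (0, 1000) for irreversible and (-1000, 1000) for
#' reversible equations, the usual +/-1000 mmol/gDW/hr convention.
#'
#' @param path file path.
#' @param id model label given to the result.
#' @return `read_model_tsv()`: a [metabolic_model()].
#' @export
read_model_tsv <- function(path, id = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  need <- c("abbreviation", "equation")
  if (!all(need %in% names(df))) stop("reaction table must have columns: ",
                                      paste(need, collapse = ", "))
  if (anyDuplicated(df$abbreviation)) stop("duplicate reaction ids in ", path)
  parsed <- lapply(df$equation, parse_equation)
  revs <- vapply(parsed, `[[`, logical(1), "reversible")
  lb <- if ("lowbnd" %in% names(df)) df$lowbnd else rep(NA_real_, nrow(df))
  ub <- if ("upbnd" %in% names(df)) df$upbnd else rep(NA_real_, nrow(df))
  lb[is.na(lb)] <- ifelse(revs[is.na(lb)], -1000, 0)
  ub[is.na(ub)] <- 1000
  gpr <- if ("gpr" %in% names(df)) ifelse(is.na(df$gpr), "", df$gpr) else ""
  sub <- if ("subsystem" %in% names(df)) ifelse(is.na(df$subsystem), "", df$subsystem) else ""
  nm <- if ("name" %in% names(df)) ifelse(is.na(df$name), df$abbreviation, df$name) else df$abbreviation

  met_ids <- sort(unique(unlist(lapply(parsed, function(p) names(p$stoich)))))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(parsed)) {
    s <- parsed[[k]]$stoich
    ii <- c(ii, match(names(s), met_ids))
    jj <- c(jj, rep(k, length(s)))
    xx <- c(xx, unname(s))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), nrow(df)))
  genes <- sort(unique(unlist(lapply(gpr, function(g) gpr_genes(parse_gpr(g))))))
  obj <- NA_character_
  if ("objective" %in% names(df)) {
    w <- which(!is.na(df$objective) & df$objective == 1)
    if (length(w) > 1L) stop("more than one objective reaction flagged in ", path)
    if (length(w) == 1L) obj <- df$abbreviation[w]
  }
  metabolic_model(
    genes = data.frame(id = genes, stringsAsFactors = FALSE),
    mets = data.frame(id = met_ids, stringsAsFactors = FALSE),
    rxns = data.frame(id = df$abbreviation, name = nm, lb = lb, ub = ub,
                      gpr = gpr, subsystem = sub, stringsAsFactors = FALSE),
    S = S, objective = obj, id = id)
}

#' @rdname read_model_tsv
#' @param model a [metabolic_model()].
#' @export
write_model_tsv <- function(model, path) {
  eqs <- vapply(seq_len(nrow(model$rxns)), function(j) {
    col <- model$S[, j]
    format_equation(col[col != 0], reversible = model$rxns$lb[j] < 0)
  }, character(1))
  df <- data.frame(abbreviation = model$rxns$id, name = model$rxns$name,
                   equation = eqs, lowbnd = model$rxns$lb, upbnd = model$rxns$ub,
                   gpr = model$rxns$gpr, subsystem = model$rxns$subsystem,
                   objective = as.integer(!is.na(model$objective) &
                                            model$rxns$id == model$objective),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write medium definitions
#'
#' Medium files are TSV with columns `exchange`, `lb`, `ub`, one row per
#' open exchange reaction; an optional `medium` column allows several media
#' per file, in which case `read_medium_tsv()` returns a named list.
#'
#' @param path file path.
#' @return a [medium_condition()] or a named list of them.
#' @export
read_medium_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("exchange", "lb", "ub") %in% names(df)))
  if ("medium" %in% names(df)) {
    out <- lapply(split(df, df$medium), function(d)
      medium_condition(d[, c("exchange", "lb", "ub")], id = d$medium[1]))
    return(out[unique(df$medium)])
  }
  medium_condition(df, id = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_medium_tsv
#' @param medium a [medium_condition()] or named list of them.
#' @export
write_medium_tsv <- function(medium, path) {
  if (inherits(medium, "medium_condition")) medium <- list(medium)
  df <- do.call(rbind, lapply(medium, function(m)
    cbind(medium = m$id, m$exchanges)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Homology tables
#'
#' A homology table maps each source-reconstruction gene to the (possibly
#' empty) set of homologous genes in a target species; it drives the
#' orthology projection. The file dialect is TSV with columns
#' `source_gene`, `species`, `target_gene`, one row per homolog pair; a
#' source gene with no row maps to the empty set.
#'
#' @param pairs data.frame with columns `source_gene`, `target_gene` and
#'   optionally `species`, `group` (provenance tag, e.g. a homology-group
#'   id).
#' @param species species label.
#' @return an object of class `homology_table` with a `map` element
#'   (named list source gene -> character vector of targets).
#' @export
homology_table <- function(pairs, species = "target") {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    pairs <- data.frame(source_gene = character(0), target_gene = character(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source_gene", "target_gene") %in% names(pairs)))
  map <- lapply(split(pairs$target_gene, pairs$source_gene), function(x) sort(unique(x)))
  structure(list(species = species, pairs = pairs, map = map),
            class = "homology_table")
}

#' @export
print.homology_table <- function(x, ...) {
  cat(sprintf("<homology_table> %s: %d source genes mapped, %d pairs\n",
              x$species, length(x$map), nrow(x$pairs)))
  invisible(x)
}

#' @rdname homology_table
#' @param path file path.
#' @export
read_homology_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("source_gene", "target_gene") %in% names(df)))
  sp <- if ("species" %in% names(df) && nrow(df)) df$species[1] else "target"
  homology_table(df, species = sp)
}

#' @rdname homology_table
#' @param h a `homology_table`.
#' @export
write_homology_tsv <- function(h, path) {
  df <- h$pairs
  if (is.null(df$species)) df$species <- h$species
  utils::write.table(df[, c("source_gene", "species", "target_gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Universal reaction databases
#'
#' A universal reaction database is the candidate pool for gap filling: a
#' set of reactions (same equation dialect as model tables, compartment
#' suffixes optional — bare metabolite ids are instantiated in the cytosol
#' when combined with a model) with a per-reaction reversibility flag and a
#' boolean organism-evidence flag used by the solution filter. File dialect:
#' TSV with columns `id`, `equation`, `reversible`, `evidence`, `source`.
#'
#' @param df data.frame with at least `id` and `equation`; missing
#'   `reversible` defaults to the equation arrow, missing `evidence` to
#'   `TRUE`, missing `source` to `""`.
#' @return an object of class `reaction_db`: the input table plus a parsed
#'   `stoich` list (cytosol-instantiated ids).
#' @export
reaction_db <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- data.frame(id = character(0), equation = character(0),
                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "equation") %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate reaction ids in database")
  parsed <- lapply(df$equation, parse_equation)
  if (is.null(df$reversible)) df$reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  if (is.null(df$evidence)) df$evidence <- rep(TRUE, nrow(df))
  if (is.null(df$source)) df$source <- rep("", nrow(df))
  stoich <- lapply(parsed, function(p) {
    s <- p$stoich
    bare <- !grepl("\\[[a-z]\\]$", names(s))
    names(s)[bare] <- paste0(names(s)[bare], "[c]")
    s
  })
  names(stoich) <- df$id
  structure(list(rxns = df[, c("id", "equation", "reversible", "evidence", "source")],
                 stoich = stoich), class = "reaction_db")
}

#' @export
print.reaction_db <- function(x, ...) {
  cat(sprintf("<reaction_db> %d reactions (%d reversible, %d with organism evidence)\n",
              nrow(x$rxns), sum(x$rxns$reversible), sum(x$rxns$evidence)))
  invisible(x)
}

#' @rdname reaction_db
#' @param path file path.
#' @export
read_reaction_db_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$reversible <- as.logical(df$reversible)
  df$evidence <- as.logical(df$evidence)
  reaction_db(df)
}

#' @rdname reaction_db
#' @param db a `reaction_db`.
#' @export
write_reaction_db_tsv <- function(db, path) {
  utils::write.table(db$rxns, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validation-test batteries
#'
#' A battery is a table of FBA producibility tests: each test applies a
#' medium, maximizes a demand objective (auto-created for a target
#' metabolite) and passes when the achieved flux reaches the threshold.
#' File dialect: TSV with columns `id`, `description`, `target` (metabolite
#' id or reaction id), `medium` (medium label resolved against a medium
#' library), `compartment_specific` (0/1), `threshold`.
#'
#' @param df data.frame as above; `description` defaults to the id,
#'   `compartment_specific` to `FALSE`, `threshold` to `1e-6`.
#' @return data.frame of class `validation_battery`.
#' @export
validation_battery <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- data.frame(id = character(0), target = character(0),
                     medium = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "target", "medium") %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate test ids")
  if (is.null(df$description)) df$description <- df$id
  if (is.null(df$compartment_specific)) df$compartment_specific <- FALSE
  df$compartment_specific <- as.logical(df$compartment_specific)
  if (is.null(df$threshold)) df$threshold <- 1e-6
  if (any(df$threshold <= 0)) stop("test thresholds must be positive")
  class(df) <- c("validation_battery", "data.frame")
  df
}

#' @rdname validation_battery
#' @param path file path.
#' @export
read_battery_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validation_battery(df)
}

#' @rdname validation_battery
#' @param battery a `validation_battery`.
#' @export
write_battery_tsv <- function(battery, path) {
  utils::write.table(as.data.frame(battery), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
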