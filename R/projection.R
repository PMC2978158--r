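#' Project a source reconstruction onto a target species
#'
#' Builds a draft reconstruction of a target species from a source model
#' and a gene homology table. A source gene counts as "present" in the
#' target when it has at least one homolog; each reaction's GPR rule is
#' evaluated against that gene set, so a reaction survives when isozymes
#' cover the loss and is removed only when no remaining gene combination
#' can catalyse it.
#'
#' Two retention policies are provided:
#' * approach `"A"` keeps every non-gene-associated reaction, removing
#'   only gene-associated reactions whose GPR fails;
#' * approach `"B"` additionally removes non-gene-associated reactions in
#'   metabolic pathways, keeping only transport, demand, sink, exchange
#'   and biomass reactions among them.
#'
#' Model B's reaction set is therefore always a subset of model A's.
#' Retained GPRs are rewritten into the target gene namespace with
#' [translate_gpr()].
#'
#' @param source a [metabolic_model()].
#' @param homology a [homology_table()].
#' @param approach `"A"` or `"B"`.
#' @return list with `model` (the projected [metabolic_model()]) and
#'   `report` (a `projection_report`: retained/removed ids, per-category
#'   counts, gene and reaction mapping ratios).
#' @export
project_model <- function(source, homology, approach = c("A", "B")) {
  approach <- match.arg(approach)
  stopifnot(inherits(homology, "homology_table"))
  mapped <- names(homology$map)[vapply(homology$map, length, integer(1)) > 0]
  mapped <- intersect(source$genes$id, mapped)

  gene_assoc <- nzchar(source$rxns$gpr)
  keep <- logical(nrow(source$rxns))
  for (j in seq_len(nrow(source$rxns))) {
    if (gene_assoc[j]) {
      keep[j] <- evaluate_gpr(source$gprs[[j]], mapped)
    } else if (approach == "A") {
      keep[j] <- TRUE
    } else {
      keep[j] <- source$rxns$kind[j] %in% c("transport", "demand", "sink",
                                            "exchange", "biomass")
    }
  }

  retained <- source$rxns$id[keep]
  removed <- source$rxns$id[!keep]

  model <- subset_reactions(source, retained, prune_mets = TRUE, prune_genes = FALSE)
  # rewrite GPRs into the target namespace
  new_gpr <- vapply(model$rxns$id, function(r) {
    tr <- translate_gpr(source$gprs[[match(r, source$rxns$id)]], homology)
    if (is_gpr_false(tr)) stop("internal: retained reaction translates to false: ", r)
    gpr_to_string(tr)
  }, character(1))
  target_genes <- sort(unique(unlist(lapply(new_gpr, function(g) gpr_genes(parse_gpr(g))))))
  rxns <- model$rxns
  rxns$gpr <- unname(new_gpr)
  model <- metabolic_model(
    genes = data.frame(id = target_genes, stringsAsFactors = FALSE),
    mets = model$mets, rxns = rxns, S = model$S,
    objective = model$objective,
    id = paste0(source$id, "_", homology$species, "_", approach))

  by_cat <- table(factor(source$rxns$kind[keep],
                         levels = sort(unique(source$rxns$kind))))
  report <- structure(list(
    approach = approach,
    species = homology$species,
    retained = retained,
    removed = removed,
    counts = as.list(by_cat),
    gene_ratio = if (nrow(source$genes)) length(mapped) / nrow(source$genes) else 1,
    reaction_ratio = length(retained) / nrow(source$rxns),
    n_source_genes = nrow(source$genes),
    n_mapped_genes = length(mapped)
  ), class = "projection_report")
  list(model = model, report = report)
}

#' @rdname project_model
#' @export
project_model_A <- function(source, homology) project_model(source, homology, "A")

#' @rdname project_model
#' @export
project_model_B <- function(source, homology) project_model(source, homology, "B")

#' @export
print.projection_report <- function(x, ...) {
  cat(sprintf("<projection_report> approach %s -> %s\n", x$approach, x$species))
  cat(sprintf("  genes mapped: %d/%d (%.1f%%)\n", x$n_mapped_genes,
              x$n_source_genes, 100 * x$gene_ratio))
  cat(sprintf("  reactions retained: %d (%.1f%%), removed: %d\n",
              length(x$retained), 100 * x$reaction_ratio, length(x$removed)))
  invisible(x)
}

#' Write a projection report summary as TSV
#'
#' One row per reaction category retained, plus the gene/reaction mapping
#' ratios.
#'
#' @param report a `projection_report`.
#' @param path file path.
#' @export
write_projection_tsv <- function(report, path) {
  df <- data.frame(
    quantity = c(paste0("retained_", names(report$counts)),
                 "retained_total", "removed_total", "gene_ratio", "reaction_ratio"),
    value = c(unlist(report$counts), length(report$retained),
              length(report$removed), report$gene_ratio, report$reaction_ratio))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
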