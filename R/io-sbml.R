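#' Read and write models in SBML
#'
#' Writes SBML Level 2 in the classic constraint-based dialect: flux bounds
#' as `LOWER_BOUND` / `UPPER_BOUND` kinetic-law parameters and GPR /
#' subsystem annotations as `GENE_ASSOCIATION:` / `SUBSYSTEM:` lines in the
#' reaction notes, with species ids of the form `M_<base>_<comp>` and
#' reaction ids prefixed `R_`. On read the dialect is auto-detected: the
#' notes fields are used when present, and models written in the `fbc`
#' package style (bound parameters referenced through
#' `fbc:lowerFluxBound` / `fbc:upperFluxBound` and gene products in
#' `fbc:geneProductAssociation`) are also understood. The objective is
#' taken from the `OBJECTIVE_COEFFICIENT` parameter (notes dialect) or the
#' active fbc objective.
#'
#' `read_model_sbml(write_model_sbml(m))` preserves structure: ids,
#' stoichiometries, bounds, GPR truth tables and subsystems.
#'
#' @param path file path.
#' @param id model label; defaults to the SBML model id.
#' @return `read_model_sbml()`: a [metabolic_model()].
#' @export
read_model_sbml <- function(path, id = NULL) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)
  if (is.null(id)) {
    id <- xml2::xml_attr(model_node, "id")
    if (is.na(id)) id <- basename(path)
  }
  fbc <- any(grepl("/fbc/", unlist(xml2::xml_ns(doc))))

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp_nodes) == 0L) stop("no species in ", path)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_bound <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  if (anyDuplicated(sp_id)) stop("duplicate species ids in ", path)
  base <- ifelse(!is.na(sp_name) & nzchar(sp_name), sp_name,
                 sub(paste0("_", sp_comp, "$"), "", sub("^M_", "", sp_id)))
  met_id <- paste0(base, "[", sp_comp, "]")
  keep_sp <- is.na(sp_bound) | sp_bound != "true"
  met_of_species <- stats::setNames(met_id, sp_id)

  # fbc bound parameters (value per parameter id)
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rx_nodes)
  if (n == 0L) stop("no reactions in ", path)
  rx_id <- sub("^R_", "", xml2::xml_attr(rx_nodes, "id"))
  if (anyDuplicated(rx_id)) stop("duplicate reaction ids in ", path)
  rx_name <- xml2::xml_attr(rx_nodes, "name")
  rx_name <- ifelse(is.na(rx_name), rx_id, rx_name)
  rx_rev <- xml2::xml_attr(rx_nodes, "reversible")

  lb <- ub <- rep(NA_real_, n)
  objc <- rep(0, n)
  gpr <- sub <- rep("", n)
  stoich <- vector("list", n)
  for (k in seq_len(n)) {
    node <- rx_nodes[[k]]
    refs <- function(xp, sign) {
      rr <- xml2::xml_find_all(node, xp, ns)
      if (length(rr) == 0L) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(rr, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, xml2::xml_attr(rr, "species"))
    }
    s <- c(refs("./s:listOfReactants/s:speciesReference", -1),
           refs("./s:listOfProducts/s:speciesReference", +1))
    s <- tapply(s, names(s), sum)
    s <- stats::setNames(as.numeric(s), names(s))
    # drop boundary species and map to metabolite ids
    s <- s[keep_sp[match(names(s), sp_id)]]
    names(s) <- met_of_species[names(s)]
    stoich[[k]] <- s[s != 0]

    kl_par <- xml2::xml_find_all(node, "./s:kineticLaw//s:parameter", ns)
    if (length(kl_par)) {
      pid <- xml2::xml_attr(kl_par, "id")
      pv <- as.numeric(xml2::xml_attr(kl_par, "value"))
      if ("LOWER_BOUND" %in% pid) lb[k] <- pv[match("LOWER_BOUND", pid)]
      if ("UPPER_BOUND" %in% pid) ub[k] <- pv[match("UPPER_BOUND", pid)]
      if ("OBJECTIVE_COEFFICIENT" %in% pid) objc[k] <- pv[match("OBJECTIVE_COEFFICIENT", pid)]
    }
    if (fbc && is.na(lb[k])) {
      lbref <- xml2::xml_attr(node, "lowerFluxBound")
      ubref <- xml2::xml_attr(node, "upperFluxBound")
      if (!is.na(lbref)) lb[k] <- par_val[[lbref]]
      if (!is.na(ubref)) ub[k] <- par_val[[ubref]]
    }
    notes <- xml2::xml_find_all(node, ".//s:notes//text()", ns)
    if (length(notes)) {
      txt <- xml2::xml_text(notes)
      ga <- grep("^\\s*GENE_ASSOCIATION:", txt, value = TRUE)
      if (length(ga)) gpr[k] <- trimws(sub("^\\s*GENE_ASSOCIATION:", "", ga[1]))
      ss <- grep("^\\s*SUBSYSTEM:", txt, value = TRUE)
      if (length(ss)) sub[k] <- trimws(sub("^\\s*SUBSYSTEM:", "", ss[1]))
    }
    if (fbc && !nzchar(gpr[k])) {
      gpa <- xml2::xml_find_first(node, ".//*[local-name()='geneProductAssociation']")
      if (!inherits(gpa, "xml_missing")) gpr[k] <- fbc_gpa_to_string(gpa)
    }
  }
  lb[is.na(lb)] <- ifelse(!is.na(rx_rev) & rx_rev == "true", -1000, 0)[is.na(lb)]
  ub[is.na(ub)] <- 1000

  objective <- NA_character_
  if (any(objc != 0)) {
    objective <- rx_id[which(objc != 0)[1]]
  } else if (fbc) {
    fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(fo, "xml_missing")) {
      ref <- xml2::xml_attr(fo, "reaction")
      objective <- sub("^R_", "", ref)
    }
  }

  met_ids <- sort(unique(unlist(lapply(stoich, names))))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_len(n)) {
    s <- stoich[[k]]
    if (length(s) == 0L) stop("reaction with empty stoichiometry in ", path, ": ", rx_id[k])
    ii <- c(ii, match(names(s), met_ids))
    jj <- c(jj, rep(k, length(s)))
    xx <- c(xx, unname(s))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(length(met_ids), n))
  genes <- sort(unique(unlist(lapply(gpr, function(g) gpr_genes(parse_gpr(g))))))
  metabolic_model(
    genes = data.frame(id = genes, stringsAsFactors = FALSE),
    mets = data.frame(id = met_ids, stringsAsFactors = FALSE),
    rxns = data.frame(id = rx_id, name = rx_name, lb = lb, ub = ub, gpr = gpr,
                      subsystem = sub, stringsAsFactors = FALSE),
    S = S, objective = objective, id = id)
}

fbc_gpa_to_string <- function(node) {
  lname <- xml2::xml_name(node)
  if (lname == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(sub("^G_", "", g))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbc_gpa_to_string, character(1))
  parts <- parts[nzchar(parts)]
  if (lname == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
  if (lname == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
  if (length(parts) == 1L) return(parts)
  paste(parts, collapse = " ")
}

sbml_sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' @rdname read_model_sbml
#' @param model a [metabolic_model()].
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  comps <- sort(unique(model$mets$comp))
  sp_id <- paste0("M_", sbml_sanitize(model$mets$base), "_", model$mets$comp)
  if (anyDuplicated(sp_id)) {
    dup <- duplicated(sp_id) | duplicated(sp_id, fromLast = TRUE)
    sp_id[dup] <- paste0(sp_id[dup], "_", seq_len(sum(dup)))
  }
  sp_of_met <- stats::setNames(sp_id, model$mets$id)

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    sprintf('  <model id="%s" name="%s">', sbml_sanitize(model$id), esc(model$id)),
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s"/>', comps),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf('      <species id="%s" name="%s" compartment="%s"/>',
            sp_id, esc(model$mets$base), model$mets$comp),
    "    </listOfSpecies>",
    "    <listOfReactions>")
  for (j in seq_len(nrow(model$rxns))) {
    col <- model$S[, j]
    s <- col[col != 0]
    rev <- model$rxns$lb[j] < 0
    lines <- sprintf('      <reaction id="R_%s" name="%s" reversible="%s">',
                     sbml_sanitize(model$rxns$id[j]), esc(model$rxns$name[j]),
                     if (rev) "true" else "false")
    notes <- c(sprintf("GENE_ASSOCIATION: %s", esc(model$rxns$gpr[j])),
               sprintf("SUBSYSTEM: %s", esc(model$rxns$subsystem[j])),
               sprintf("ABBREVIATION: %s", esc(model$rxns$id[j])))
    lines <- c(lines, "        <notes>",
               '          <body xmlns="http://www.w3.org/1999/xhtml">',
               sprintf("            <p>%s</p>", notes),
               "          </body>", "        </notes>")
    subs <- s[s < 0]; prods <- s[s > 0]
    if (length(subs)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%g"/>',
                         sp_of_met[names(subs)], abs(subs)),
                 "        </listOfReactants>")
    }
    if (length(prods)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%g"/>',
                         sp_of_met[names(prods)], prods),
                 "        </listOfProducts>")
    }
    objc <- if (!is.na(model$objective) && model$rxns$id[j] == model$objective) 1 else 0
    lines <- c(lines,
               "        <kineticLaw>",
               "          <math xmlns=\"http://www.w3.org/1998/Math/MathML\"><ci>FLUX_VALUE</ci></math>",
               "          <listOfParameters>",
               sprintf('            <parameter id="LOWER_BOUND" value="%.10g" units="mmol_per_gDW_per_hr"/>',
                       model$rxns$lb[j]),
               sprintf('            <parameter id="UPPER_BOUND" value="%.10g" units="mmol_per_gDW_per_hr"/>',
                       model$rxns$ub[j]),
               sprintf('            <parameter id="OBJECTIVE_COEFFICIENT" value="%g"/>', objc),
               "          </listOfParameters>",
               "        </kineticLaw>",
               "      </reaction>")
    out <- c(out, lines)
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

#' Read a model from either supported format
#'
#' @param path file path.
#' @param format `"sbml"`, `"tsv"`, or `"auto"` (by file extension, with
#'   `.xml`/`.sbml` as SBML).
#' @param ... passed to the format-specific reader.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "sbml", "tsv"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  }
  switch(format, sbml = read_model_sbml(path, ...), tsv = read_model_tsv(path, ...))
}

#' @rdname read_model
#' @param model a [metabolic_model()].
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  }
  switch(format, sbml = write_model_sbml(model, path), tsv = write_model_tsv(model, path))
}
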