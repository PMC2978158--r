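#' Run the reconstruction pipeline end to end
#'
#' Orchestrates the full workflow with one reproducible configuration:
#' generate (or read) a source model, project it onto the target species
#' (approach A or B, optionally compartment-collapsed), check biomass
#' producibility, gap fill when broken, run the validation battery with
#' iterative curation, screen gene essentiality, and analyse requested
#' knockouts. All stage outputs are written beneath the run directory
#' (`models/`, `reports/`, `logs/`) in the package's file dialects; every
#' report is reproducible from the config and its seed.
#'
#' The configuration is a named list (or a YAML file with the same keys):
#' \describe{
#'   \item{source}{path to a source model (TSV/SBML), or `"synthetic"`
#'     (default) to generate one.}
#'   \item{synthetic}{list of [synthetic_spec()] arguments (used when
#'     `source = "synthetic"`).}
#'   \item{homology}{path to a homology TSV, or a retention rate in
#'     \[0, 1\] for a generated table (default 1.0).}
#'   \item{approach}{`"A"` (default) or `"B"`.}
#'   \item{collapse}{merge intracellular compartments (default `FALSE`).}
#'   \item{gapfill}{list: `enabled` (default `TRUE`: gap fill when biomass
#'     is not producible), `n_iter`, `epsilon`, `big_M`, `db` (path to a
#'     universal db TSV; default: generated around the projection's
#'     removed reactions).}
#'   \item{validate}{run the battery + curation loop (default `TRUE`).}
#'   \item{essentiality}{list: `enabled` (default `TRUE`), `medium`
#'     (medium name, default `"rich"`), `threshold`.}
#'   \item{knockouts}{character vector of genes for knockout FVA shift
#'     analysis (default none).}
#'   \item{alpha, k}{shift-test significance settings (defaults 0.05, 10).}
#'   \item{seed}{root seed for every stage (default 1).}
#' }
#'
#' @param config named list or path to a YAML file.
#' @param run_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list of stage summaries: projection report,
#'   biomass optima, gap-fill report, validation outcome, essentiality
#'   screen, knockout shift tables, plus all output paths.
#' @export
run_pipeline <- function(config = list(), run_dir = tempfile("ofxrun"),
                         quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    source = "synthetic", synthetic = list(), homology = 1.0,
    approach = "A", collapse = FALSE,
    gapfill = list(), validate = TRUE, essentiality = list(),
    knockouts = character(0), alpha = 0.05, k = 10, seed = 1
  ), as.list(config))
  cfg$gapfill <- utils::modifyList(
    list(enabled = TRUE, n_iter = 5L, epsilon = 1, big_M = 1000, db = NULL),
    as.list(cfg$gapfill))
  cfg$essentiality <- utils::modifyList(
    list(enabled = TRUE, medium = "rich", threshold = 1e-6),
    as.list(cfg$essentiality))

  dir.create(file.path(run_dir, "models"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(run_dir, "reports"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(run_dir, "logs"), recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "logs", "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    if (!quiet) message(line)
  }
  out <- list(run_dir = run_dir, config = cfg)
  logf("seed: %d", cfg$seed)

  # --- source model -------------------------------------------------------
  gen <- NULL
  if (identical(cfg$source, "synthetic")) {
    spec <- do.call(synthetic_spec,
                    utils::modifyList(list(seed = cfg$seed), cfg$synthetic))
    gen <- generate_source_model(spec)
    source_model <- gen$model
    media <- gen$media
    logf("stage generate: %d reactions, %d metabolites, %d genes",
         nrow(source_model$rxns), nrow(source_model$mets), nrow(source_model$genes))
  } else {
    source_model <- read_model(cfg$source)
    media <- list()
    logf("stage read: %s (%d reactions)", cfg$source, nrow(source_model$rxns))
  }
  write_model_tsv(source_model, file.path(run_dir, "models", "source.tsv"))

  # --- projection ---------------------------------------------------------
  h <- if (is.character(cfg$homology)) read_homology_tsv(cfg$homology)
       else generate_homology_table(source_model, rate = cfg$homology,
                                    seed = cfg$seed)
  proj <- project_model(source_model, h, approach = cfg$approach)
  model <- proj$model
  logf("stage project (%s): retained %d / removed %d reactions, gene ratio %.3f",
       cfg$approach, length(proj$report$retained), length(proj$report$removed),
       proj$report$gene_ratio)
  write_projection_tsv(proj$report, file.path(run_dir, "reports", "projection.tsv"))
  out$projection <- proj$report

  if (isTRUE(cfg$collapse)) {
    model <- decompartmentalize(model)
    logf("stage collapse: %d reactions, %d metabolites",
         nrow(model$rxns), nrow(model$mets))
  }
  write_model_tsv(model, file.path(run_dir, "models", "draft.tsv"))

  # --- biomass check + gap fill ------------------------------------------
  rich <- if ("rich" %in% names(media)) media$rich else NULL
  fba <- solve_fba(apply_medium(model, rich))
  out$draft_biomass <- fba$objective_value
  logf("stage biomass-check: status %s, optimum %.6g", fba$status,
       fba$objective_value)
  if (cfg$gapfill$enabled &&
      (fba$status != "optimal" || fba$objective_value < cfg$gapfill$epsilon)) {
    db <- if (!is.null(cfg$gapfill$db)) read_reaction_db_tsv(cfg$gapfill$db)
          else generate_universal_db(source_model, proj$report$removed,
                                     seed = cfg$seed)
    gf <- gapfill(apply_medium(model, rich), db,
                  n_iter = cfg$gapfill$n_iter, epsilon = cfg$gapfill$epsilon,
                  big_M = cfg$gapfill$big_M)
    gf <- filter_solutions(gf, model, db)
    write_gapfill_tsv(gf, file.path(run_dir, "reports", "gapfill.tsv"))
    acc <- which(gf$verdicts$accepted)
    if (length(acc)) {
      model <- apply_gapfill(model, db, gf$solutions[[acc[1]]]$added,
                             big_M = cfg$gapfill$big_M)
      logf("stage gapfill: %d solution(s), applied {%s}", length(gf$solutions),
           paste(gf$solutions[[acc[1]]]$added, collapse = ", "))
    } else {
      logf("stage gapfill: %d solution(s), none accepted", length(gf$solutions))
    }
    out$gapfill <- gf
    out$post_gapfill_biomass <- solve_fba(apply_medium(model, rich))$objective_value
  }

  # --- validation + curation ---------------------------------------------
  if (isTRUE(cfg$validate) && !is.null(gen)) {
    bat <- generate_test_battery(gen)
    cur <- curate_model(model, bat$battery, bat$media, source_model,
                        proj$report$removed)
    model <- cur$model
    write_battery_tsv(bat$battery, file.path(run_dir, "reports", "battery.tsv"))
    utils::write.table(as.data.frame(cur$outcome),
                       file.path(run_dir, "reports", "validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("stage validate: pass fraction %.3f (restored %d reactions, %d unresolved)",
         pass_fraction(cur$outcome), length(cur$restored), length(cur$unresolved))
    out$validation <- cur
  }
  write_model_tsv(model, file.path(run_dir, "models", "final.tsv"))
  write_model_sbml(model, file.path(run_dir, "models", "final.xml"))

  # --- essentiality -------------------------------------------------------
  if (cfg$essentiality$enabled) {
    med <- media[[cfg$essentiality$medium]]
    scr <- essentiality_screen(model, medium = med,
                               threshold = cfg$essentiality$threshold)
    write_screen_tsv(scr, file.path(run_dir, "reports", "essentiality.tsv"))
    logf("stage essentiality: %d / %d genes essential", sum(scr$essential),
         nrow(scr))
    out$essentiality <- scr
  }

  # --- knockout shift analyses -------------------------------------------
  if (length(cfg$knockouts)) {
    med <- media[[cfg$essentiality$medium]]
    out$knockouts <- list()
    for (g in cfg$knockouts) {
      kp <- knockout_phenotype(model, med, g, alpha = cfg$alpha, k = cfg$k)
      utils::write.table(as.data.frame(kp$shift),
                         file.path(run_dir, "reports",
                                   sprintf("knockout_%s.tsv", g)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("stage knockout %s: %d reactions disabled, %d significant subsystems",
           g, length(kp$disabled), sum(kp$shift$significant))
      out$knockouts[[g]] <- kp$shift
    }
  }
  logf("done")
  invisible(out)
}
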