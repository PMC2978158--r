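#' Compare wild-type and knockout FVA results
#'
#' Classifies each reaction's flux-capacity change from the shift in its
#' maximal attainable flux (`v_max`): `decreased` when `v_max` dropped by
#' more than the tolerance, `increased` when it rose by more, `unchanged`
#' otherwise. The tolerance is relative with an absolute floor so that LP
#' round-off cannot create spurious counts. Both results must cover the
#' same reaction universe (knockout-disabled reactions appear with range
#' (0, 0)).
#'
#' @param wt,ko [run_fva()] results on the same reaction set.
#' @param tol_rel relative no-change tolerance (default `1e-6`).
#' @param tol_abs absolute no-change floor (default `1e-9`).
#' @param use_range classify on the full range width
#'   (`(max - min)`) instead of `v_max` alone; non-default variant.
#' @return data.frame of class `capacity_changes`: `reaction`, `wt_max`,
#'   `ko_max`, `delta`, `status`, `subsystem`.
#' @export
compare_fva <- function(wt, ko, tol_rel = 1e-6, tol_abs = 1e-9,
                        use_range = FALSE) {
  if (!setequal(wt$reaction, ko$reaction)) {
    stop("wild-type and knockout FVA cover different reaction sets")
  }
  ko <- ko[match(wt$reaction, ko$reaction), , drop = FALSE]
  a <- if (use_range) wt$max - wt$min else wt$max
  b <- if (use_range) ko$max - ko$min else ko$max
  delta <- b - a
  tol <- pmax(tol_abs, tol_rel * pmax(abs(a), abs(b)))
  status <- ifelse(delta < -tol, "decreased",
                   ifelse(delta > tol, "increased", "unchanged"))
  out <- data.frame(reaction = wt$reaction, wt_max = a, ko_max = b,
                    delta = delta, status = status,
                    subsystem = wt$subsystem, stringsAsFactors = FALSE)
  class(out) <- c("capacity_changes", "data.frame")
  out
}

#' Chi-square test of down/up counts against even probability
#'
#' The single-value goodness-of-fit statistic with 1 degree of freedom for
#' observed counts of decreased and increased flux capacity against equal
#' expected counts `E = (n_down + n_up) / 2`:
#' `X^2 = (n_down - E)^2/E + (n_up - E)^2/E`, with the upper-tail p-value
#' of the chi-square distribution with 1 df and no continuity correction.
#' Zero total counts give statistic 0 and p = 1.
#'
#' @param n_down,n_up non-negative counts (vectorized).
#' @return list with `statistic` and `p_value` (vectors when the inputs
#'   are).
#' @examples
#' chi_square_even(85, 133)$p_value  # 0.00115
#' chi_square_even(48, 48)$p_value   # 1
#' @export
chi_square_even <- function(n_down, n_up) {
  if (any(n_down < 0) || any(n_up < 0)) stop("counts must be non-negative")
  total <- n_down + n_up
  E <- total / 2
  stat <- ifelse(total == 0, 0, (n_down - E)^2 / E + (n_up - E)^2 / E)
  p <- ifelse(total == 0, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  list(statistic = unname(stat), p_value = unname(p))
}

#' Per-subsystem flux-capacity shift test
#'
#' Counts the decreased and increased reactions per major subsystem
#' (`unchanged` reactions and reactions with no or an `unassigned`
#' subsystem are excluded) and applies [chi_square_even()] to each, with
#' Bonferroni-style significance at `alpha / k` for the `k` independent
#' subsystem tests.
#'
#' @param changes a [compare_fva()] result, or any data.frame with
#'   `status` and `subsystem` columns.
#' @param subsystems optional named character vector mapping reaction id
#'   to major subsystem, overriding the `subsystem` column.
#' @param alpha family-wise significance level (default 0.05).
#' @param k number of independent tests for the correction (default 10,
#'   the number of major subsystems).
#' @return data.frame of class `subsystem_shift`: `subsystem`, `n_down`,
#'   `n_up`, `statistic`, `p_value`, `significant`.
#' @export
subsystem_shift_test <- function(changes, subsystems = NULL, alpha = 0.05,
                                 k = 10) {
  df <- as.data.frame(changes)
  if (!is.null(subsystems)) {
    df$subsystem <- unname(subsystems[df$reaction])
  }
  df <- df[!is.na(df$subsystem) & nzchar(df$subsystem) &
             df$subsystem != "unassigned", , drop = FALSE]
  subs <- sort(unique(df$subsystem))
  n_down <- vapply(subs, function(s)
    sum(df$subsystem == s & df$status == "decreased"), integer(1))
  n_up <- vapply(subs, function(s)
    sum(df$subsystem == s & df$status == "increased"), integer(1))
  cs <- chi_square_even(n_down, n_up)
  out <- data.frame(subsystem = subs, n_down = n_down, n_up = n_up,
                    statistic = cs$statistic, p_value = cs$p_value,
                    significant = cs$p_value < alpha / k,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "k") <- k
  class(out) <- c("subsystem_shift", "data.frame")
  out
}

#' Count significant metabolism subsections
#'
#' Summarizes a shift-test table as the number of significantly shifted
#' major subsections of metabolism. The `Transporters` subsystem is not a
#' metabolism subsection and is excluded from the count by default.
#'
#' @param shift a [subsystem_shift_test()] result.
#' @param exclude subsystem labels excluded from the count.
#' @return integer count.
#' @export
count_significant_subsections <- function(shift, exclude = "Transporters") {
  sum(shift$significant & !shift$subsystem %in% exclude)
}

#' Knockout phenotype analysis
#'
#' Composes the knockout pipeline: delete the gene, run FVA on wild type
#' and knockout under the same medium, classify per-reaction flux-capacity
#' changes and test each major subsystem for a significant shift. A gene
#' whose deletion disables no reaction is a fixed point: all reactions
#' unchanged, no significant subsystem.
#'
#' @param model a [metabolic_model()].
#' @param medium [medium_condition()] applied to both models (e.g. a
#'   minimal growth medium), or `NULL` to use the model's bounds as-is.
#' @param gene gene id to knock out.
#' @param fraction FVA objective fraction (see [run_fva()]).
#' @param alpha,k significance settings (see [subsystem_shift_test()]).
#' @param ... passed to [compare_fva()].
#' @return list with `changes` (a [compare_fva()] table), `shift`
#'   (a [subsystem_shift_test()] table), `disabled` reaction ids and the
#'   two `fva` results.
#' @export
knockout_phenotype <- function(model, medium, gene, fraction = 1.0,
                               alpha = 0.05, k = 10, ...) {
  model <- apply_medium(model, medium)
  ko <- delete_gene(model, gene)
  wt_fva <- run_fva(model, fraction = fraction)
  ko_fva <- run_fva(ko, fraction = fraction)
  changes <- compare_fva(wt_fva, ko_fva, ...)
  shift <- subsystem_shift_test(changes, alpha = alpha, k = k)
  list(changes = changes, shift = shift, disabled = attr(ko, "disabled"),
       wt_fva = wt_fva, ko_fva = ko_fva)
}

#' Binary activity profile from an FVA result
#'
#' @param fva a [run_fva()] result.
#' @param tol activity tolerance (see [count_active()]).
#' @return named logical vector: reaction active (can carry non-zero
#'   flux) or not.
#' @export
activity_profile <- function(fva, tol = 1e-6) {
  stats::setNames(pmax(abs(fva$min), abs(fva$max)) > tol, fva$reaction)
}

#' Distance tree over FVA activity profiles
#'
#' Builds a tree relating models by the similarity of their FVA activity
#' profiles: pairwise Jaccard distances on the active reaction sets over
#' the shared universe (a reaction missing from a profile counts as
#' inactive), then agglomerative clustering (average linkage by default)
#' rendered as a phylogenetic tree with branch lengths. Profile order is
#' normalized by label so ties break deterministically.
#'
#' @param profiles named list of logical activity vectors
#'   (see [activity_profile()]); at least 3.
#' @param linkage hclust agglomeration method.
#' @return an [ape::as.phylo()] tree; write with [ape::write.tree()].
#' @export
fva_distance_tree <- function(profiles, linkage = "average") {
  if (length(profiles) < 3L) stop("need at least 3 profiles for a tree")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("profiles must be named")
  }
  profiles <- profiles[order(names(profiles))]
  universe <- sort(unique(unlist(lapply(profiles, names))))
  mat <- vapply(profiles, function(p) {
    v <- stats::setNames(rep(FALSE, length(universe)), universe)
    v[names(p)[p]] <- TRUE
    v
  }, logical(length(universe)))
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- sum(mat[, i] & mat[, j])
    uni <- sum(mat[, i] | mat[, j])
    d[i, j] <- d[j, i] <- if (uni == 0) 0 else 1 - inter / uni
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  ape::as.phylo(hc)
}
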