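#' Curated literature phenotypes for predicted-essential mouse genes
#'
#' The 17 genes predicted essential by the curated mouse genome-scale
#' model for which a homozygous-knockout phenotype has been described in
#' the literature, with the metabolic subgroup of their reactions and
#' whether the knockout is lethal in vivo. Shipped as packaged data so the
#' in-silico/in-vivo agreement (the lethal fraction) can be recomputed.
#'
#' @return data.frame with columns `gene`, `enzyme`, `subgroup`, `lethal`
#'   (`"yes"`/`"no"`).
#' @examples
#' tab <- ko_phenotype_literature()
#' mean(tab$lethal == "yes")  # lethal fraction among predicted-essential
#' @export
ko_phenotype_literature <- function() {
  utils::read.delim(system.file("extdata", "mouse_ko_literature.tsv",
                                package = "orthoflux"),
                    stringsAsFactors = FALSE)
}

#' Published per-subsystem flux-capacity shift counts
#'
#' Down/up reaction counts per major subsystem from knockout-vs-wild-type
#' FVA comparisons of the curated mouse model, for the knockouts PGM1,
#' FUT9, SORD, DHCR7 (all ten major subsystems) and LPL (the two printed
#' subsystems). The `printed_p` column carries the originally reported
#' p-value string; the chi-square statistic and p-value are recomputed
#' from the counts with [chi_square_even()].
#'
#' @return data.frame with columns `knockout`, `subsystem`, `n_down`,
#'   `n_up`, `printed_p`.
#' @examples
#' counts <- published_shift_counts()
#' fut9 <- counts[counts$knockout == "FUT9" &
#'                counts$subsystem == "Amino Acid Metabolism", ]
#' chi_square_even(fut9$n_down, fut9$n_up)$p_value
#' @export
published_shift_counts <- function() {
  utils::read.delim(system.file("extdata", "published_shift_counts.tsv",
                                package = "orthoflux"),
                    stringsAsFactors = FALSE)
}

#' Recompute the shift tests for a published knockout
#'
#' Applies [chi_square_even()] and the significance convention to the
#' packaged [published_shift_counts()] of one knockout.
#'
#' @param knockout knockout label present in the packaged table.
#' @param alpha,k significance settings (defaults 0.05 and 10: ten major
#'   subsystems tested independently).
#' @return a `subsystem_shift` data.frame (see [subsystem_shift_test()]).
#' @export
published_knockout_shift <- function(knockout, alpha = 0.05, k = 10) {
  counts <- published_shift_counts()
  counts <- counts[counts$knockout == knockout, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no packaged counts for knockout: ", knockout)
  cs <- chi_square_even(counts$n_down, counts$n_up)
  out <- data.frame(subsystem = counts$subsystem,
                    n_down = counts$n_down, n_up = counts$n_up,
                    statistic = cs$statistic, p_value = cs$p_value,
                    significant = cs$p_value < alpha / k,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "k") <- k
  class(out) <- c("subsystem_shift", "data.frame")
  out
}
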