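#' Delimitation configuration
#'
#' Collects every threshold the pipeline applies.  Defaults mirror common
#' practice for a slow/medium ribosomal + fast coding three-locus design:
#' coverage at half the alignment length, inclusive 2x relative distance
#' threshold, parsimony connection limits of 98\% for the two ribosomal-like
#' loci and 90\% for the fast locus, bootstrap/posterior support cutoffs of
#' 70/0.95, and at least two concordant loci with three specimens for a
#' describable species.
#'
#' @param min_fraction coverage filter threshold ([coverage_filter()]).
#' @param ratio relative distance threshold (inclusive).
#' @param connection_limits numeric vector of per-locus parsimony probability
#'   limits, recycled in locus order (names, when given, match locus names).
#' @param bootstrap_threshold,posterior_threshold tree support cutoffs.
#' @param min_concordant_loci loci that must recover the clade.
#' @param min_separate_loci loci in which the clade must be network-separate.
#' @param min_specimens below three specimens a clade is never described.
#' @param allow_unvalidated promote clades lacking an external multilocus
#'   validation result (default \code{TRUE}: well-supported clades may be
#'   described without one).
#' @param validation_threshold,validation_min_analyses a clade is validated
#'   when at least \code{validation_min_analyses} posterior probabilities
#'   reach \code{validation_threshold}.
#' @param all_trees require every tree of a locus to pass (default: any).
#' @param discovery_locus locus (name or index) used for de novo discovery.
#' @param ambiguity,missing_matches comparison policies, see
#'   [pairwise_p_distance()] and [collapse_haplotypes()].
#' @return a named list of class \code{delim_config}.
#' @export
delim_config <- function(min_fraction = 0.5,
                         ratio = 2,
                         connection_limits = c(0.98, 0.98, 0.90),
                         bootstrap_threshold = 70,
                         posterior_threshold = 0.95,
                         min_concordant_loci = 2,
                         min_separate_loci = 1,
                         min_specimens = 3,
                         allow_unvalidated = TRUE,
                         validation_threshold = 0.95,
                         validation_min_analyses = 2,
                         all_trees = FALSE,
                         discovery_locus = 1,
                         ambiguity = "overlap",
                         missing_matches = TRUE) {
  stopifnot(ratio > 0, min_fraction > 0, min_fraction <= 1,
            all(connection_limits > 0 & connection_limits < 1))
  structure(as.list(environment()), class = "delim_config")
}

#' Evaluate one clade against all evidence streams
#'
#' Applies the combined decision rule to a per-clade evidence summary.  A
#' clade is a \code{described_candidate} when it has at least
#' \code{min_specimens} specimens, is concordantly recovered in at least
#' \code{min_concordant_loci} gene trees, passes the relative distance
#' threshold in at least one locus, is network-separate in at least
#' \code{min_separate_loci} loci, is validated (or untested with
#' \code{allow_unvalidated}), and carries no veto.  Clades with two or fewer
#' specimens are always plain \code{candidate}s (too poorly known for formal
#' description), as are clades whose concordance could not be assessed at
#' all or that carry a veto; everything else is \code{unresolved}.
#'
#' @param evidence a one-row list or tibble with elements \code{clade},
#'   \code{n_specimens}, \code{distance_pass_loci} (count),
#'   \code{separate_loci} (count), \code{concordant_loci} (count),
#'   \code{assessable_loci} (count of loci with an assessable tree),
#'   \code{validated} (\code{"yes"}, \code{"no"} or \code{"untested"}) and
#'   optional \code{veto} (character, \code{""}/\code{NA} = none).
#' @param config a [delim_config()].
#' @return the evidence row as a tibble with an added \code{status} column.
#' @export
evaluate_clade <- function(evidence, config = delim_config()) {
  ev <- tibble::as_tibble(evidence)
  stopifnot(nrow(ev) == 1L)
  veto <- !is.null(ev$veto) && !is.na(ev$veto[1]) && nzchar(ev$veto[1])
  validated_ok <- ev$validated == "yes" ||
    (ev$validated == "untested" && config$allow_unvalidated)
  status <- if (veto) {
    "candidate"
  } else if (ev$n_specimens <= 2 || ev$n_specimens < config$min_specimens) {
    "candidate"
  } else if (ev$assessable_loci == 0) {
    "candidate"   # concordance not assessable: evidence insufficient
  } else if (ev$concordant_loci >= config$min_concordant_loci &&
             ev$distance_pass_loci >= 1 &&
             ev$separate_loci >= config$min_separate_loci &&
             validated_ok) {
    "described_candidate"
  } else {
    "unresolved"
  }
  ev$status <- status
  ev
}

# "yes" / "no" / "untested" from up to three posterior probabilities
validation_status <- function(pp, threshold, min_analyses) {
  pp <- pp[!is.na(pp)]
  if (!length(pp)) return("untested")
  if (sum(pp >= threshold) >= min_analyses) "yes" else "no"
}

#' Read an external validation table
#'
#' A TSV with columns \code{clade} and up to three per-analysis posterior
#' probabilities (\code{pp_prior1 pp_prior2 pp_prior3}), typically from a
#' multilocus Bayesian validation run under different prior settings.
#'
#' @param path path to the TSV.
#' @return tibble with a \code{clade} column and numeric \code{pp_} columns.
#' @export
read_validation_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    clade = readr::col_character(), .default = readr::col_double()))
  if (!"clade" %in% names(tb)) stop("validation table needs a 'clade' column")
  tb
}

# format helpers for the evidence table (percentages to one decimal)
fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", 100 * x))
fmt_dist_cell <- function(inter, intra) {
  ifelse(is.na(inter) & is.na(intra), "-",
         paste0(fmt_pct(inter), "/", fmt_pct(intra)))
}
fmt_net_cell <- function(sep) {
  dplyr::case_when(
    !sep$has_data ~ "-",
    sep$is_separate & sep$n_networks_spanned == 1L ~ "yes",
    sep$is_separate ~ "yes*",
    TRUE ~ as.character(sep$min_steps_to_nonmember)
  )
}
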