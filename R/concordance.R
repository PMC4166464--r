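#' Assess a clade in a single gene tree
#'
#' Monophyly is evaluated on the leaf set of this tree: clade members absent
#' from the tree are ignored (per-gene sampling differs between loci).  When
#' outgroup taxa are supplied and present, the tree is rooted on them first;
#' otherwise the tree is used with its given rooting.  Support is read from
#' the node subtending the clade; a node without a support label is
#' \emph{unsupported} (\code{NA}), which never passes.
#'
#' @param tree a \code{support_tree}.
#' @param clade character vector of specimen ids.
#' @param support_threshold minimum support to pass; defaults to 70 for
#'   bootstrap trees and 0.95 for posterior-probability trees.
#' @param outgroup optional character vector of outgroup specimen ids.
#' @return one-row tibble: \code{assessable}, \code{n_present},
#'   \code{monophyletic}, \code{support}, \code{passes}.
#' @export
clade_in_tree <- function(tree, clade, support_threshold = NULL,
                          outgroup = NULL) {
  kind <- attr(tree, "support_kind") %||% "bootstrap_percent"
  if (is.null(support_threshold)) {
    support_threshold <- if (kind == "posterior_probability") 0.95 else 70
  }
  present <- intersect(clade, tree$tip.label)
  if (length(present) < 2L) {
    return(tibble::tibble(assessable = FALSE, n_present = length(present),
                          monophyletic = NA, support = NA_real_,
                          passes = NA))
  }
  phy <- tree
  sup <- attr(tree, "node_support")
  og <- intersect(outgroup %||% character(), phy$tip.label)
  og <- setdiff(og, present)
  if (length(og)) {
    # reroot on the outgroup; carry node support through as labels
    phy$node.label <- as.character(seq_len(phy$Nnode))
    phy <- ape::root(phy, outgroup = og, resolve.root = TRUE)
    idx <- suppressWarnings(as.integer(phy$node.label))
    sup <- ifelse(is.na(idx), NA_real_, sup[idx])
  }
  if (length(present) == length(phy$tip.label)) {
    mono <- TRUE
    support <- NA_real_
  } else {
    mono <- ape::is.monophyletic(phy, present)
    support <- NA_real_
    if (mono) {
      node <- ape::getMRCA(phy, present)
      support <- sup[node - length(phy$tip.label)]
    }
  }
  tibble::tibble(
    assessable = TRUE, n_present = length(present),
    monophyletic = mono, support = support,
    passes = isTRUE(mono) && !is.na(support) && support >= support_threshold
  )
}

#' Multilocus concordance of a clade
#'
#' Counts the loci whose gene trees recover a clade as monophyletic with
#' support at or above the threshold.  Several trees per locus (for example
#' an ML and a Bayesian analysis) are handled by naming them
#' \code{"<locus>"} or \code{"<locus>.<method>"}; by default a locus counts
#' as concordant when \emph{any} of its trees passes
#' (\code{all_trees = TRUE} requires every tree to pass).
#'
#' @param trees named list of \code{support_tree}s.
#' @param clade character vector of specimen ids.
#' @param bootstrap_threshold,posterior_threshold support cutoffs (defaults
#'   70 and 0.95; reported values in the source studies are printed raw, so
#'   these cutoffs are explicit assumptions).
#' @param outgroup optional outgroup ids used to root each tree.
#' @param all_trees require all trees of a locus to pass (default any).
#' @return a \code{clade_assessment}: list with \code{per_tree} tibble
#'   (\code{tree}, \code{locus}, assessment columns),
#'   \code{concordant_locus_count} and \code{n_assessable_loci}.
#' @export
concordance_count <- function(trees, clade,
                              bootstrap_threshold = 70,
                              posterior_threshold = 0.95,
                              outgroup = NULL,
                              all_trees = FALSE) {
  if (!length(trees)) {
    res <- structure(list(per_tree = tibble::tibble(),
                          concordant_locus_count = 0L,
                          n_assessable_loci = 0L),
                     class = "clade_assessment")
    return(res)
  }
  per_tree <- purrr::imap_dfr(trees, function(tr, nm) {
    kind <- attr(tr, "support_kind") %||% "bootstrap_percent"
    thr <- if (kind == "posterior_probability") posterior_threshold
           else bootstrap_threshold
    dplyr::bind_cols(
      tibble::tibble(tree = nm,
                     locus = strsplit(nm, ".", fixed = TRUE)[[1]][1]),
      clade_in_tree(tr, clade, support_threshold = thr, outgroup = outgroup)
    )
  })
  by_locus <- per_tree |>
    dplyr::filter(.data$assessable) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(pass = if (all_trees) all(.data$passes)
                     else any(.data$passes))
  structure(list(per_tree = per_tree,
                 concordant_locus_count = sum(by_locus$pass),
                 n_assessable_loci = nrow(by_locus)),
            class = "clade_assessment")
}

#' @export
print.clade_assessment <- function(x, ...) {
  cat("<clade_assessment> concordant in ", x$concordant_locus_count, " of ",
      x$n_assessable_loci, " assessable loci\n", sep = "")
  invisible(x)
}
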