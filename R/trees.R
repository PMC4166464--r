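#' Read a gene tree with node support
#'
#' Parses a Newick tree whose internal-node labels carry support values,
#' either as plain labels (\code{(a,b)95}) or as the first field of a
#' \code{ml/bayes}-style composite label (\code{(a,b)95/0.99}); square-bracket
#' comments of the form \code{[&support=x]} are also recognised.  Nodes
#' without a support value are marked \emph{unsupported} (\code{NA}), never
#' zero.
#'
#' @param path path to a Newick file.
#' @param support_kind \code{"bootstrap_percent"} (values in \eqn{[0,100]}) or
#'   \code{"posterior_probability"} (values in \eqn{[0,1]}).
#' @return a \code{support_tree}: an [ape::phylo] with attributes
#'   \code{node_support} (numeric per internal node, \code{NA} =
#'   unsupported) and \code{support_kind}.
#' @export
read_support_tree <- function(path,
                              support_kind = c("bootstrap_percent",
                                               "posterior_probability")) {
  support_kind <- match.arg(support_kind)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # comment dialect: lift [&support=x] (or [x]) onto the node label
  txt <- gsub("\\)\\[&?(support=)?([0-9.eE+-]+)\\]", ")\\2", txt)
  txt <- gsub("\\[[^][]*\\]", "", txt)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL)
  if (is.null(phy)) stop("unparseable Newick in ", path)
  as_support_tree(phy, support_kind)
}

#' Attach support metadata to a phylo object
#'
#' @param phy an [ape::phylo]; internal node labels (possibly
#'   \code{"ml/bayes"} composites, first field used) are read as support.
#' @param support_kind see [read_support_tree()].
#' @export
as_support_tree <- function(phy,
                            support_kind = c("bootstrap_percent",
                                             "posterior_probability")) {
  support_kind <- match.arg(support_kind)
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", phy$Nnode)
  first <- vapply(strsplit(lab, "/", fixed = TRUE),
                  function(p) if (length(p)) p[[1]] else "", "")
  sup <- suppressWarnings(as.numeric(first))
  rng <- if (support_kind == "bootstrap_percent") c(0, 100) else c(0, 1)
  bad <- !is.na(sup) & (sup < rng[1] | sup > rng[2])
  if (any(bad)) {
    stop("support value out of range for ", support_kind, ": ",
         paste(sup[bad], collapse = ", "))
  }
  attr(phy, "node_support") <- sup
  attr(phy, "support_kind") <- support_kind
  class(phy) <- c("support_tree", class(phy))
  phy
}

#' @export
print.support_tree <- function(x, ...) {
  sup <- attr(x, "node_support")
  cat("<support_tree> ", length(x$tip.label), " tips, ",
      sum(!is.na(sup)), "/", x$Nnode, " supported nodes (",
      attr(x, "support_kind"), ")\n", sep = "")
  invisible(x)
}

#' Assemble a multilocus dataset
#'
#' Cross-references per-locus alignments, the specimen table and per-locus
#' gene trees into one dataset object, reporting which specimens are absent
#' from each locus (per-gene sampling routinely differs).
#'
#' @param alignments named list of [dna_alignment]s (one per locus).
#' @param specimens specimen tibble ([read_specimen_table()]).
#' @param trees optional named list of \code{support_tree}s; names should be
#'   \code{"<locus>"} or \code{"<locus>.<method>"}.
#' @return a \code{multilocus_dataset}: list with elements \code{loci},
#'   \code{specimens}, \code{trees} and \code{missing_report} (tibble
#'   \code{locus}, \code{specimen_id} for specimens in the table but absent
#'   from that locus).
#' @export
assemble_dataset <- function(alignments, specimens, trees = list()) {
  if (is.null(names(alignments)) || anyDuplicated(names(alignments))) {
    stop("alignments must be a uniquely named list")
  }
  all_aln_ids <- unique(unlist(lapply(alignments, specimen_ids)))
  unannotated <- setdiff(all_aln_ids, specimens$specimen_id)
  if (length(unannotated)) {
    warning("specimens present in alignments but not in the table: ",
            paste(unannotated, collapse = ", "))
  }
  for (nm in names(trees)) {
    extra <- setdiff(trees[[nm]]$tip.label, c(specimens$specimen_id, all_aln_ids))
    if (length(extra)) {
      stop("tree '", nm, "' has leaves absent from the specimen table: ",
           paste(extra, collapse = ", "))
    }
  }
  missing_report <- purrr::map_dfr(names(alignments), function(nm) {
    absent <- setdiff(specimens$specimen_id, specimen_ids(alignments[[nm]]))
    if (length(absent)) tibble::tibble(locus = nm, specimen_id = absent)
    else tibble::tibble(locus = character(), specimen_id = character())
  })
  structure(
    list(loci = alignments, specimens = specimens, trees = trees,
         missing_report = missing_report),
    class = "multilocus_dataset"
  )
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat("<multilocus_dataset> ", length(x$loci), " loci, ",
      nrow(x$specimens), " specimens, ", length(x$trees), " trees\n", sep = "")
  for (nm in names(x$loci)) {
    cat("  ", nm, ": ", nrow(x$loci[[nm]]), " specimens x ",
        ncol(x$loci[[nm]]), " bp\n", sep = "")
  }
  invisible(x)
}

#' Per-locus specimen counts
#' @param dataset a \code{multilocus_dataset}.
#' @return tibble \code{locus}, \code{n_specimens}, \code{n_columns}.
#' @export
locus_counts <- function(dataset) {
  tibble::tibble(
    locus = names(dataset$loci),
    n_specimens = unname(vapply(dataset$loci, nrow, 0L)),
    n_columns = unname(vapply(dataset$loci, ncol, 0L))
  )
}
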