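#' Tajima's D
#'
#' The normalized difference between mean pairwise nucleotide differences
#' and the Watterson estimate from segregating sites,
#' \eqn{D = (\hat\pi - S/a_1)/\sqrt{e_1 S + e_2 S (S-1)}}, with the standard
#' constants \eqn{a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2} computed from the
#' number of sequences and retained for audit.  Under the default
#' \code{"complete"} deletion policy every column containing a gap, missing
#' or ambiguous state is removed before counting (matching the common
#' default of desktop phylogenetics software); under \code{"pairwise"}
#' deletion each pair is compared over its own resolved columns and
#' segregating sites are counted over columns with at least two resolved
#' states.
#'
#' @param aln a [dna_alignment] with at least four sequences.
#' @param deletion column-deletion policy.
#' @return a \code{tajima_result}: list with \code{n}, \code{n_sites},
#'   \code{S}, \code{pi} (mean pairwise differences, in counts), \code{theta_w},
#'   \code{D} (\code{NA} with an \code{undefined} flag when \code{S = 0}) and
#'   \code{constants}.
#' @export
tajimas_d <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  e <- encode_alignment(aln)
  n <- nrow(e)
  if (n < 4L) stop("Tajima's D needs at least four sequences")
  pure <- matrix(e %in% c(1L, 2L, 4L, 8L), nrow = n)

  if (deletion == "complete") {
    keep <- colSums(pure) == n
    e <- e[, keep, drop = FALSE]
    n_sites <- ncol(e)
    S <- sum(apply(e, 2L, function(col) length(unique(col))) > 1L)
    diffs <- 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) diffs <- diffs + sum(e[i, ] != e[j, ])
    }
    pi <- diffs / choose(n, 2)
  } else {
    n_sites <- ncol(e)
    S <- sum(vapply(seq_len(ncol(e)), function(col) {
      states <- e[pure[, col], col]
      length(unique(states)) > 1L
    }, TRUE))
    tot <- 0; npairs <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        cc <- pure[i, ] & pure[j, ]
        tot <- tot + sum(e[i, cc] != e[j, cc])
        npairs <- npairs + 1L
      }
    }
    pi <- tot / npairs
  }

  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  constants <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 c1 = c1, c2 = c2, e1 = e1, e2 = e2)

  theta_w <- S / a1
  if (S == 0) {
    D <- NA_real_
    undefined <- TRUE
  } else {
    D <- (pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
    undefined <- FALSE
  }
  structure(list(n = n, n_sites = n_sites, S = S, pi = pi,
                 theta_w = theta_w, D = D, undefined = undefined,
                 deletion = deletion, constants = constants),
            class = "tajima_result")
}

#' @export
print.tajima_result <- function(x, ...) {
  cat("<tajima_result> n = ", x$n, ", S = ", x$S,
      ", pi = ", sprintf("%.4f", x$pi), ", D = ",
      if (x$undefined) "undefined (S = 0)" else sprintf("%.6f", x$D),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.tajima_result <- function(x, ...) {
  tibble::tibble(term = c("n", "n_sites", "S", "pi", "theta_w", "D"),
                 value = c(x$n, x$n_sites, x$S, x$pi, x$theta_w, x$D))
}

#' @export
glance.tajima_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_sites = x$n_sites, S = x$S, pi = x$pi,
                 theta_w = x$theta_w, D = x$D, undefined = x$undefined,
                 deletion = x$deletion)
}

#' Substitution-saturation diagnostics
#'
#' For every pair of specimens present in both the alignment and the tree,
#' pairs the uncorrected p-distance with the patristic (path-sum) distance
#' on the tree, and summarises the relationship by the least-squares slope
#' through the origin.  A saturating locus shows a lower slope and a
#' plateauing upper tail, because multiple substitutions stop adding
#' observable differences.
#'
#' @param aln a [dna_alignment].
#' @param tree a tree with branch lengths ([ape::phylo]) whose tips are
#'   specimens of the alignment.
#' @return a \code{saturation_data} tibble: \code{id_a}, \code{id_b},
#'   \code{p_distance}, \code{tree_distance}; attribute \code{slope}.
#' @export
saturation_points <- function(aln, tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ids <- intersect(tree$tip.label, rownames(aln))
  if (length(ids) < 2L) stop("need at least two shared specimens")
  dm <- pairwise_p_distance(subset_alignment(aln, ids))
  pat <- ape::cophenetic.phylo(ape::keep.tip(tree, ids))[ids, ids]
  idx <- which(upper.tri(dm$distance), arr.ind = TRUE)
  out <- tibble::tibble(
    id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
    p_distance = dm$distance[idx],
    tree_distance = pat[idx]
  )
  out <- dplyr::filter(out, !is.na(.data$p_distance))
  slope <- sum(out$p_distance * out$tree_distance) / sum(out$tree_distance^2)
  attr(out, "slope") <- slope
  class(out) <- c("saturation_data", class(out))
  out
}

#' Saturation slope
#' @param sat a \code{saturation_data}.
#' @export
saturation_slope <- function(sat) attr(sat, "slope")
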