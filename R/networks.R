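#' Collapse identical sequences into haplotypes
#'
#' Two specimens share a haplotype when their aligned sequences are identical
#' under the comparison policy: gaps are a fifth character state and, by
#' default, a missing state (\code{?}/\code{N}) matches anything
#' (\code{missing_matches = TRUE}, so partial sequences join the haplotype of
#' their best-resolved twin; specimens are scanned in input order and merged
#' into the first compatible haplotype).  Ambiguity codes match when their
#' state sets overlap.
#'
#' @param aln a [dna_alignment].
#' @param missing_matches should missing states match any state (default) or
#'   only missing states?
#' @return a \code{haplotype_set}: tibble with columns \code{haplotype}
#'   (\code{H1..Hk}), \code{members} (list of specimen ids),
#'   \code{multiplicity}; attributes \code{representatives} (encoded matrix,
#'   one row per haplotype: the first member's sequence) and \code{locus}.
#' @export
collapse_haplotypes <- function(aln, missing_matches = TRUE) {
  e <- encode_alignment(aln)
  n <- nrow(e)
  reps <- integer(0)      # row indices of representatives
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (hap_steps(e[reps[k], ], e[i, ], missing_matches) == 0L) {
        hit <- k; break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- length(reps)
    }
    assign[i] <- hit
  }
  members <- split(rownames(e), assign)
  mem <- unname(members[as.character(seq_along(reps))])
  out <- tibble::tibble(
    haplotype = paste0("H", seq_along(reps)),
    members = mem,
    multiplicity = lengths(mem)
  )
  attr(out, "representatives") <-
    `rownames<-`(e[reps, , drop = FALSE], out$haplotype)
  attr(out, "locus") <- attr(aln, "locus_name")
  attr(out, "n_sites") <- ncol(e)
  class(out) <- c("haplotype_set", class(out))
  out
}

# mutational steps between two encoded rows; gap is a fifth state,
# missing contributes 0 steps (permissive) or matches only missing (strict)
hap_steps <- function(a, b, missing_matches = TRUE) {
  if (missing_matches) {
    use <- a != .MISSING & b != .MISSING
    a <- a[use]; b <- b[use]
  } else {
    a[a == .MISSING] <- 32L
    b[b == .MISSING] <- 32L
  }
  gap_a <- a == .GAP | a == 32L
  gap_b <- b == .GAP | b == 32L
  either_gap <- gap_a | gap_b
  steps <- sum(either_gap & (a != b))
  base <- !either_gap
  steps + sum(bitwAnd(a[base], b[base]) == 0L)
}

#' Mutational step distance between two sequences
#'
#' Counts the columns at which two equal-length aligned sequences differ,
#' with the gap character \code{-} counted as a fifth state (a base/gap
#' column is one step) and missing states contributing no steps.  Ambiguity
#' codes with overlapping state sets do not count as a step.
#'
#' @param h1,h2 character strings or character vectors of equal length.
#' @return integer number of steps.
#' @export
step_distance <- function(h1, h2) {
  if (length(h1) == 1L) h1 <- strsplit(toupper(h1), "", fixed = TRUE)[[1]]
  if (length(h2) == 1L) h2 <- strsplit(toupper(h2), "", fixed = TRUE)[[1]]
  if (length(h1) != length(h2)) stop("sequences must have equal length")
  hap_steps(.iupac_mask[h1], .iupac_mask[h2])
}

#' Statistical-parsimony connection limit
#'
#' Computes the maximum number of mutational steps \code{j_max} at which two
#' haplotypes are still connected into one network, following the
#' probability-of-parsimony rationale of statistical parsimony: under a
#' Jukes-Cantor finite-sites model with the divergence for \code{j} observed
#' differences over \code{L} sites estimated as
#' \eqn{\theta_j = -\frac{3}{4}\log(1 - \frac{4j}{3L})}, the probability that
#' every observed difference reflects a single substitution is
#' \eqn{P_j = (\theta_j e^{-\theta_j} / (j/L))^j}.  \code{j_max} is the
#' largest \code{j} with \eqn{P_j \ge} \code{prob_limit}.  \eqn{P_j} is
#' non-increasing in \code{j}, and lowering the probability limit never
#' decreases \code{j_max}.
#'
#' @param n_sites alignment length L in sites.
#' @param prob_limit required probability of parsimony, in (0, 1); the
#'   conventional settings are 0.95 for fast mitochondrial markers, 0.98 for
#'   slower nuclear ribosomal genes, 0.90 for a relaxed analysis.
#' @return a \code{connection_limit}: list with \code{n_sites},
#'   \code{prob_limit}, \code{j_max} and the audit vector \code{p_j}
#'   (probability at each step \code{1..j_max + 1}).
#' @export
connection_limit <- function(n_sites, prob_limit = 0.95) {
  stopifnot(n_sites >= 1, prob_limit > 0, prob_limit < 1)
  p_j <- numeric(0)
  j <- 0L
  repeat {
    j <- j + 1L
    p <- parsimony_probability(j, n_sites)
    p_j[j] <- p
    if (p < prob_limit || j >= n_sites) break
  }
  j_max <- if (p_j[j] >= prob_limit) j else j - 1L
  structure(list(n_sites = n_sites, prob_limit = prob_limit,
                 j_max = j_max, p_j = p_j),
            class = "connection_limit")
}

# probability that all j observed differences over L sites are single
# substitutions, under Jukes-Cantor with divergence estimated from j/L
parsimony_probability <- function(j, L) {
  p <- j / L
  if (p >= 0.75) return(0)
  theta <- -0.75 * log(1 - 4 * p / 3)
  r <- theta * exp(-theta) / p
  r^j
}

#' @export
print.connection_limit <- function(x, ...) {
  cat("<connection_limit> L = ", x$n_sites, " sites, prob >= ",
      x$prob_limit, " -> j_max = ", x$j_max, "\n", sep = "")
  invisible(x)
}

#' Build statistical-parsimony haplotype networks
#'
#' Connects haplotypes whose mutational step distance is at most the
#' connection limit and enumerates the connected components; each component
#' is one network, and unconnected haplotypes form singleton networks.
#' Edges are drawn directly between sampled haplotypes (the downstream use
#' is co-membership, not reconstructed intermediate haplotypes).
#'
#' @param haps a \code{haplotype_set} from [collapse_haplotypes()].
#' @param limit a \code{connection_limit} computed for the same alignment
#'   length, or \code{NULL} when \code{fixed_steps} is given.
#' @param fixed_steps optional integer overriding the probability model.
#' @return a \code{haplotype_networks}: tibble \code{haplotype},
#'   \code{network} (\code{N1..}), \code{members}, \code{multiplicity};
#'   attributes \code{steps} (haplotype-by-haplotype step matrix),
#'   \code{j_max}, \code{locus}.
#' @export
build_networks <- function(haps, limit = NULL, fixed_steps = NULL) {
  if (is.null(fixed_steps)) {
    if (is.null(limit)) stop("either limit or fixed_steps is required")
    if (limit$n_sites != attr(haps, "n_sites")) {
      stop("connection limit computed for ", limit$n_sites,
           " sites but alignment has ", attr(haps, "n_sites"))
    }
    j_max <- limit$j_max
  } else {
    j_max <- as.integer(fixed_steps)
  }
  reps <- attr(haps, "representatives")
  k <- nrow(reps)
  steps <- matrix(0L, k, k, dimnames = list(rownames(reps), rownames(reps)))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        steps[i, j] <- steps[j, i] <- hap_steps(reps[i, ], reps[j, ])
      }
    }
  }
  adj <- steps <= j_max
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  out <- tibble::as_tibble(haps)
  out$network <- paste0("N", comp[out$haplotype])
  out <- out[, c("haplotype", "network", "members", "multiplicity")]
  attr(out, "steps") <- steps
  attr(out, "j_max") <- j_max
  attr(out, "locus") <- attr(haps, "locus")
  class(out) <- c("haplotype_networks", class(out))
  out
}

#' Number of networks
#' @param nets a \code{haplotype_networks}.
#' @export
n_networks <- function(nets) length(unique(nets$network))

#' Network separation of a putative species
#'
#' Reports whether a group's specimens occupy haplotype networks of their
#' own: \code{is_separate} is \code{TRUE} when no network contains both a
#' member and a non-member, \code{n_networks_spanned} counts the networks
#' holding members (a group split over several exclusive networks is still
#' separate: the "asterisk" case), and for shared networks
#' \code{min_steps_to_nonmember} gives the smallest step distance from a
#' member haplotype to a non-member haplotype in the same network.
#'
#' @param nets a \code{haplotype_networks}.
#' @param partition partition tibble or named vector.
#' @param group group label to assess.
#' @return one-row tibble: \code{group}, \code{has_data},
#'   \code{is_separate}, \code{n_networks_spanned},
#'   \code{min_steps_to_nonmember} (\code{NA} when separate).
#' @export
network_separation <- function(nets, partition, group) {
  partition <- as_partition(partition)
  members <- partition$specimen_id[partition$group == group]
  hap_of <- tidyr::unnest(
    tibble::as_tibble(nets)[, c("haplotype", "network", "members")],
    "members") |>
    # specimens outside the partition (outgroups, unassigned) are neither
    # members nor counter-evidence
    dplyr::filter(.data$members %in% partition$specimen_id)
  hap_members <- dplyr::filter(hap_of, .data$members %in% !!members)
  if (!nrow(hap_members)) {
    return(tibble::tibble(group = group, has_data = FALSE,
                          is_separate = NA, n_networks_spanned = 0L,
                          min_steps_to_nonmember = NA_real_))
  }
  member_haps <- unique(hap_members$haplotype)
  spanned <- unique(hap_members$network)
  # haplotypes are "member haplotypes" if any member carries them; a shared
  # haplotype (member + non-member specimens) already breaks separation
  shared_hap <- hap_of |>
    dplyr::filter(.data$haplotype %in% member_haps,
                  !(.data$members %in% !!members))
  other_haps_in_spanned <- hap_of |>
    dplyr::filter(.data$network %in% spanned,
                  !(.data$haplotype %in% member_haps))
  is_separate <- nrow(shared_hap) == 0L && nrow(other_haps_in_spanned) == 0L
  min_steps <- NA_real_
  if (!is_separate) {
    if (nrow(shared_hap)) {
      min_steps <- 0
    } else {
      steps <- attr(nets, "steps")
      min_steps <- min(steps[member_haps,
                             unique(other_haps_in_spanned$haplotype),
                             drop = FALSE])
    }
  }
  tibble::tibble(group = group, has_data = TRUE, is_separate = is_separate,
                 n_networks_spanned = length(spanned),
                 min_steps_to_nonmember = min_steps)
}

#' Export network membership
#'
#' Writes a TSV with columns \code{locus network haplotype specimen_ids}.
#'
#' @param nets a \code{haplotype_networks}.
#' @param path output path.
#' @export
write_networks <- function(nets, path) {
  out <- tibble::tibble(
    locus = attr(nets, "locus") %||% "",
    network = nets$network,
    haplotype = nets$haplotype,
    specimen_ids = vapply(nets$members, paste, "", collapse = ",")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the haplotype graph
#'
#' Writes the thresholded haplotype graph (edges where the step distance is
#' within the connection limit, weighted by steps) as GraphML or DOT for
#' external layout tools.
#'
#' @param nets a \code{haplotype_networks}.
#' @param path output path.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @export
export_network_graph <- function(nets, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  steps <- attr(nets, "steps")
  adj <- steps <= attr(nets, "j_max")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  ij <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$steps <- steps[cbind(ij[, 1], ij[, 2])]
  igraph::V(g)$network <- nets$network[match(igraph::V(g)$name,
                                             nets$haplotype)]
  igraph::V(g)$multiplicity <- nets$multiplicity[match(igraph::V(g)$name,
                                                       nets$haplotype)]
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
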