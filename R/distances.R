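#' Exclude low-coverage specimens
#'
#' Removes specimens whose count of resolved characters (anything other than
#' gap or missing) is below \code{min_fraction} of the alignment length, the
#' usual guard before distance and network analyses of partial sequences.
#'
#' @param aln a [dna_alignment].
#' @param min_fraction minimum resolved fraction, default 0.5 (sequences
#'   shorter than half the alignment length are excluded).
#' @return the filtered [dna_alignment] with attribute \code{excluded_ids}.
#' @export
coverage_filter <- function(aln, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  e <- encode_alignment(aln)
  resolved <- rowSums(e != .GAP & e != .MISSING)
  keep <- resolved >= min_fraction * ncol(aln)
  if (!any(keep)) stop("all specimens fall below the coverage threshold")
  out <- subset_alignment(aln, rownames(aln)[keep])
  attr(out, "excluded_ids") <- rownames(aln)[!keep]
  out
}

#' Trim an alignment to a column range
#'
#' Columns are 1-based and inclusive.  The returned alignment carries a
#' \code{coordinate_offset} attribute so positions found after trimming can
#' be mapped back (original column = trimmed column + offset).
#'
#' @param aln a [dna_alignment].
#' @param from,to first and last column to keep.
#' @export
trim_alignment <- function(aln, from, to) {
  if (from < 1 || to > ncol(aln) || from > to) {
    stop("invalid trim interval [", from, ", ", to, "] for ",
         ncol(aln), " columns")
  }
  m <- unclass(aln)[, from:to, drop = FALSE]
  structure(m, class = "dna_alignment",
            locus_name = attr(aln, "locus_name"),
            coordinate_offset = from - 1L)
}

#' Uncorrected pairwise distances
#'
#' Computes p-distances under pairwise deletion: for each pair, comparable
#' sites are the columns where neither sequence has a gap or missing state;
#' the distance is mismatches / comparable sites.  Under the default
#' \code{ambiguity = "overlap"} policy, two IUPAC codes match when their
#' state sets intersect (conservative: never inflates divergence); under
#' \code{"missing"} ambiguity codes are excluded from comparable sites.
#' A pair with zero comparable sites has an undefined (\code{NA}) distance,
#' never zero.
#'
#' @param aln a [dna_alignment] with at least two specimens.
#' @param ambiguity ambiguity-code policy, see Details.
#' @return a \code{p_dist} object: list with \code{specimen_ids}, symmetric
#'   \code{distance} matrix (fractions, \code{NA} where undefined) and
#'   integer \code{comparable_sites} matrix.
#' @export
pairwise_p_distance <- function(aln, ambiguity = c("overlap", "missing")) {
  ambiguity <- match.arg(ambiguity)
  if (nrow(aln) < 2L) stop("need at least two specimens")
  e <- encode_alignment(aln)
  if (ambiguity == "missing") {
    pure <- e %in% c(1L, 2L, 4L, 8L, .GAP)
    e[!pure] <- .MISSING
    dim(e) <- dim(aln)
  }
  n <- nrow(e)
  ok <- e != .GAP & e != .MISSING
  d <- matrix(0, n, n, dimnames = list(rownames(e), rownames(e)))
  comp <- matrix(0L, n, n, dimnames = list(rownames(e), rownames(e)))
  for (i in seq_len(n - 1L)) {
    ei <- e[i, ]; oki <- ok[i, ]
    for (j in (i + 1L):n) {
      cc <- oki & ok[j, ]
      nc <- sum(cc)
      comp[i, j] <- comp[j, i] <- nc
      if (nc == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        mism <- sum(bitwAnd(ei[cc], e[j, cc]) == 0L)
        d[i, j] <- d[j, i] <- mism / nc
      }
    }
  }
  structure(list(specimen_ids = rownames(e), distance = d,
                 comparable_sites = comp),
            class = "p_dist")
}

#' @export
print.p_dist <- function(x, ...) {
  cat("<p_dist> ", length(x$specimen_ids), " specimens; mean distance ",
      sprintf("%.4f", mean(x$distance[upper.tri(x$distance)], na.rm = TRUE)),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.p_dist <- function(x, ...) {
  n <- length(x$specimen_ids)
  idx <- which(upper.tri(x$distance), arr.ind = TRUE)
  tibble::tibble(
    id_a = x$specimen_ids[idx[, 1]],
    id_b = x$specimen_ids[idx[, 2]],
    distance = x$distance[idx],
    comparable_sites = x$comparable_sites[idx]
  )
}

#' Write a distance matrix
#'
#' @param dm a \code{p_dist}.
#' @param path output path.
#' @param format \code{"tsv"} (long format, columns
#'   \code{id_a id_b distance comparable_sites}) or \code{"phylip"} (square).
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(tidy.p_dist(dm), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$specimen_ids)), con)
    for (i in seq_along(dm$specimen_ids)) {
      writeLines(paste(c(formatC(dm$specimen_ids[i], width = -10),
                         sprintf("%.6f", dm$distance[i, ])), collapse = " "),
                 con)
    }
  }
  invisible(path)
}

# Normalize a partition to a tibble(specimen_id, group).
as_partition <- function(partition) {
  if (tibble::is_tibble(partition) || is.data.frame(partition)) {
    stopifnot(all(c("specimen_id", "group") %in% names(partition)))
    tibble::as_tibble(partition[, c("specimen_id", "group")])
  } else if (!is.null(names(partition))) {
    tibble::tibble(specimen_id = names(partition),
                   group = as.character(partition))
  } else {
    stop("partition must be a tibble(specimen_id, group) or a named vector")
  }
}

#' Within- and between-group distance summary
#'
#' Arithmetic means over all defined pairwise distances within each group and
#' between each group pair, plus each group's nearest neighbour.  Singleton
#' groups have an undefined (\code{NA}) mean intra-group distance.
#'
#' @param dm a \code{p_dist}.
#' @param partition tibble \code{specimen_id, group} (or named vector) for
#'   every specimen in \code{dm}.
#' @return a \code{group_dist_summary}: tibble with one row per group
#'   (\code{group}, \code{n}, \code{mean_intra}, \code{nearest_group},
#'   \code{min_mean_inter}) and attribute \code{pairs} (tibble
#'   \code{group_a}, \code{group_b}, \code{mean_inter}).
#' @export
group_summary <- function(dm, partition) {
  partition <- as_partition(partition)
  missing <- setdiff(dm$specimen_ids, partition$specimen_id)
  if (length(missing)) {
    stop("specimens without a group assignment: ", paste(missing, collapse = ", "))
  }
  grp <- setNames(partition$group, partition$specimen_id)[dm$specimen_ids]
  groups <- sort(unique(grp))
  d <- dm$distance

  mean_block <- function(ids_a, ids_b, within) {
    block <- d[ids_a, ids_b, drop = FALSE]
    vals <- if (within) block[upper.tri(block)] else as.vector(block)
    vals <- vals[!is.na(vals)]
    if (length(vals)) mean(vals) else NA_real_
  }

  ids_of <- split(dm$specimen_ids, grp)
  intra <- unname(vapply(groups, function(g) {
    if (length(ids_of[[g]]) < 2L) NA_real_
    else mean_block(ids_of[[g]], ids_of[[g]], within = TRUE)
  }, 0))

  pairs <- tidyr::expand_grid(group_a = groups, group_b = groups) |>
    dplyr::filter(.data$group_a < .data$group_b) |>
    dplyr::mutate(mean_inter = purrr::map2_dbl(
      .data$group_a, .data$group_b,
      ~ mean_block(ids_of[[.x]], ids_of[[.y]], within = FALSE)))

  nearest <- purrr::map_dfr(groups, function(g) {
    rows <- dplyr::filter(pairs, .data$group_a == g | .data$group_b == g)
    rows <- dplyr::filter(rows, !is.na(.data$mean_inter))
    if (!nrow(rows)) {
      return(tibble::tibble(group = g, nearest_group = NA_character_,
                            min_mean_inter = NA_real_))
    }
    k <- which.min(rows$mean_inter)
    tibble::tibble(
      group = g,
      nearest_group = ifelse(rows$group_a[k] == g, rows$group_b[k], rows$group_a[k]),
      min_mean_inter = rows$mean_inter[k]
    )
  })

  out <- tibble::tibble(
    group = groups,
    n = unname(vapply(ids_of[groups], length, 0L)),
    mean_intra = intra
  ) |>
    dplyr::left_join(nearest, by = "group")
  attr(out, "pairs") <- pairs
  class(out) <- c("group_dist_summary", class(out))
  out
}

#' Relative (2x) threshold test
#'
#' A group passes species-level distance discovery when its smallest mean
#' distance to any other group is at least \code{ratio} (default 2,
#' inclusive) times its mean intra-group distance.  Groups whose intra-group
#' mean is undefined (singletons) or exactly zero pass with an explicit
#' \code{intra_undefined}/infinite-ratio flag rather than being dropped.
#'
#' @param summary a \code{group_dist_summary} from [group_summary()].
#' @param ratio required inter/intra ratio, default 2 (inclusive).
#' @return tibble: \code{group}, \code{mean_intra}, \code{min_mean_inter},
#'   \code{ratio} (\code{Inf} when intra is zero or undefined),
#'   \code{intra_undefined}, \code{passes}.
#' @export
relative_threshold_test <- function(summary, ratio = 2) {
  dplyr::transmute(
    tibble::as_tibble(summary),
    group = .data$group,
    mean_intra = .data$mean_intra,
    min_mean_inter = .data$min_mean_inter,
    intra_undefined = is.na(.data$mean_intra),
    ratio = dplyr::case_when(
      is.na(.data$min_mean_inter) ~ NA_real_,
      is.na(.data$mean_intra) | .data$mean_intra == 0 ~ Inf,
      TRUE ~ .data$min_mean_inter / .data$mean_intra
    ),
    passes = dplyr::case_when(
      is.na(.data$min_mean_inter) ~ TRUE,   # sole group: vacuous
      is.na(.data$mean_intra) ~ TRUE,       # singleton: retained, flagged
      .data$mean_intra == 0 ~ TRUE,
      TRUE ~ .data$min_mean_inter / .data$mean_intra >= !!ratio
    )
  )
}

#' Distance-based species discovery
#'
#' Finds putative species groups from a distance matrix by combining the
#' barcoding-gap structure of an average-linkage dendrogram with the relative
#' threshold criterion.  Candidate partitions are the dendrogram cuts between
#' successive merge heights; they are ranked by the relative jump in merge
#' height at the cut (the "gap"), and the highest-ranked partition in which
#' every group passes the 2x test is returned.  During discovery a group with
#' zero or undefined intra-group distance passes only when its nearest-group
#' distance is at least \code{ratio} times the largest positive intra-group
#' mean in the partition (or strictly positive when no group shows internal
#' variation), which keeps genuine singleton species while preventing the
#' degenerate all-singletons solution.  The search is deterministic and does
#' not depend on specimen order or labels.
#'
#' @param dm a \code{p_dist} over at least two specimens.
#' @param ratio inter/intra ratio required of every group (default 2).
#' @return a partition tibble \code{specimen_id, group} with groups labelled
#'   \code{G1..Gk} in order of first appearance.
#' @export
discover_distance_groups <- function(dm, ratio = 2) {
  d <- dm$distance
  n <- nrow(d)
  if (n < 2L) stop("need at least two specimens with defined distances")
  if (anyNA(d)) {
    fill <- max(d, na.rm = TRUE)
    d[is.na(d)] <- fill + fill / 10
  }
  single <- tibble::tibble(specimen_id = dm$specimen_ids, group = "G1")
  if (n == 2L || max(d) == 0) return(single)
  hc <- hclust(as.dist(d), method = "average")
  h <- hc$height  # non-decreasing for average linkage

  passes_all <- function(groups) {
    part <- tibble::tibble(specimen_id = dm$specimen_ids,
                           group = as.character(groups))
    s <- group_summary(dm, part)
    scale_intra <- suppressWarnings(max(c(0, s$mean_intra), na.rm = TRUE))
    ok <- ifelse(
      is.na(s$mean_intra) | s$mean_intra == 0,
      !is.na(s$min_mean_inter) &
        (if (scale_intra > 0) s$min_mean_inter >= ratio * scale_intra
         else s$min_mean_inter > 0),
      is.na(s$min_mean_inter) | s$min_mean_inter / s$mean_intra >= ratio
    )
    all(ok)
  }

  # cut after merge i leaves k = n - i groups; rank cuts by relative height
  # gap.  Cuts whose lower height is zero only collapse duplicate sequences
  # and carry no within-group scale, so they are considered only after every
  # positive-gap candidate fails.
  i <- seq_len(n - 2L)
  gap <- h[i + 1L] / pmax(h[i], 1e-12)
  pos <- i[h[i] > 0 & gap[i] > 1]
  zero <- i[h[i] == 0 & h[i + 1L] > 0]
  ord <- c(pos[order(-gap[pos], -(n - pos))],
           zero[order(-h[zero + 1L], -(n - zero))])
  chosen <- NULL
  for (ii in ord) {
    groups <- cutree(hc, k = n - ii)
    if (passes_all(groups)) { chosen <- groups; break }
  }
  if (is.null(chosen)) {
    if (max(dm$distance, na.rm = TRUE) > 0) {
      warning("no multi-group partition satisfies the relative threshold; ",
              "returning a single group")
    }
    return(single)
  }
  relabel <- setNames(paste0("G", seq_along(unique(chosen))), unique(chosen))
  tibble::tibble(specimen_id = dm$specimen_ids,
                 group = unname(relabel[as.character(chosen)]))
}
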