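#' @export
tidy.haplotype_networks <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::unnest("members") |>
    dplyr::rename(specimen_id = "members")
}

#' @export
glance.haplotype_networks <- function(x, ...) {
  tibble::tibble(locus = attr(x, "locus") %||% "",
                 n_haplotypes = nrow(x),
                 n_networks = n_networks(x),
                 j_max = attr(x, "j_max"))
}

#' @export
tidy.group_dist_summary <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.delim_result <- function(x, ...) x$evidence

#' @export
glance.delim_result <- function(x, ...) {
  tibble::tibble(
    n_specimens = nrow(x$partition),
    n_clades = length(unique(x$partition$group)),
    n_described = sum(x$evidence$status == "described_candidate"),
    n_candidate = sum(x$evidence$status == "candidate"),
    n_unresolved = sum(x$evidence$status == "unresolved")
  )
}

#' @export
tidy.connection_limit <- function(x, ...) {
  tibble::tibble(j = seq_along(x$p_j), p_parsimony = x$p_j,
                 connected = seq_along(x$p_j) <= x$j_max)
}

#' Plot saturation diagnostics
#'
#' Uncorrected p-distance against patristic distance; the dashed unit-slope
#' reference line is the expectation without multiple substitutions, and
#' the solid line is the fitted through-origin slope.  A plateauing cloud
#' far below the reference indicates saturation.
#'
#' @param object a \code{saturation_data}.
#' @param ... unused.
#' @export
autoplot.saturation_data <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tree_distance,
                               y = .data$p_distance)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = attr(object, "slope"), intercept = 0) +
    ggplot2::labs(x = "patristic distance (substitutions/site)",
                  y = "uncorrected p-distance") +
    ggplot2::theme_minimal()
}

#' Plot haplotype network composition
#'
#' One bar per network, stacked by haplotype multiplicity.
#'
#' @param object a \code{haplotype_networks}.
#' @param ... unused.
#' @export
autoplot.haplotype_networks <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network,
                                   y = .data$multiplicity,
                                   fill = .data$haplotype)) +
    ggplot2::geom_col(show.legend = FALSE, colour = "grey30") +
    ggplot2::labs(x = "network", y = "specimens") +
    ggplot2::theme_minimal()
}

#' Plot a distance matrix
#'
#' Heatmap of pairwise uncorrected distances in specimen order.
#'
#' @param object a \code{p_dist}.
#' @param ... unused.
#' @export
autoplot.p_dist <- function(object, ...) {
  df <- tidy.p_dist(object)
  lv <- object$specimen_ids
  df$id_a <- factor(df$id_a, levels = lv)
  df$id_b <- factor(df$id_b, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id_a, y = .data$id_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "p-distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-clade evidence status
#'
#' Clades ordered by specimen count, coloured by delimitation status.
#'
#' @param object a \code{delim_result}.
#' @param ... unused.
#' @export
autoplot.delim_result <- function(object, ...) {
  df <- object$evidence
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$clade, .data$n_specimens),
    y = .data$n_specimens, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "specimens", fill = "status") +
    ggplot2::theme_minimal()
}
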