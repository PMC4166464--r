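#' Run the full delimitation pipeline
#'
#' Executes the stages in order for every locus: coverage filtering,
#' uncorrected pairwise distances, statistical-parsimony haplotype networks,
#' per-clade distance and network-separation evidence, gene-tree
#' concordance, and the combined decision rule.  The run is a pure function
#' of its inputs: identical inputs and configuration give identical results.
#'
#' @param dataset a \code{multilocus_dataset} ([assemble_dataset()] or
#'   [simulate_dataset()]).
#' @param partition \code{NULL} to discover groups de novo from the
#'   configured discovery locus, the string \code{"apriori"} to use the
#'   specimen table's clade labels, or a partition tibble
#'   \code{specimen_id, group}.
#' @param config a [delim_config()].
#' @param validations optional validation tibble ([read_validation_table()]).
#' @param vetoes optional tibble \code{group, veto} of free-text vetoes that
#'   demote a clade to candidate for non-molecular reasons.
#' @return a \code{delim_result}: list with \code{partition},
#'   \code{evidence} (the formatted per-clade evidence table),
#'   \code{per_locus} (filtered alignments, distances, summaries, threshold
#'   tests, networks, separation), \code{concordance} (per clade),
#'   \code{excluded} (coverage-filtered specimens) and \code{config}.
#' @export
run_delimitation <- function(dataset, partition = NULL,
                             config = delim_config(),
                             validations = NULL, vetoes = NULL) {
  stopifnot(inherits(dataset, "multilocus_dataset"))
  loci <- names(dataset$loci)
  limits <- rep_len(config$connection_limits, length(loci))
  if (!is.null(names(config$connection_limits))) {
    limits <- config$connection_limits[loci]
    if (anyNA(limits)) stop("connection_limits names do not cover all loci")
  }
  names(limits) <- loci

  outgroup <- dataset$specimens$specimen_id[dataset$specimens$is_outgroup]

  per_locus <- purrr::map(loci, function(nm) {
    aln <- coverage_filter(dataset$loci[[nm]], config$min_fraction)
    dm <- if (nrow(aln) >= 2) {
      pairwise_p_distance(aln, ambiguity = config$ambiguity)
    }
    haps <- collapse_haplotypes(aln, missing_matches = config$missing_matches)
    lim <- connection_limit(ncol(aln), limits[[nm]])
    nets <- build_networks(haps, lim)
    list(alignment = aln, excluded = attr(aln, "excluded_ids"),
         distances = dm, limit = lim, networks = nets)
  })
  names(per_locus) <- loci

  # partition: discovered, a-priori, or supplied
  discovered <- is.null(partition)
  if (discovered) {
    disc <- if (is.character(config$discovery_locus)) config$discovery_locus
            else loci[config$discovery_locus]
    dm <- per_locus[[disc]]$distances
    if (is.null(dm)) stop("discovery locus has fewer than two specimens")
    partition <- discover_distance_groups(dm, ratio = config$ratio)
  } else if (identical(partition, "apriori")) {
    tab <- dplyr::filter(dataset$specimens, nzchar(.data$clade))
    partition <- tibble::tibble(specimen_id = tab$specimen_id,
                                group = tab$clade)
  } else {
    partition <- as_partition(partition)
  }
  partition <- dplyr::filter(partition,
                             !(.data$specimen_id %in% !!outgroup))
  # specimens filtered out of the discovery locus (or absent from it) but
  # present elsewhere are classified to their nearest group, one vote per
  # locus where they have data
  all_ids <- unique(unlist(purrr::map(per_locus,
                                      ~ specimen_ids(.x$alignment))))
  unassigned <- if (discovered) {
    setdiff(setdiff(all_ids, outgroup), partition$specimen_id)
  } else character(0)
  for (id in sort(unassigned)) {
    votes <- character(0)
    for (nm in loci) {
      dm <- per_locus[[nm]]$distances
      if (is.null(dm) || !id %in% dm$specimen_ids) next
      grp_mean <- purrr::map_dbl(
        split(partition$specimen_id, partition$group),
        function(ids) {
          ids <- intersect(ids, dm$specimen_ids)
          if (!length(ids)) return(NA_real_)
          mean(dm$distance[id, ids], na.rm = TRUE)
        })
      grp_mean <- sort(grp_mean[!is.na(grp_mean)])
      if (!length(grp_mean)) next
      # membership requires the nearest group to be clearly closer than the
      # runner-up (same relative-threshold logic as discovery); otherwise the
      # specimen is distinct from every current group
      d2 <- if (length(grp_mean) >= 2) grp_mean[2] else Inf
      votes <- c(votes,
                 if (grp_mean[1] <= d2 / config$ratio) names(grp_mean)[1]
                 else ".new")
    }
    if (length(votes)) {
      tally <- sort(table(votes), decreasing = TRUE)
      pick <- names(tally)[1]
      if (pick == ".new") {
        k <- 1L
        while (paste0("G", k) %in% partition$group) k <- k + 1L
        pick <- paste0("G", k)
      }
      partition <- dplyr::bind_rows(
        partition, tibble::tibble(specimen_id = id, group = pick))
    }
  }
  groups <- sort(unique(partition$group))

  # per-locus group evidence
  for (nm in loci) {
    pl <- per_locus[[nm]]
    ids <- intersect(partition$specimen_id, specimen_ids(pl$alignment))
    part_here <- dplyr::filter(partition, .data$specimen_id %in% !!ids)
    if (!is.null(pl$distances) && length(ids) >= 2) {
      sub <- subset_alignment(pl$alignment, ids)
      dm_here <- if (length(ids) == length(specimen_ids(pl$alignment)))
        pl$distances else pairwise_p_distance(sub, config$ambiguity)
      summ <- group_summary(dm_here, part_here)
      thr <- relative_threshold_test(summ, ratio = config$ratio)
    } else {
      summ <- NULL
      thr <- tibble::tibble(group = character(), passes = logical())
    }
    sep <- purrr::map_dfr(groups, function(g) {
      network_separation(pl$networks, partition, g)
    })
    per_locus[[nm]]$summary <- summ
    per_locus[[nm]]$threshold <- thr
    per_locus[[nm]]$separation <- sep
    per_locus[[nm]]$n_by_group <- part_here |>
      dplyr::count(.data$group, name = "n")
  }

  concord <- purrr::map(setNames(groups, groups), function(g) {
    clade <- partition$specimen_id[partition$group == g]
    concordance_count(dataset$trees, clade,
                      bootstrap_threshold = config$bootstrap_threshold,
                      posterior_threshold = config$posterior_threshold,
                      outgroup = outgroup,
                      all_trees = config$all_trees)
  })

  evidence <- evidence_table(per_locus, partition, concord,
                             validations, vetoes, config)

  structure(list(partition = partition, evidence = evidence,
                 per_locus = per_locus, concordance = concord,
                 excluded = purrr::map(per_locus, "excluded"),
                 config = config),
            class = "delim_result")
}

#' Assemble the per-clade evidence table
#'
#' One row per clade: specimen counts per locus, smallest-interspecific vs
#' intraspecific mean distance per locus (printed as percentages to one
#' decimal), network separation per locus (\code{yes}, \code{yes*} when the
#' clade spans several exclusive networks, or the step count to the nearest
#' non-member when a network is shared), concordant-locus count, validation
#' outcome and resulting status.  Usually called through
#' [run_delimitation()].
#'
#' @param per_locus,partition,concord,validations,vetoes,config internal
#'   pieces as assembled by [run_delimitation()].
#' @return a tibble, one row per clade.
#' @export
evidence_table <- function(per_locus, partition, concord,
                           validations = NULL, vetoes = NULL,
                           config = delim_config()) {
  partition <- as_partition(partition)
  groups <- sort(unique(partition$group))
  loci <- names(per_locus)

  rows <- purrr::map_dfr(groups, function(g) {
    n_total <- sum(partition$group == g)
    n_by <- vapply(loci, function(nm) {
      tb <- per_locus[[nm]]$n_by_group
      k <- match(g, tb$group)
      if (is.na(k)) 0L else tb$n[k]
    }, 0L)
    dist_cells <- vapply(loci, function(nm) {
      s <- per_locus[[nm]]$summary
      if (is.null(s) || !g %in% s$group) return("-")
      r <- s[s$group == g, ]
      fmt_dist_cell(r$min_mean_inter, r$mean_intra)
    }, "")
    dist_pass <- vapply(loci, function(nm) {
      t <- per_locus[[nm]]$threshold
      k <- match(g, t$group)
      !is.na(k) && isTRUE(t$passes[k])
    }, TRUE)
    intra_undef <- vapply(loci, function(nm) {
      t <- per_locus[[nm]]$threshold
      k <- match(g, t$group)
      !is.na(k) && isTRUE(t$intra_undefined[k])
    }, TRUE)
    seps <- purrr::map(loci, function(nm) {
      s <- per_locus[[nm]]$separation
      s[s$group == g, ]
    })
    net_cells <- vapply(seps, fmt_net_cell, "")
    separate <- vapply(seps, function(s) isTRUE(s$is_separate), TRUE)
    ca <- concord[[g]]
    pp <- if (!is.null(validations) && g %in% validations$clade) {
      as.numeric(validations[match(g, validations$clade),
                             grep("^pp", names(validations)), drop = TRUE])
    } else numeric(0)
    veto <- if (!is.null(vetoes) && g %in% vetoes$group) {
      vetoes$veto[match(g, vetoes$group)]
    } else ""
    ev <- tibble::tibble(
      clade = g,
      n_specimens = n_total,
      n_per_locus = paste(n_by, collapse = "/"),
      !!!setNames(as.list(dist_cells), paste0("dist_", loci)),
      !!!setNames(as.list(net_cells), paste0("net_", loci)),
      distance_pass_loci = sum(dist_pass),
      intra_undefined_loci = sum(intra_undef),
      separate_loci = sum(separate),
      concordant_loci = ca$concordant_locus_count,
      assessable_loci = ca$n_assessable_loci,
      validation = if (length(pp)) paste(pp, collapse = "/") else "-",
      validated = validation_status(pp, config$validation_threshold,
                                    config$validation_min_analyses),
      veto = veto
    )
    evaluate_clade(ev, config)
  })
  rows
}

# minimal pipe-table rendering for the markdown reports
knit_md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L,
                                      dimnames = list(NULL, names(df)))
  c(paste0("| ", paste(colnames(cells), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(cells)), collapse = "|"), "|"),
    apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' @export
print.delim_result <- function(x, ...) {
  cat("<delim_result> ", length(unique(x$partition$group)), " clades over ",
      nrow(x$partition), " specimens\n", sep = "")
  print(dplyr::count(x$evidence, .data$status))
  invisible(x)
}

#' Write delimitation outputs
#'
#' Writes the evidence table (TSV), the partition, per-locus network
#' memberships and distance matrices into a directory.  Every file carries a
#' header line recording the thresholds applied (coordinates are 1-based and
#' inclusive throughout).
#'
#' @param result a \code{delim_result}.
#' @param dir output directory (created if needed).
#' @export
write_delimitation <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  hdr <- paste0("# crypticdelim evidence table; 1-based inclusive coordinates; ",
                "ratio>=", cfg$ratio,
                "; connection limits ",
                paste(cfg$connection_limits, collapse = "/"),
                "; support >= ", cfg$bootstrap_threshold, "/",
                cfg$posterior_threshold)
  path <- file.path(dir, "evidence_table.tsv")
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(result$evidence, path, append = TRUE,
                                    col_names = TRUE))
  readr::write_tsv(result$partition, file.path(dir, "partition.tsv"))
  md <- c("# Species delimitation evidence", "",
          sub("^# ", "", hdr), "",
          knit_md_table(result$evidence))
  writeLines(md, file.path(dir, "evidence_report.md"))
  for (nm in names(result$per_locus)) {
    write_networks(result$per_locus[[nm]]$networks,
                   file.path(dir, paste0("networks_", nm, ".tsv")))
    if (!is.null(result$per_locus[[nm]]$distances)) {
      write_distance_matrix(result$per_locus[[nm]]$distances,
                            file.path(dir, paste0("distances_", nm, ".tsv")))
    }
  }
  invisible(dir)
}
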