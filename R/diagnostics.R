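#' Map an alignment column to a sequence position
#'
#' Converts a 1-based alignment column into the 1-based position in a given
#' specimen's ungapped sequence (the coordinate printed in brackets in
#' nucleotide-based diagnoses): the count of non-gap characters in that
#' specimen's row from column 1 through the column.
#'
#' @param aln a [dna_alignment].
#' @param specimen_id the reference (for example the holotype) specimen.
#' @param aln_pos 1-based alignment column; the specimen must hold a
#'   non-gap state there.
#' @return integer sequence position.
#' @export
map_alignment_position <- function(aln, specimen_id, aln_pos) {
  if (!specimen_id %in% rownames(aln)) stop("unknown specimen ", specimen_id)
  if (aln_pos < 1 || aln_pos > ncol(aln)) {
    stop("alignment position ", aln_pos, " outside 1..", ncol(aln))
  }
  row <- unclass(aln)[specimen_id, ]
  if (row[aln_pos] == "-") {
    stop("specimen ", specimen_id, " has a gap at column ", aln_pos,
         ": no sequence coordinate")
  }
  sum(row[seq_len(aln_pos)] != "-")
}

#' Diagnostic nucleotide positions for a species
#'
#' Finds pure diagnostic characters: alignment columns at which every
#' sequence of the focal species carries one identical unambiguous state
#' that no sequence of any other species carries.  Non-focal gaps count as
#' a distinct (fifth) state, so a base-versus-gap contrast can be
#' diagnostic; non-focal missing or ambiguous states are treated as
#' unresolved and ignored.  Under the strict default policy a column with
#' any missing or ambiguous focal state is excluded, and a focal gap blocks
#' a substitution diagnostic but contributes to \emph{insert} diagnostics:
#' maximal runs of columns where all focal sequences share bases and every
#' resolved non-focal sequence is gapped are reported as a single insert
#' character with a column range and the inserted string.
#'
#' Positions are reported in dual coordinates: the 1-based alignment column
#' (range for inserts) and the corresponding position in the designated
#' reference specimen's ungapped sequence.
#'
#' @param aln a [dna_alignment].
#' @param partition partition tibble or named vector covering the aligned
#'   specimens (specimens without a group are ignored as comparison
#'   material is undefined for them).
#' @param focal_species group label to diagnose.
#' @param ref_id reference specimen (must belong to the focal species);
#'   defaults to its first specimen.
#' @return tibble with columns \code{species}, \code{locus},
#'   \code{aln_start}, \code{aln_end}, \code{ref_start}, \code{ref_end},
#'   \code{state}, \code{kind} (\code{"substitution"} or \code{"insert"});
#'   zero rows when the species has no diagnostic character at this locus.
#' @export
diagnostic_positions <- function(aln, partition, focal_species,
                                 ref_id = NULL) {
  partition <- as_partition(partition)
  focal_ids <- intersect(rownames(aln),
                         partition$specimen_id[partition$group == focal_species])
  if (!length(focal_ids)) stop("focal species has no sequence at this locus")
  other_ids <- intersect(rownames(aln),
                         partition$specimen_id[partition$group != focal_species])
  if (is.null(ref_id)) ref_id <- focal_ids[1]
  if (!ref_id %in% focal_ids) {
    stop("reference specimen ", ref_id, " is not in species ", focal_species)
  }
  e <- encode_alignment(aln)
  fo <- e[focal_ids, , drop = FALSE]
  ot <- e[other_ids, , drop = FALSE]
  pure_base <- c(1L, 2L, 4L, 8L)

  # per column, is every focal state the same unambiguous base?
  f_first <- fo[1, ]
  f_same <- colSums(fo != rep(f_first, each = nrow(fo))) == 0L
  f_base <- f_same & f_first %in% pure_base
  f_allgapless <- colSums(fo == .GAP) == 0L

  # non-focal resolved states: bases and gaps; missing/ambiguity unresolved
  o_resolved <- matrix(ot %in% c(pure_base, .GAP), nrow = nrow(ot))
  o_state_hits <- function(col, state) {
    res <- o_resolved[, col]
    any(ot[res, col] == state)
  }
  ncol_a <- ncol(e)
  subst <- logical(ncol_a)
  for (col in which(f_base & f_allgapless)) {
    subst[col] <- !o_state_hits(col, f_first[col])
  }

  # insert columns: focal all base (identical), all resolved others gapped
  o_all_gap <- vapply(seq_len(ncol_a), function(col) {
    res <- o_resolved[, col]
    any(res) && all(ot[res, col] == .GAP)
  }, TRUE)
  insert_col <- f_base & o_all_gap

  chars <- list()
  base_letter <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T")
  for (col in which(subst & !insert_col)) {
    chars[[length(chars) + 1L]] <- tibble::tibble(
      aln_start = col, aln_end = col,
      state = base_letter[[as.character(f_first[col])]],
      kind = "substitution")
  }
  # maximal runs of insert columns
  if (any(insert_col)) {
    r <- rle(insert_col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      cols <- starts[k]:ends[k]
      chars[[length(chars) + 1L]] <- tibble::tibble(
        aln_start = starts[k], aln_end = ends[k],
        state = paste(base_letter[as.character(f_first[cols])], collapse = ""),
        kind = "insert")
    }
  }
  if (!length(chars)) {
    return(tibble::tibble(species = character(), locus = character(),
                          aln_start = integer(), aln_end = integer(),
                          ref_start = integer(), ref_end = integer(),
                          state = character(), kind = character()))
  }
  out <- dplyr::arrange(dplyr::bind_rows(chars), .data$aln_start)
  out$ref_start <- vapply(out$aln_start, function(p) {
    map_alignment_position(aln, ref_id, p)
  }, 0L)
  out$ref_end <- vapply(out$aln_end, function(p) {
    map_alignment_position(aln, ref_id, p)
  }, 0L)
  tibble::tibble(species = focal_species,
                 locus = attr(aln, "locus_name") %||% "",
                 out[, c("aln_start", "aln_end", "ref_start", "ref_end",
                         "state", "kind")])
}

#' Diagnostic characters for every species over every locus
#'
#' Convenience wrapper applying [diagnostic_positions()] to each species at
#' each locus of a dataset.  Reference specimens default to the
#' holotype/neotype recorded in the specimen table, else the species' first
#' specimen at the locus.  Diagnostics are relative to the sampled
#' comparison set: they hold against the other species in this dataset.
#'
#' @param dataset a \code{multilocus_dataset}.
#' @param partition partition tibble or named vector.
#' @return tibble as in [diagnostic_positions()], all species and loci
#'   combined; species lacking any diagnostic at a locus simply contribute
#'   no rows there.
#' @export
diagnostic_table <- function(dataset, partition) {
  partition <- as_partition(partition)
  groups <- sort(unique(partition$group))
  types <- dataset$specimens
  purrr::map_dfr(names(dataset$loci), function(nm) {
    aln <- dataset$loci[[nm]]
    purrr::map_dfr(groups, function(g) {
      ids <- intersect(rownames(aln),
                       partition$specimen_id[partition$group == g])
      if (!length(ids)) return(NULL)
      ref <- ids[1]
      ty <- types$specimen_id[types$type_status %in% c("holotype", "neotype") &
                                types$specimen_id %in% ids]
      if (length(ty)) ref <- ty[1]
      diagnostic_positions(aln, partition, g, ref_id = ref)
    })
  })
}

#' Write diagnostic characters to disk
#'
#' TSV plus a Markdown rendering of the per-species diagnostic characters.
#' The header records that positions are 1-based and that diagnostics are
#' relative to the sampled comparison set.
#'
#' @param diagnostics tibble from [diagnostic_table()].
#' @param path output TSV path; the Markdown file takes the same path with
#'   a \code{.md} extension.
#' @export
write_diagnostics <- function(diagnostics, path) {
  hdr <- paste("# diagnostic characters; 1-based inclusive positions;",
               "valid relative to the sampled comparison species")
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(diagnostics, path, append = TRUE,
                                    col_names = TRUE))
  md_path <- sub("\\.[^.]*$", ".md", path)
  writeLines(c("# Diagnostic characters", "", sub("^# ", "", hdr), "",
               knit_md_table(diagnostics)), md_path)
  invisible(path)
}

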