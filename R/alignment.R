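# IUPAC nucleotide codes as bitmasks over A=1, C=2, G=4, T=8.
# Gap ('-') is code 16; missing ('?' and 'N') is code 0.  'U' is read as 'T'.
.iupac_mask <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 0L, `?` = 0L, `-` = 16L
)

.GAP <- 16L
.MISSING <- 0L

.valid_chars <- names(.iupac_mask)

#' Construct a DNA alignment
#'
#' An alignment is stored as an upper-case character matrix (specimens in
#' rows, alignment columns in columns) over the alphabet
#' \code{A C G T}, the IUPAC ambiguity codes, \code{-} (gap) and
#' \code{?}/\code{N} (missing).  All positions are 1-based and inclusive
#' throughout the package.
#'
#' @param x named character vector of equal-length sequences, or a character
#'   matrix with specimen ids as row names.
#' @param locus_name name of the locus the alignment represents.
#' @return an object of class \code{dna_alignment}.
#' @export
dna_alignment <- function(x, locus_name = "locus") {
  if (is.character(x) && !is.matrix(x)) {
    ids <- names(x)
    if (is.null(ids)) stop("sequences must be named by specimen id")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      bad <- ids[which(lens != lens[1])[1]]
      stop("alignment records differ in length: record '", bad,
           "' has ", nchar(x[bad]), " columns, expected ", lens[1])
    }
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- ids
  } else if (is.matrix(x)) {
    m <- toupper(x)
    if (is.null(rownames(m))) stop("alignment matrix must have specimen row names")
  } else {
    stop("x must be a named character vector or character matrix")
  }
  m[m == "U"] <- "T"
  if (anyDuplicated(rownames(m))) {
    stop("duplicate specimen ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  bad <- setdiff(unique(as.vector(m)), .valid_chars)
  if (length(bad)) {
    stop("invalid characters in alignment: ", paste(bad, collapse = " "))
  }
  structure(m, class = "dna_alignment", locus_name = locus_name)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment> locus '", attr(x, "locus_name"), "': ",
      nrow(x), " specimens x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

#' @rdname dna_alignment
#' @param aln a \code{dna_alignment}.
#' @export
locus_name <- function(aln) attr(aln, "locus_name")

#' Number of alignment columns
#' @param aln a \code{dna_alignment}.
#' @export
n_columns <- function(aln) ncol(aln)

#' Specimen ids of an alignment
#' @param aln a \code{dna_alignment}.
#' @export
specimen_ids <- function(aln) rownames(aln)

# Integer-encode an alignment (bitmask matrix; see .iupac_mask).
encode_alignment <- function(aln) {
  e <- .iupac_mask[aln]
  dim(e) <- dim(aln)
  rownames(e) <- rownames(aln)
  e
}

# subset rows, keeping class/attributes
subset_alignment <- function(aln, ids) {
  m <- unclass(aln)[ids, , drop = FALSE]
  structure(m, class = "dna_alignment", locus_name = attr(aln, "locus_name"))
}

#' Read an aligned FASTA file
#'
#' Records must all have the same length.  Sequences are upper-cased and
#' \code{U} is mapped to \code{T}; record order is preserved.
#'
#' @param path path to an aligned FASTA file.
#' @param locus_name locus label attached to the alignment (defaults to the
#'   file name without extension).
#' @return a [dna_alignment].
#' @export
read_alignment <- function(path, locus_name = NULL) {
  if (is.null(locus_name)) {
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(ss)
  # FASTA headers may carry descriptions after whitespace; the id is word 1
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  dna_alignment(seqs, locus_name = locus_name)
}

#' Write an alignment as FASTA
#' @param aln a [dna_alignment].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Expects a TSV with header
#' \code{specimen_id  clade  locality  outgroup  type_status}.
#'
#' @param path path to the TSV file.
#' @return a tibble with columns \code{specimen_id}, \code{clade},
#'   \code{locality}, \code{is_outgroup} (logical) and \code{type_status}.
#' @export
read_specimen_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("specimen_id", "clade", "locality", "outgroup", "type_status")
  missing <- setdiff(required, names(tb))
  if (length(missing)) stop("specimen table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(tb$specimen_id)) {
    stop("duplicate specimen ids in table: ",
         paste(unique(tb$specimen_id[duplicated(tb$specimen_id)]), collapse = ", "))
  }
  tibble::tibble(
    specimen_id = tb$specimen_id,
    clade = dplyr::coalesce(tb$clade, ""),
    locality = dplyr::coalesce(tb$locality, ""),
    is_outgroup = tolower(dplyr::coalesce(tb$outgroup, "false")) %in% c("true", "yes", "1"),
    type_status = dplyr::coalesce(tb$type_status, "none")
  )
}

#' Write a specimen metadata table
#' @param specimens tibble as returned by [read_specimen_table()].
#' @param path output path.
#' @export
write_specimen_table <- function(specimens, path) {
  out <- tibble::tibble(
    specimen_id = specimens$specimen_id,
    clade = specimens$clade,
    locality = specimens$locality,
    outgroup = ifelse(specimens$is_outgroup, "true", "false"),
    type_status = specimens$type_status
  )
  readr::write_tsv(out, path)
  invisible(path)
}
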