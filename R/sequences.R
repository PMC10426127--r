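#' One-hot encode a DNA sequence
#'
#' Encodes an uppercase DNA string as a 4 x L binary matrix with channel
#' (row) order A, C, G, T. Each A/C/G/T position contributes exactly one 1;
#' an `N` yields an all-zero column, so ambiguous positions carry no signal
#' into the convolution.
#'
#' @param seq A single uppercase DNA string over the alphabet ACGTN.
#' @return A 4 x nchar(seq) numeric matrix with rownames A, C, G, T.
#' @examples
#' one_hot_encode("ACGT")
#' @export
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(ch), c(NUCLEOTIDES, "N"))
  if (length(bad) > 0) {
    stop("sequence contains characters outside ACGTN: ", paste(bad, collapse = ", "))
  }
  X <- matrix(0, nrow = 4L, ncol = length(ch), dimnames = list(NUCLEOTIDES, NULL))
  idx <- match(ch, NUCLEOTIDES)
  keep <- !is.na(idx)
  X[cbind(idx[keep], which(keep))] <- 1
  X
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot_encode()]; all-zero columns decode to `N`.
#'
#' @param mat A 4 x L one-hot matrix (rows A, C, G, T).
#' @return A DNA string.
#' @export
one_hot_decode <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == 4L)
  idx <- apply(mat, 2L, function(col) {
    w <- which(col == 1)
    if (length(w) == 1L) w else NA_integer_
  })
  paste(ifelse(is.na(idx), "N", NUCLEOTIDES[idx]), collapse = "")
}

#' Construct a sequence set
#'
#' Bundles equal-length uppercase DNA sequences with their identifiers and a
#' 4 x L x n one-hot tensor. Records containing `N` are dropped with a
#' warning, matching the promoter-extraction convention; to keep them,
#' encode with [one_hot_encode()] directly (N becomes an all-zero column).
#'
#' @param sequences Character vector of equal-length DNA strings.
#' @param ids Identifiers, one per sequence (defaults to `names(sequences)`).
#' @param drop_n Drop sequences containing N? Default TRUE.
#' @return An object of class `sequence_set` with elements `ids`,
#'   `sequences`, `onehot` (4 x L x n array) and `length`.
#' @export
sequence_set <- function(sequences, ids = names(sequences), drop_n = TRUE) {
  stopifnot(is.character(sequences), length(sequences) > 0)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  stopifnot(length(ids) == length(sequences))
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  sequences <- toupper(sequences)
  if (drop_n) {
    has_n <- grepl("N", sequences, fixed = TRUE)
    if (any(has_n)) {
      warning(sum(has_n), " sequence(s) containing N dropped")
      sequences <- sequences[!has_n]
      ids <- ids[!has_n]
    }
  }
  if (length(sequences) == 0) stop("no sequences left after N filtering")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must all have equal length")
  onehot <- array(0, dim = c(4L, L, length(sequences)),
                  dimnames = list(NUCLEOTIDES, NULL, ids))
  for (i in seq_along(sequences)) onehot[, , i] <- one_hot_encode(sequences[i])
  structure(
    list(ids = ids, sequences = setNames(sequences, ids),
         onehot = onehot, length = L),
    class = "sequence_set"
  )
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set> ", length(x$ids), " sequences of length ", x$length, " nt\n", sep = "")
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$ids)

#' Read a FASTA file of equal-length sequences
#'
#' @param path FASTA file path.
#' @param drop_n Drop N-containing records? Default TRUE.
#' @return A [sequence_set()].
#' @export
read_sequence_fasta <- function(path, drop_n = TRUE) {
  dss <- Biostrings::readDNAStringSet(path)
  sequence_set(as.character(dss), ids = names(dss), drop_n = drop_n)
}

#' Write a sequence set to FASTA
#'
#' @param seqs A [sequence_set()].
#' @param path Output file path.
#' @export
write_sequence_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(seqs$sequences)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a region/gene table
#'
#' Reads a TSV with columns `chromosome`, `anchor`, `strand`, `id` (extra
#' columns are kept). `coord_base` declares the coordinate convention of the
#' `anchor` column: 1 for Ensembl-style gene tables (default), 0 for
#' BED-like half-open coordinates. Anchors are converted to 0-based
#' internally.
#'
#' @param path TSV path.
#' @param coord_base 0 or 1 (default 1).
#' @return A tibble with a 0-based `anchor` column.
#' @export
read_region_table <- function(path, coord_base = 1) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  region_table(tbl, coord_base = coord_base)
}

#' Validate a region table
#'
#' @param tbl Data frame with columns `chromosome`, `anchor`, `strand`, `id`.
#' @param coord_base Coordinate base of `anchor` (0 or 1); converted to
#'   0-based.
#' @return A validated tibble, `anchor` 0-based.
#' @export
region_table <- function(tbl, coord_base = 0) {
  required <- c("chromosome", "anchor", "strand", "id")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("region table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(coord_base %in% c(0, 1))
  tbl <- tibble::as_tibble(tbl)
  tbl$anchor <- as.numeric(tbl$anchor) - coord_base
  if (any(is.na(tbl$anchor)) || any(tbl$anchor < 0)) {
    stop("anchors must be non-negative coordinates")
  }
  if (!all(tbl$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(tbl$id)) stop("region ids must be unique")
  tbl
}

#' Extract fixed-width windows around genomic anchors
#'
#' Cuts strand-aware windows around each region anchor (for genes, the
#' strand-aware transcription start site). For a `+` strand record the
#' window is `[anchor - window_up, anchor + window_down)` in 0-based
#' half-open coordinates; for a `-` strand record the reverse complement of
#' `[anchor - window_down, anchor + window_up)` is returned, so every
#' sequence reads 5' to 3' with `window_up` nt upstream of the anchor.
#' Records that fall outside chromosome bounds, name a missing chromosome,
#' or contain N are dropped with a warning.
#'
#' @param genome A FASTA path or a named `Biostrings::DNAStringSet`.
#' @param regions A validated [region_table()] (anchors 0-based).
#' @param window_up,window_down Window extent in nt upstream/downstream of
#'   the anchor. Defaults 500/500 (1-kb promoter windows); use 120/120 for
#'   peak-midpoint windows.
#' @return A [sequence_set()] of length `window_up + window_down` windows.
#' @export
extract_window_sequences <- function(genome, regions, window_up = 500, window_down = 500) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  # FASTA headers often carry descriptions; key on the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_len <- setNames(Biostrings::width(genome), names(genome))

  out_seq <- character(nrow(regions))
  keep <- logical(nrow(regions))
  n_missing <- 0L; n_oob <- 0L
  for (i in seq_len(nrow(regions))) {
    chr <- regions$chromosome[i]
    if (!chr %in% names(genome)) { n_missing <- n_missing + 1L; next }
    a <- regions$anchor[i]
    if (regions$strand[i] == "+") {
      start0 <- a - window_up; end0 <- a + window_down      # [start0, end0)
    } else {
      start0 <- a - window_down; end0 <- a + window_up
    }
    if (start0 < 0 || end0 > chrom_len[[chr]]) { n_oob <- n_oob + 1L; next }
    s <- as.character(Biostrings::subseq(genome[[chr]], start = start0 + 1L, end = end0))
    if (regions$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    out_seq[i] <- s
    keep[i] <- TRUE
  }
  if (n_missing > 0) warning(n_missing, " record(s) dropped: chromosome not in genome")
  if (n_oob > 0) warning(n_oob, " record(s) dropped: window out of chromosome bounds")
  if (!any(keep)) stop("no extractable regions")
  sequence_set(toupper(out_seq[keep]), ids = regions$id[keep], drop_n = TRUE)
}
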