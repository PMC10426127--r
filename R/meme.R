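#' Write motifs to a MEME minimal-format file
#'
#' Writes position probability matrices as a single MEME minimal format
#' (version 4) file with ACGT alphabet and uniform 0.25 background, the
#' format consumed by Tomtom and the rest of the MEME suite.
#'
#' @param motifs A named list of 4 x m PPMs (rows A, C, G, T, columns
#'   summing to 1), or a `motif_set` tibble from [extract_pfms()] (written
#'   as `<run>_<filter>` records with a small pseudocount to avoid zero
#'   probabilities).
#' @param path Output file path.
#' @param nsites Optional per-motif site counts (recycled); defaults to the
#'   `n_contributing` column for motif sets, else 20.
#' @return The path, invisibly.
#' @export
write_meme <- function(motifs, path, nsites = NULL) {
  if (inherits(motifs, "motif_set")) {
    keep <- !motifs$empty
    if (!all(keep)) message(sum(!keep), " empty motif(s) omitted from MEME output")
    motifs <- motifs[keep, ]
    nsites <- nsites %||% motifs$n_contributing
    ppms <- setNames(lapply(motifs$ppm, meme_pseudocount), motifs$motif)
  } else {
    stopifnot(is.list(motifs))
    if (is.null(names(motifs))) stop("motif list must be named")
    ppms <- motifs
  }
  if (is.null(nsites)) nsites <- rep(20L, length(ppms))
  nsites <- rep_len(nsites, length(ppms))
  for (nm in names(ppms)) {
    ppm <- ppms[[nm]]
    if (!is.matrix(ppm) || nrow(ppm) != 4L) stop("PPM '", nm, "' is not a 4-row matrix")
    if (any(abs(colSums(ppm) - 1) > 1e-6)) stop("PPM '", nm, "' has columns not summing to 1")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", ""
  ), con)
  for (k in seq_along(ppms)) {
    ppm <- ppms[[k]]
    writeLines(sprintf("MOTIF %s", names(ppms)[k]), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(ppm), nsites[k]), con)
    # MEME rows are positions, columns A C G T
    writeLines(apply(t(ppm), 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

# pseudocount applied only at MEME export so written probabilities are
# never exactly zero (Tomtom log-odds dislike zeros); extraction itself
# uses plain count division
meme_pseudocount <- function(ppm, eps = 1e-4) {
  sweep(ppm + eps, 2L, colSums(ppm + eps), "/")
}

#' Read a MEME minimal-format motif file
#'
#' Parses MEME minimal format (as written by [write_meme()] or exported
#' from motif databases such as CIS-BP) into a named list of 4 x m PPMs.
#'
#' @param path MEME file path.
#' @return Named list of 4 x m matrices with rownames A, C, G, T.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motif_starts <- grep("^MOTIF\\s+", lines)
  if (length(motif_starts) == 0) stop("no MOTIF records found in ", path)
  out <- list()
  for (s in motif_starts) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]][1]
    hdr <- s + 1L
    while (hdr <= length(lines) && !grepl("^letter-probability matrix", lines[hdr])) hdr <- hdr + 1L
    if (hdr > length(lines)) stop("motif '", name, "' has no letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    if (any(vapply(vals, length, 1L) != 4L)) stop("malformed matrix row in motif '", name, "'")
    ppm <- t(do.call(rbind, vals))
    rownames(ppm) <- NUCLEOTIDES
    if (any(abs(colSums(ppm) - 1) > 1e-4)) {
      stop("motif '", name, "' columns do not sum to 1")
    }
    out[[name]] <- ppm
  }
  out
}
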