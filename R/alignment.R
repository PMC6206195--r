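#' DNA alignment objects
#'
#' A `dna_alignment` is a character matrix of single upper-case characters
#' over the alphabet `A C G T - N`, one row per sequence, with unique
#' rownames giving the sequence identifiers. All rows have the same number
#' of columns (the alignment length in bp). `N` is stored as a valid state
#' but is treated as missing data by every downstream statistic; `-` marks
#' an alignment gap.
#'
#' @param x character matrix of single characters, or a named character
#'   vector of equal-length sequence strings.
#' @return A validated `dna_alignment` object.
#' @examples
#' aln <- dna_alignment(c(a = "ACGT", b = "AC-T"))
#' aln_length(aln)
#' @export
dna_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      ds_stop("sequences must be named", "identifier_error")
    }
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      ds_stop(sprintf("sequences differ in length (%s)",
                      paste(unique(lens), collapse = ", ")),
              "alignment_shape_error")
    }
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
    x <- m
  }
  if (!is.matrix(x) || !is.character(x)) {
    ds_stop("alignment must be a character matrix", "alignment_shape_error")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    ds_stop("alignment must have at least one row and one column",
            "empty_alignment_error")
  }
  if (is.null(rownames(x))) {
    ds_stop("alignment rows must be named", "identifier_error")
  }
  if (anyDuplicated(rownames(x))) {
    ds_stop(sprintf("duplicate sequence identifiers: %s",
                    paste(unique(rownames(x)[duplicated(rownames(x))]),
                          collapse = ", ")),
            "identifier_error")
  }
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), DNA_ALPHABET)
  if (length(bad) > 0L) {
    ds_stop(sprintf("illegal character(s) in alignment: %s",
                    paste(bad, collapse = ", ")),
            "alphabet_error")
  }
  structure(x, class = c("dna_alignment", "matrix", "array"))
}

#' @rdname dna_alignment
#' @param aln a `dna_alignment`.
#' @export
aln_length <- function(aln) ncol(aln)

#' @rdname dna_alignment
#' @export
aln_names <- function(aln) rownames(aln)

#' Collapse alignment rows to sequence strings
#'
#' @param aln a `dna_alignment`.
#' @return Named character vector of sequence strings, in row order.
#' @export
aln_strings <- function(aln) {
  out <- apply(unclass(aln), 1L, paste0, collapse = "")
  names(out) <- rownames(aln)
  out
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d sequences x %d bp\n", nrow(x), ncol(x)))
  show <- utils::head(aln_strings(x), 5L)
  trunc <- function(s) if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  for (i in seq_along(show)) {
    cat(sprintf("  %-12s %s\n", names(show)[i], trunc(show[[i]])))
  }
  if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  invisible(x)
}

#' Read a FASTA alignment
#'
#' Reads an aligned FASTA file (arbitrary line wrapping) into a
#' [dna_alignment()]. Input order is preserved, lower case is folded to
#' upper case, and any character outside `A C G T - N` is rejected —
#' ambiguous IUPAC codes other than `N` are not silently recoded.
#'
#' @param path path to a FASTA file.
#' @return A `dna_alignment`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    ds_stop(sprintf("file not found: %s", path), "io_error")
  }
  # BStringSet keeps record content verbatim, so illegal characters are
  # caught by validation instead of being silently recoded or dropped
  seqs <- as.character(Biostrings::readBStringSet(path))
  if (length(seqs) == 0L) {
    ds_stop(sprintf("no FASTA records in %s", path), "io_error")
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # id = first header token
  if (anyDuplicated(names(seqs))) {
    ds_stop(sprintf("duplicate identifiers in %s", path), "identifier_error")
  }
  dna_alignment(seqs)
}

#' Write a FASTA alignment
#'
#' Writes a [dna_alignment()] with 60-column line wrapping. Round-trips
#' exactly through [read_fasta()].
#'
#' @param aln a `dna_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqs <- aln_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Eliminate gap positions
#'
#' Removes every alignment column in which at least one sequence has a gap
#' (`-`), keeping all other columns in order. This reduces a gappy alignment
#' (e.g. a D-loop fragment whose flanks align poorly across individuals) to
#' its common gap-free core; the full Gblocks conservation/flank machinery
#' is deliberately not applied.
#'
#' @param aln a `dna_alignment`.
#' @return A `dna_alignment` with the gap-containing columns removed.
#' @examples
#' aln <- dna_alignment(c(a = "AC-T", b = "ACGT"))
#' aln_strings(eliminate_gap_positions(aln))  # both rows "ACT"
#' @export
eliminate_gap_positions <- function(aln) {
  aln <- dna_alignment(aln)
  keep <- colSums(unclass(aln) == "-") == 0L
  if (!any(keep)) {
    ds_stop("every column contains a gap; empty alignment would result",
            "empty_alignment_error")
  }
  dna_alignment(unclass(aln)[, keep, drop = FALSE])
}

#' Concatenate gene partitions with missing-data padding
#'
#' Concatenates several single-gene alignments into one supermatrix. A
#' specimen absent from a partition (e.g. one for which only cytochrome b
#' could be sequenced) is padded with the missing symbol `N` across that
#' partition's columns. Row order: specimens in order of first appearance
#' across the partitions.
#'
#' @param parts list of `dna_alignment` objects, one per gene partition.
#'   Names of the list become partition labels (defaults `part1`, ...).
#' @param pad single missing-data character, `"N"` by default.
#' @return A list with components `alignment` (the concatenated
#'   `dna_alignment`) and `partitions` (data.frame with columns `name`,
#'   `start`, `end`: 0-based half-open column intervals in input order).
#' @examples
#' cytb <- dna_alignment(c(a = "ACG", b = "TTT"))
#' dloop <- dna_alignment(c(a = "GG"))
#' cc <- concatenate_alignments(list(cytb = cytb, dloop = dloop))
#' aln_strings(cc$alignment)  # b is padded to "TTTNN"
#' cc$partitions
#' @export
concatenate_alignments <- function(parts, pad = "N") {
  if (!is.list(parts) || length(parts) == 0L) {
    ds_stop("at least one partition is required", "parameter_error")
  }
  if (!is.character(pad) || length(pad) != 1L || nchar(pad) != 1L ||
      !(toupper(pad) %in% DNA_ALPHABET)) {
    ds_stop(sprintf("pad symbol must be one of %s",
                    paste(DNA_ALPHABET, collapse = " ")),
            "alphabet_error")
  }
  pad <- toupper(pad)
  parts <- lapply(parts, dna_alignment)
  labels <- names(parts) %||% rep(NA_character_, length(parts))
  labels[is.na(labels) | labels == ""] <-
    paste0("part", seq_along(parts))[is.na(labels) | labels == ""]

  all_names <- unique(unlist(lapply(parts, rownames), use.names = FALSE))
  lens <- vapply(parts, ncol, integer(1))
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])

  out <- matrix(pad, nrow = length(all_names), ncol = sum(lens),
                dimnames = list(all_names, NULL))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    out[rownames(p), (starts[i] + 1L):ends[i]] <- unclass(p)
  }
  list(
    alignment = dna_alignment(out),
    partitions = data.frame(name = unname(labels), start = unname(starts),
                            end = unname(ends), stringsAsFactors = FALSE)
  )
}

#' Extract one partition from a concatenated alignment
#'
#' @param aln concatenated `dna_alignment`.
#' @param partition one row of the `partitions` data.frame produced by
#'   [concatenate_alignments()] (or any list with 0-based half-open
#'   `start`/`end`).
#' @return The `dna_alignment` slice covering that partition's columns.
#' @export
extract_partition <- function(aln, partition) {
  aln <- dna_alignment(aln)
  s <- partition$start; e <- partition$end
  if (s < 0 || e > ncol(aln) || s >= e) {
    ds_stop("partition interval out of range", "parameter_error")
  }
  dna_alignment(unclass(aln)[, (s + 1L):e, drop = FALSE])
}

#' Write a partition table as TSV
#'
#' @param partitions data.frame from [concatenate_alignments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_table <- function(partitions, path) {
  utils::write.table(partitions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
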