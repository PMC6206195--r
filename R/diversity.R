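# Core population-genetic estimators. A site is "comparable" for a pair of
# sequences iff both characters are in {A,C,G,T}; N and '-' are missing data
# (pairwise deletion). Watterson's theta instead uses complete deletion so
# that S and L stay consistent.

# Coerce sequences to a character matrix of single characters.
# Accepts a dna_alignment, a named/unnamed character vector of strings,
# or an already-split character matrix.
.as_rows <- function(x) {
  if (inherits(x, "dna_alignment")) return(unclass(x))
  if (is.matrix(x) && is.character(x)) return(x)
  if (is.character(x) && length(x) == 0L) {
    ds_stop("no sequences supplied", "insufficient_sample_error")
  }
  if (is.character(x)) {
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      ds_stop("sequences differ in length", "alignment_shape_error")
    }
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
    return(m)
  }
  ds_stop("cannot interpret sequences", "parameter_error")
}

# n x n matrices of comparable-site counts and mismatch counts, via
# crossproducts of per-base indicator matrices (fast for n in the hundreds).
.pair_counts <- function(m) {
  valid <- m %in% DNA_BASES
  dim(valid) <- dim(m)
  V <- matrix(as.numeric(valid), nrow(m))
  comparable <- tcrossprod(V)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in DNA_BASES) {
    I <- matrix(as.numeric(m == b & valid), nrow(m))
    matches <- matches + tcrossprod(I)
  }
  list(comparable = comparable, diff = comparable - matches)
}

# p-distance matrix with pairwise deletion; errors if any off-diagonal pair
# has no comparable site.
.p_matrix <- function(m) {
  pc <- .pair_counts(m)
  off <- upper.tri(pc$comparable)
  if (any(pc$comparable[off] == 0)) {
    ds_stop("a sequence pair shares no comparable (A/C/G/T vs A/C/G/T) site",
            "undefined_distance_error")
  }
  p <- pc$diff / pc$comparable
  diag(p) <- 0
  dimnames(p) <- list(rownames(m), rownames(m))
  p
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among comparable sites, where a site is
#' comparable iff both characters are `A`, `C`, `G` or `T` (pairwise
#' deletion of `N` and gaps).
#'
#' @param a,b aligned sequences of equal length, as strings or character
#'   vectors of single characters.
#' @return Proportion in `[0, 1]`.
#' @examples
#' pairwise_p_distance("ACGT", "ACGA")  # 0.25
#' pairwise_p_distance("ACGN", "ACTA")  # 1/3: N site is dropped
#' @export
pairwise_p_distance <- function(a, b) {
  a <- .one_seq(a); b <- .one_seq(b)
  if (length(a) != length(b)) {
    ds_stop("sequences differ in length", "alignment_shape_error")
  }
  comp <- a %in% DNA_BASES & b %in% DNA_BASES
  if (!any(comp)) {
    ds_stop("no comparable site between the two sequences",
            "undefined_distance_error")
  }
  sum(a[comp] != b[comp]) / sum(comp)
}

.one_seq <- function(x) {
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L) {
    x <- strsplit(x, "", fixed = TRUE)[[1]]
  }
  toupper(x)
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise p-distance over all n(n-1)/2 unordered sequence pairs,
#' with pairwise deletion of missing data — the per-site probability that
#' two sequences drawn from the sample differ.
#'
#' @param rows sequences: a `dna_alignment`, character vector of strings,
#'   or character matrix.
#' @return Per-site nucleotide diversity (non-negative).
#' @examples
#' nucleotide_diversity(c("ACGT", "ACGA", "ACCA"))  # 1/3
#' @export
nucleotide_diversity <- function(rows) {
  m <- .as_rows(rows)
  if (nrow(m) < 2L) {
    ds_stop("nucleotide diversity needs at least 2 sequences",
            "insufficient_sample_error")
  }
  p <- .p_matrix(m)
  mean(p[upper.tri(p)])
}

#' Watterson's theta
#'
#' `S / (a_n * L)` where `S` counts segregating sites, `a_n` is the
#' harmonic number `sum(1/i, i = 1..n-1)`, and `L` is the number of sites
#' retained after complete deletion of every column containing a non-ACGT
#' character.
#'
#' @inheritParams nucleotide_diversity
#' @return Per-site Watterson estimate.
#' @export
watterson_theta <- function(rows) {
  m <- .as_rows(rows)
  n <- nrow(m)
  if (n < 2L) {
    ds_stop("Watterson's theta needs at least 2 sequences",
            "insufficient_sample_error")
  }
  valid_col <- colSums(matrix(!(m %in% DNA_BASES), nrow(m))) == 0L
  L <- sum(valid_col)
  if (L == 0L) {
    ds_stop("no column free of missing data; theta undefined",
            "undefined_distance_error")
  }
  mm <- m[, valid_col, drop = FALSE]
  S <- sum(apply(mm, 2L, function(col) length(unique(col)) > 1L))
  a_n <- sum(1 / seq_len(n - 1L))
  S / (a_n * L)
}

#' Haplotype diversity
#'
#' `(n/(n-1)) * (1 - sum(f_k^2))` over the relative frequencies `f_k` of
#' bitwise-identical sequences.
#'
#' @inheritParams nucleotide_diversity
#' @return Haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(rows) {
  m <- .as_rows(rows)
  n <- nrow(m)
  if (n < 2L) {
    ds_stop("haplotype diversity needs at least 2 sequences",
            "insufficient_sample_error")
  }
  haps <- apply(m, 1L, paste0, collapse = "")
  f <- table(haps) / n
  (n / (n - 1)) * (1 - sum(f^2))
}

#' Mean p-distance between two groups of sequences
#'
#' Mean of [pairwise_p_distance()] over all cross pairs (one sequence from
#' each group); the standard between-lineage divergence summary.
#'
#' @param rows_a,rows_b sequences of the two groups (any form accepted by
#'   [nucleotide_diversity()]).
#' @return Mean proportion of differing comparable sites.
#' @export
between_group_p_distance <- function(rows_a, rows_b) {
  a <- .as_rows(rows_a); b <- .as_rows(rows_b)
  if (nrow(a) < 1L || nrow(b) < 1L) {
    ds_stop("both groups must be non-empty", "insufficient_sample_error")
  }
  if (ncol(a) != ncol(b)) {
    ds_stop("groups come from alignments of different length",
            "alignment_shape_error")
  }
  rownames(a) <- paste0("a", seq_len(nrow(a)))
  rownames(b) <- paste0("b", seq_len(nrow(b)))
  p <- .p_matrix(rbind(a, b))
  mean(p[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b))])
}

#' Pairwise genetic distance matrix
#'
#' Distances between all sequence pairs of an alignment under the selected
#' model, with pairwise deletion of non-ACGT characters. `"p"` is the raw
#' proportion of differing sites (computed here); `"JC69"` and `"K80"` are
#' the standard one- and two-parameter corrections (via [ape::dist.dna()]).
#'
#' @param aln a `dna_alignment` (or anything [nucleotide_diversity()]
#'   accepts) with at least 2 sequences.
#' @param model `"p"`, `"JC69"` or `"K80"`.
#' @return Symmetric numeric matrix with sequence names as dimnames.
#' @export
distance_matrix <- function(aln, model = c("p", "JC69", "K80")) {
  model <- match.arg(model)
  m <- .as_rows(aln)
  if (nrow(m) < 2L) {
    ds_stop("a distance matrix needs at least 2 sequences",
            "insufficient_sample_error")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  if (model == "p") return(.p_matrix(m))
  dna <- ape::as.DNAbin(tolower(m))
  d <- suppressWarnings(
    ape::dist.dna(dna, model = model, pairwise.deletion = TRUE,
                  as.matrix = TRUE)
  )
  if (any(!is.finite(d))) {
    ds_stop(sprintf("%s distance undefined for at least one pair (saturation)",
                    model),
            "saturation_error")
  }
  d
}

#' Write a distance matrix as square TSV
#'
#' @param d symmetric matrix from [distance_matrix()].
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(name = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
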