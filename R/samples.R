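#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius). Sub-0.5% ellipsoidal error is immaterial at the 1-km
#' deduplication threshold and the 25-75 km window radii used here.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84).
#'   Vectors are recycled elementwise.
#' @return Numeric vector of distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 1)  # ~111.19 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  validate_coords(lat1, lon1)
  validate_coords(lat2, lon2)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.vector(geosphere::distHaversine(p1, p2, r = 6371.0088 * 1000)) / 1000
}

validate_coords <- function(lat, lon) {
  if (anyNA(lat) || anyNA(lon) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    ds_stop("coordinates must satisfy -90 <= lat <= 90, -180 <= lon <= 180",
            "coordinate_error")
  }
  invisible(TRUE)
}

# Full pairwise great-circle distance matrix (km) for a sample table.
pairwise_km <- function(samples) {
  validate_coords(samples$lat, samples$lon)
  m <- geosphere::distm(cbind(samples$lon, samples$lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2,
                                                   r = 6371.0088 * 1000))
  m / 1000
}

#' Validate a georeferenced sample table
#'
#' A sample table has one row per specimen with columns `id`, `lat`, `lon`,
#' `basin` (river-basin label), `phylogroup` (mitochondrial group label,
#' e.g. A1/A2a/A2b/B) and `seq_name` (the row name of the specimen's
#' sequence in the companion alignment).
#'
#' @param samples data.frame with the columns above.
#' @param aln optional `dna_alignment`; when given, every `seq_name` must
#'   resolve to a row of it.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validate_samples <- function(samples, aln = NULL) {
  req <- c("id", "lat", "lon", "basin", "phylogroup", "seq_name")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0L) {
    ds_stop(sprintf("sample table lacks column(s): %s",
                    paste(miss, collapse = ", ")),
            "parameter_error")
  }
  if (anyDuplicated(samples$id)) {
    ds_stop("duplicate sample ids", "identifier_error")
  }
  validate_coords(samples$lat, samples$lon)
  if (!is.null(aln)) {
    unlinked <- setdiff(samples$seq_name, rownames(aln))
    if (length(unlinked) > 0L) {
      ds_stop(sprintf("seq_name(s) not present in alignment: %s",
                      paste(utils::head(unlinked, 5), collapse = ", ")),
              "linkage_error")
    }
  }
  samples
}

#' Read / write a sample table (TSV)
#'
#' @param path TSV file with header `id lat lon basin phylogroup seq_name`.
#' @return A validated sample data.frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) {
    ds_stop(sprintf("file not found: %s", path), "io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(id = "character",
                                         basin = "character",
                                         phylogroup = "character",
                                         seq_name = "character"))
  validate_samples(df)
}

#' @rdname read_sample_table
#' @param samples sample data.frame.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse putative repeat samples of one individual
#'
#' Noninvasive (fecal) sampling can pick up the same individual more than
#' once. Two samples are treated as candidate repeats iff their sequence
#' rows are bitwise identical (including `N` positions — no mismatch
#' tolerance); among such identical haplotypes, a sample is dropped when it
#' lies strictly closer than `min_km` to an already-kept sample of the same
#' haplotype. The pass is greedy in input order (first kept wins) and a
#' pair at exactly `min_km` is kept on both sides ("at least" one km
#' apart). Samples with distinct haplotypes are never dropped, however
#' close.
#'
#' @param samples sample data.frame (see [validate_samples()]).
#' @param aln `dna_alignment` containing every `seq_name`.
#' @param min_km distance threshold in km (default 1, the typical upper
#'   bound on a water shrew's home range).
#' @return List with data.frames `kept` and `dropped` partitioning the
#'   input rows.
#' @export
dedup_by_haplotype <- function(samples, aln, min_km = 1.0) {
  samples <- validate_samples(samples, aln)
  if (!is.numeric(min_km) || length(min_km) != 1L || min_km <= 0) {
    ds_stop("min_km must be a single positive number", "parameter_error")
  }
  seqs <- aln_strings(aln)[samples$seq_name]
  keep <- logical(nrow(samples))
  for (h in unique(seqs)) {
    idx <- which(seqs == h)
    kept_idx <- integer(0)
    for (i in idx) {
      if (length(kept_idx) == 0L) {
        keep[i] <- TRUE
        kept_idx <- i
      } else {
        d <- great_circle_km(samples$lat[i], samples$lon[i],
                             samples$lat[kept_idx], samples$lon[kept_idx])
        if (all(d >= min_km)) {
          keep[i] <- TRUE
          kept_idx <- c(kept_idx, i)
        }
      }
    }
  }
  list(kept = samples[keep, , drop = FALSE],
       dropped = samples[!keep, , drop = FALSE])
}
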