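#' Samples within a window around a center sample
#'
#' Members of the moving window centered on one sampling point: all samples
#' (the center included) lying within `radius_km` great-circle kilometres
#' of the center (closed ball, so a sample at exactly the radius is in)
#' AND carrying the center's phylogroup label. Restricting the window to
#' the center's phylogroup keeps window diversity from being inflated in
#' contact zones where divergent phylogroups mix.
#'
#' @param center single-row data.frame (one sample).
#' @param samples sample data.frame (see [validate_samples()]).
#' @param radius_km window radius in km (default 75).
#' @return The member rows of `samples`.
#' @export
window_members <- function(center, samples, radius_km = 75) {
  if (!is.numeric(radius_km) || length(radius_km) != 1L || radius_km <= 0) {
    ds_stop("radius_km must be a single positive number", "parameter_error")
  }
  if (is.na(center$phylogroup) || !nzchar(center$phylogroup)) {
    ds_stop("window center has no phylogroup label", "missing_label_error")
  }
  d <- great_circle_km(center$lat, center$lon, samples$lat, samples$lon)
  samples[d <= radius_km & samples$phylogroup == center$phylogroup, ,
          drop = FALSE]
}

#' Moving-window nucleotide-diversity surface
#'
#' For each sampling point, computes the nucleotide diversity of all
#' same-phylogroup samples within `radius_km` of it; window values
#' supported by fewer than `min_samples` members are omitted (not
#' zero-filled). Windows are centered on sampling points, not on a raster
#' grid, so the surface is a set of georeferenced points.
#'
#' @param samples sample data.frame with phylogroup labels for every row.
#' @param aln `dna_alignment` holding the sequences (`seq_name` links).
#' @param radius_km window radius in km (default 75).
#' @param min_samples minimum window size for a value to be reported
#'   (default 5; must be >= 2).
#' @return A `diversity_surface`: data.frame with columns `sample_id`,
#'   `lat`, `lon`, `phylogroup`, `n_support`, `pi`, one row per retained
#'   window center.
#' @export
diversity_surface <- function(samples, aln, radius_km = 75, min_samples = 5) {
  samples <- validate_samples(samples, aln)
  if (!is.numeric(min_samples) || length(min_samples) != 1L ||
      min_samples < 2) {
    ds_stop("min_samples must be a single number >= 2", "parameter_error")
  }
  if (any(is.na(samples$phylogroup)) || any(!nzchar(samples$phylogroup))) {
    ds_stop("every sample needs a phylogroup label for diversity mapping",
            "missing_label_error")
  }
  # Pairwise geographic and genetic distances once; each window's pi is the
  # mean of the p-distance submatrix over its members.
  km <- pairwise_km(samples)
  p <- .p_matrix(.as_rows(aln)[samples$seq_name, , drop = FALSE])
  same_group <- outer(samples$phylogroup, samples$phylogroup, "==")
  member <- km <= radius_km & same_group

  rows <- lapply(seq_len(nrow(samples)), function(i) {
    idx <- which(member[i, ])
    if (length(idx) < min_samples) return(NULL)
    sub <- p[idx, idx, drop = FALSE]
    data.frame(sample_id = samples$id[i],
               lat = samples$lat[i], lon = samples$lon[i],
               phylogroup = samples$phylogroup[i],
               n_support = length(idx),
               pi = mean(sub[upper.tri(sub)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), lat = numeric(0),
                      lon = numeric(0), phylogroup = character(0),
                      n_support = integer(0), pi = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out,
            class = c("diversity_surface", "data.frame"),
            radius_km = radius_km, min_samples = min_samples)
}

#' @export
print.diversity_surface <- function(x, ...) {
  cat(sprintf(
    "Moving-window nucleotide diversity: %d window(s), radius %g km, >= %d samples\n",
    nrow(x), attr(x, "radius_km"), attr(x, "min_samples")))
  if (nrow(x) > 0L) {
    cat(sprintf("  pi range: %.4f - %.4f\n", min(x$pi), max(x$pi)))
    print.data.frame(utils::head(cbind(x[1:4],
                                       n_support = x$n_support,
                                       pi = round(x$pi, 4)), 10L))
    if (nrow(x) > 10L) cat(sprintf("  ... and %d more rows\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' Plot a diversity surface as a color-coded map
#'
#' @param x a `diversity_surface`.
#' @param palette color ramp function (low to high diversity).
#' @param ... passed to [graphics::plot()].
#' @export
plot.diversity_surface <- function(x,
                                   palette = grDevices::colorRampPalette(
                                     c("blue", "yellow", "red")),
                                   ...) {
  if (nrow(x) == 0L) {
    ds_stop("empty diversity surface; nothing to plot", "parameter_error")
  }
  cols <- palette(100L)
  rng <- range(x$pi)
  idx <- if (diff(rng) == 0) rep(1L, nrow(x)) else
    pmax(1L, ceiling(99 * (x$pi - rng[1]) / diff(rng)))
  graphics::plot(x$lon, x$lat, col = cols[idx], pch = 19,
                 xlab = "Longitude", ylab = "Latitude",
                 main = sprintf("Nucleotide diversity (radius %g km)",
                                attr(x, "radius_km")), ...)
  invisible(x)
}

#' Write a diversity surface as TSV
#'
#' `pi` is written with 4 decimal places.
#'
#' @param surface a `diversity_surface`.
#' @param path output path.
#' @export
write_diversity_surface <- function(surface, path) {
  out <- as.data.frame(surface)
  out$pi <- sprintf("%.4f", out$pi)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
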