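#' Georeferenced suitability rasters
#'
#' A `suit_raster` is a single-band grid of values with a simple affine
#' georeference (lower-left corner + square cell size, north-up), the
#' layout of an ESRI ASCII grid. Values are stored as a numeric matrix in
#' map orientation (row 1 = northernmost row); missing cells are `NA`.
#' Continuous habitat-suitability layers live in `[0, 1]`; binary and
#' consensus layers hold small integers.
#'
#' @param grid numeric matrix (row 1 = top/north row).
#' @param xll,yll x and y coordinate of the lower-left corner of the grid.
#' @param cellsize cell edge length (map units, e.g. degrees).
#' @param crs_label free-text coordinate reference identifier.
#' @param nodata sentinel written for `NA` cells on output (default -9999).
#' @return A `suit_raster` object.
#' @export
suit_raster <- function(grid, xll = 0, yll = 0, cellsize = 1,
                        crs_label = "EPSG:4326", nodata = -9999) {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    ds_stop("grid must be a numeric matrix", "parameter_error")
  }
  if (any(is.infinite(grid))) {
    ds_stop("grid values must be finite or NA", "parameter_error")
  }
  structure(list(grid = grid, xll = xll, yll = yll, cellsize = cellsize,
                 crs_label = crs_label, nodata = nodata),
            class = "suit_raster")
}

#' @export
print.suit_raster <- function(x, ...) {
  cat(sprintf(
    "suit_raster: %d rows x %d cols, cell %g, origin (%g, %g), %s\n",
    nrow(x$grid), ncol(x$grid), x$cellsize, x$xll, x$yll, x$crs_label))
  v <- x$grid[!is.na(x$grid)]
  if (length(v)) cat(sprintf("  values: %.4g - %.4g (%d NA cells)\n",
                             min(v), max(v), sum(is.na(x$grid))))
  invisible(x)
}

#' @export
plot.suit_raster <- function(x, ...) {
  nr <- nrow(x$grid); nc <- ncol(x$grid)
  xs <- x$xll + (seq_len(nc) - 0.5) * x$cellsize
  ys <- x$yll + (seq_len(nr) - 0.5) * x$cellsize
  # image() wants z[x, y] with y ascending: transpose and flip rows
  graphics::image(xs, ys, t(x$grid[nr:1, , drop = FALSE]),
                  xlab = "x", ylab = "y", ...)
  invisible(x)
}

# TRUE when two rasters can enter one cellwise operation.
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$grid), dim(b$grid)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Read / write ESRI ASCII grids
#'
#' The plain-text `.asc` raster dialect: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed
#' by rows of whitespace-separated values, north row first.
#'
#' @param path file path.
#' @param crs_label CRS tag to attach on read (the format itself carries
#'   none).
#' @return A `suit_raster` (read) or `path` invisibly (write).
#' @export
read_esri_ascii <- function(path, crs_label = "EPSG:4326") {
  if (!file.exists(path)) {
    ds_stop(sprintf("file not found: %s", path), "io_error")
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    ds_stop(sprintf("malformed ESRI ASCII header in %s", path), "io_error")
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    ds_stop(sprintf("expected %d cells, found %d in %s",
                    hdr$ncols * hdr$nrows, length(vals), path), "io_error")
  }
  grid <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  grid[grid == nodata] <- NA
  suit_raster(grid, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, crs_label = crs_label,
              nodata = nodata)
}

#' @rdname read_esri_ascii
#' @param raster a `suit_raster`.
#' @export
write_esri_ascii <- function(raster, path) {
  stopifnot(inherits(raster, "suit_raster"))
  g <- raster$grid
  g[is.na(g)] <- raster$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", raster$xll),
    sprintf("yllcorner %.10g", raster$yll),
    sprintf("cellsize %.10g", raster$cellsize),
    sprintf("NODATA_value %.10g", raster$nodata)
  ), con)
  writeLines(apply(g, 1L, function(r) paste(format(r, trim = TRUE,
                                                   digits = 10),
                                            collapse = " ")), con)
  invisible(path)
}

#' Prune correlated predictor variables
#'
#' Greedy scan in input (e.g. BIO-number) order: a variable is dropped iff
#' its absolute Pearson correlation with any already-kept variable reaches
#' the threshold. With the conventional 0.8 cutoff this reproduces the
#' usual "keep variables with correlation lower than 0.8" preprocessing of
#' bioclimatic layers before distribution modelling.
#'
#' @param predictors numeric matrix or data.frame, one column per variable,
#'   one row per location.
#' @param threshold correlation cutoff in (0, 1), default 0.8.
#' @return Character vector of kept variable names, in input order.
#' @export
prune_correlated <- function(predictors, threshold = 0.8) {
  predictors <- as.matrix(predictors)
  if (ncol(predictors) < 2L) {
    ds_stop("at least 2 predictor variables are required", "parameter_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    ds_stop("threshold must lie strictly between 0 and 1", "parameter_error")
  }
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("v", seq_len(ncol(predictors)))
  }
  sds <- apply(predictors, 2L, stats::sd)
  if (any(sds == 0)) {
    ds_stop(sprintf("zero-variance variable(s): %s",
                    paste(colnames(predictors)[sds == 0], collapse = ", ")),
            "undefined_correlation_error")
  }
  kept <- integer(0)
  for (j in seq_len(ncol(predictors))) {
    if (length(kept) == 0L) {
      kept <- j
    } else {
      r <- abs(stats::cor(predictors[, j], predictors[, kept]))
      if (all(r < threshold)) kept <- c(kept, j)
    }
  }
  colnames(predictors)[kept]
}

#' Percentile-threshold a suitability raster to a binary layer
#'
#' Computes the threshold as the `pct`-th percentile (linear interpolation,
#' [stats::quantile()] type 7) of the model's suitability either at the
#' presence localities (the MaxEnt "percentile training presence"
#' convention, default) or over all data cells, then sets each cell to 1
#' iff its suitability is at least the threshold. `NA` cells stay `NA`.
#'
#' @param raster a `suit_raster` of continuous suitabilities.
#' @param presence_values suitability values at the occurrence points
#'   (required when `over = "presence"`).
#' @param pct percentile in `[0, 100]` (the analysis here contrasts the
#'   permissive 10th with the restrictive 90th).
#' @param over `"presence"` or `"cells"`.
#' @return List with `raster` (binary `suit_raster`) and `threshold`.
#' @export
percentile_threshold <- function(raster, presence_values = NULL, pct = 90,
                                 over = c("presence", "cells")) {
  stopifnot(inherits(raster, "suit_raster"))
  over <- match.arg(over)
  if (!is.numeric(pct) || length(pct) != 1L || pct < 0 || pct > 100) {
    ds_stop("pct must be a single value in [0, 100]", "parameter_error")
  }
  pool <- if (over == "presence") presence_values else
    raster$grid[!is.na(raster$grid)]
  if (is.null(pool) || length(pool) == 0L || anyNA(pool)) {
    ds_stop("a non-empty, NA-free set of suitability values is required",
            "parameter_error")
  }
  t <- unname(stats::quantile(pool, pct / 100, type = 7))
  g <- raster$grid
  bin <- ifelse(is.na(g), NA_real_, as.numeric(g >= t))
  dim(bin) <- dim(g)
  out <- raster
  out$grid <- bin
  list(raster = out, threshold = t)
}

#' Multi-model consensus of binary layers
#'
#' Cellwise sum of binary presence layers: the value of each cell is the
#' number of models predicting presence there (0..m). `NA` in any input
#' propagates `NA`; all inputs must share grid shape and georeference.
#'
#' @param binaries list of binary `suit_raster`s (>= 2).
#' @return A `suit_raster` of agreement counts.
#' @export
consensus_raster <- function(binaries) {
  if (!is.list(binaries) || length(binaries) < 2L) {
    ds_stop("at least 2 binary rasters are required", "parameter_error")
  }
  lapply(binaries, function(b) stopifnot(inherits(b, "suit_raster")))
  ref <- binaries[[1]]
  for (b in binaries[-1]) {
    if (!same_geometry(ref, b)) {
      ds_stop("rasters differ in shape or georeference",
              "grid_mismatch_error")
    }
  }
  out <- ref
  out$grid <- Reduce(`+`, lapply(binaries, `[[`, "grid"))
  out
}
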