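#' Run the full spatial-diversity pipeline
#'
#' Chains the analysis stages — sample deduplication, gap stripping and
#' partition concatenation, diversity statistics, moving-window diversity
#' mapping, one-way AMOVA by basin, and suitability-raster consensus — on
#' either files named in the configuration or a dataset simulated in
#' place. Each stage can be switched off; outputs are written under
#' `out_dir` and every file produced is listed in a JSON manifest together
#' with the parameters and seed used. Progress is logged to stderr.
#'
#' @param config configuration as a named list or the path to a YAML file
#'   with the same structure:
#' \describe{
#'   \item{out_dir}{output directory (created if absent). Required.}
#'   \item{seed}{integer seed; used for simulation and the AMOVA
#'     permutations. Default 1.}
#'   \item{stages}{character vector among `dedup`, `concat`, `stats`,
#'     `map`, `amova`, `sdm`; default all that have inputs.}
#'   \item{simulate}{optional list of [sim_config()] arguments; when
#'     present the dataset (and rasters, if the `sdm` stage runs) is
#'     simulated.}
#'   \item{alignment, dloop, samples}{input paths (FASTA, FASTA, TSV) used
#'     when `simulate` is absent.}
#'   \item{rasters}{character vector of ESRI ASCII paths for `sdm`.}
#'   \item{presence}{TSV with a `suitability` column per raster-model
#'     column, or absent to take percentiles over cells.}
#'   \item{min_km, radius_km, min_samples, model, n_perm, pct}{stage
#'     parameters; defaults 1, 75, 5, "p", 999, 90.}
#' }
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      ds_stop(sprintf("config file not found: %s", config), "io_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$out_dir)) {
    ds_stop("config must be a list (or YAML file) with an out_dir",
            "parameter_error")
  }
  p <- list(seed = config$seed %||% 1L,
            min_km = config$min_km %||% 1.0,
            radius_km = config$radius_km %||% 75,
            min_samples = config$min_samples %||% 5,
            model = config$model %||% "p",
            n_perm = config$n_perm %||% 999,
            pct = config$pct %||% 90)
  all_stages <- c("dedup", "concat", "stats", "map", "amova", "sdm")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    ds_stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
            "parameter_error")
  }

  # pre-flight: every referenced input must exist before anything runs
  inputs <- unlist(config[c("alignment", "dloop", "samples", "rasters",
                            "presence")])
  missing_in <- if (length(inputs)) inputs[!file.exists(inputs)] else
    character(0)
  if (length(missing_in) > 0L) {
    ds_stop(sprintf("input file(s) not found: %s",
                    paste(missing_in, collapse = ", ")), "io_error")
  }
  if (is.null(config$simulate) && is.null(config$alignment) &&
      length(intersect(stages, c("dedup", "concat", "stats", "map",
                                 "amova"))) > 0L) {
    ds_stop("either 'simulate' or input paths must be provided",
            "parameter_error")
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = p, stages = stages, outputs = list(),
                   counts = list())
  emit <- function(stage, file) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]], file)
    file
  }
  note <- function(stage, ...) {
    manifest$counts[[stage]] <<- utils::modifyList(
      manifest$counts[[stage]] %||% list(), list(...))
  }
  log_msg <- function(...) message(sprintf(...))
  out <- function(f) file.path(config$out_dir, f)

  run_stage <- function(stage, body) {
    log_msg("[%s] starting", stage)
    ok <- tryCatch({ body(); TRUE }, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        class = c("pipeline_stage_error", "divscape_error")))
    })
    log_msg("[%s] done", stage)
    invisible(ok)
  }

  # ---- load or simulate inputs -------------------------------------------
  dloop <- NULL
  rasters <- NULL
  presence_df <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% p$seed
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(cfg)
    aln <- sim$alignment
    samples <- sim$samples
    dloop <- sim$dloop
    emit("simulate", write_fasta(aln, out("cytb.fasta")))
    if (!is.null(dloop)) emit("simulate", write_fasta(dloop,
                                                      out("dloop.fasta")))
    emit("simulate", write_sample_table(samples, out("samples.tsv")))
    if ("sdm" %in% stages) {
      rsim <- simulate_rasters(cfg)
      rasters <- rsim$rasters
      presence_df <- data.frame(sapply(seq_along(rasters), function(m) {
        g <- rasters[[m]]
        col <- pmin(ncol(g$grid), pmax(1L, ceiling(
          (rsim$presence$lon - g$xll) / g$cellsize)))
        row <- pmin(nrow(g$grid), pmax(1L, ceiling(
          (g$yll + nrow(g$grid) * g$cellsize - rsim$presence$lat) /
            g$cellsize)))
        g$grid[cbind(row, col)]
      }))
      names(presence_df) <- paste0("model", seq_along(rasters))
      for (m in seq_along(rasters)) {
        emit("simulate", write_esri_ascii(rasters[[m]],
                                          out(sprintf("model%d.asc", m))))
      }
    }
    note("simulate", n_samples = nrow(samples), seed = cfg$seed)
  } else if (!is.null(config$alignment)) {
    aln <- read_fasta(config$alignment)
    samples <- read_sample_table(config$samples)
    if (!is.null(config$dloop)) dloop <- read_fasta(config$dloop)
    if (!is.null(config$rasters)) {
      rasters <- lapply(config$rasters, read_esri_ascii)
    }
    if (!is.null(config$presence)) {
      presence_df <- utils::read.table(config$presence, header = TRUE,
                                       sep = "\t")
    }
  } else {
    aln <- NULL; samples <- NULL
  }

  # ---- dedup --------------------------------------------------------------
  if ("dedup" %in% stages && !is.null(aln)) run_stage("dedup", function() {
    dd <- dedup_by_haplotype(samples, aln, min_km = p$min_km)
    note("dedup", n_in = nrow(samples), n_kept = nrow(dd$kept),
         n_dropped = nrow(dd$dropped))
    samples <<- dd$kept
    emit("dedup", write_sample_table(dd$kept, out("samples_dedup.tsv")))
    emit("dedup", write_sample_table(dd$dropped, out("samples_dropped.tsv")))
  })

  # ---- concat (gap strip + concatenation) ---------------------------------
  if ("concat" %in% stages && !is.null(dloop)) run_stage("concat", function() {
    core <- eliminate_gap_positions(dloop)
    note("concat", dloop_columns_in = aln_length(dloop),
         dloop_core = aln_length(core),
         columns_removed = aln_length(dloop) - aln_length(core))
    cc <- concatenate_alignments(list(cytb = aln, dloop = core))
    note("concat", concatenated_bp = aln_length(cc$alignment))
    emit("concat", write_fasta(cc$alignment, out("concatenated.fasta")))
    emit("concat", write_partition_table(cc$partitions,
                                         out("partitions.tsv")))
  })

  # ---- stats --------------------------------------------------------------
  if ("stats" %in% stages && !is.null(aln)) run_stage("stats", function() {
    keep <- samples$seq_name
    sub <- dna_alignment(unclass(aln)[keep, , drop = FALSE])
    d <- distance_matrix(sub, model = p$model)
    emit("stats", write_distance_matrix(d, out("distances.tsv")))
    by_grp <- split(seq_len(nrow(samples)), samples$phylogroup)
    stats_tab <- do.call(rbind, lapply(names(by_grp), function(g) {
      ix <- by_grp[[g]]
      if (length(ix) < 2L) return(NULL)
      rows <- unclass(sub)[ix, , drop = FALSE]
      data.frame(phylogroup = g, n = length(ix),
                 pi = round(nucleotide_diversity(rows), 4),
                 theta_w = round(watterson_theta(rows), 4),
                 hap_div = round(haplotype_diversity(rows), 4))
    }))
    f <- out("diversity_by_group.tsv")
    utils::write.table(stats_tab, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("stats", f)
    note("stats", n_groups = length(by_grp))
  })

  # ---- map ----------------------------------------------------------------
  if ("map" %in% stages && !is.null(aln)) run_stage("map", function() {
    surf <- diversity_surface(samples, aln, radius_km = p$radius_km,
                              min_samples = p$min_samples)
    note("map", windows_emitted = nrow(surf),
         centers_total = nrow(samples))
    emit("map", write_diversity_surface(surf, out("diversity_map.tsv")))
  })

  # ---- amova --------------------------------------------------------------
  if ("amova" %in% stages && !is.null(aln)) run_stage("amova", function() {
    sub <- dna_alignment(unclass(aln)[samples$seq_name, , drop = FALSE])
    d <- distance_matrix(sub, model = p$model)
    res <- amova_oneway(d, samples$basin, n_perm = p$n_perm, seed = p$seed)
    note("amova", phi_st = res$phi_st, pct_among = res$pct_among,
         p_value = res$p_value)
    emit("amova", write_amova_table(res, out("amova.tsv")))
  })

  # ---- sdm ----------------------------------------------------------------
  if ("sdm" %in% stages && !is.null(rasters)) run_stage("sdm", function() {
    bins <- lapply(seq_along(rasters), function(m) {
      pv <- if (!is.null(presence_df)) presence_df[[m]] else NULL
      percentile_threshold(rasters[[m]], presence_values = pv, pct = p$pct,
                           over = if (is.null(pv)) "cells" else
                             "presence")$raster
    })
    cons <- consensus_raster(bins)
    note("sdm", n_models = length(rasters),
         cells_all_models = sum(cons$grid == length(rasters),
                                na.rm = TRUE))
    emit("sdm", write_esri_ascii(cons, out("consensus.asc")))
  })

  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_msg("manifest written to %s", manifest_path)
  invisible(c(manifest, list(manifest_file = manifest_path)))
}
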