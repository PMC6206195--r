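# Synthetic-data generator: a two-phylogroup landscape with contact zones,
# river basins, and coalescent within-group sequence variation, emulating a
# noninvasive mitochondrial survey of an Iberian semi-aquatic mammal.

#' Configuration for the synthetic landscape generator
#'
#' Defaults mirror the study conditions the package's analyses assume:
#' 132 samples in 2 divergent phylogroups over an Iberia-sized bounding box
#' (36-44N, -9-3E), 752 bp of cytochrome b for every sample plus a gappy
#' ~450 bp D-loop fragment (272 bp gap-free core) for a subset, expected
#' between-phylogroup p-distance 1.16%, within-group nucleotide diversity
#' spanning 0.005 (first group) down to 0.0003 (last group), ten river
#' basins, and 19% of within-group molecular variance structured by basin.
#'
#' @param n_samples total number of samples.
#' @param n_groups number of phylogroups (allopatric longitude slabs with
#'   narrow contact bands between neighbours).
#' @param seq_length cytochrome-b alignment length in bp.
#' @param between_group_div target expected sample-level p-distance between
#'   phylogroups.
#' @param within_theta per-group target nucleotide diversity; recycled to
#'   `n_groups`. Default: log-spaced from 0.005 down to 0.0003.
#' @param landscape named vector `lat_min`, `lat_max`, `lon_min`, `lon_max`
#'   in decimal degrees.
#' @param contact_band_km width of the spatial overlap between adjacent
#'   group ranges.
#' @param n_basins number of river basins (longitude bands).
#' @param basin_effect target among-basin fraction of within-group
#'   molecular variance (AMOVA sense), in `[0, 1)`.
#' @param dloop_fraction fraction of samples with a D-loop sequence.
#' @param dloop_length,dloop_core total and gap-free-core length of the
#'   D-loop fragment (bp).
#' @param genealogy within-group model of descent. `"star"` (default)
#'   mutates every sample independently from its group ancestor at
#'   per-site rate `within_theta/2`, so realized group diversity
#'   concentrates tightly at its target; `"coalescent"` evolves the group
#'   on a Kingman genealogy ([ape::rcoal()] plus [phangorn::simSeq()]),
#'   reproducing the genealogical correlation and inter-locus variance of
#'   neutral-equilibrium data (under which pi and Watterson's theta share
#'   the same expectation).
#' @param seed mandatory RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 132, n_groups = 2, seq_length = 752,
                       between_group_div = 0.0116, within_theta = NULL,
                       landscape = c(lat_min = 36, lat_max = 44,
                                     lon_min = -9, lon_max = 3),
                       contact_band_km = 30, n_basins = 10,
                       basin_effect = 0.19, dloop_fraction = 103 / 132,
                       dloop_length = 450, dloop_core = 272,
                       genealogy = c("star", "coalescent"),
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    ds_stop("a single numeric seed is mandatory", "parameter_error")
  }
  genealogy <- match.arg(genealogy)
  if (is.null(within_theta)) {
    within_theta <- if (n_groups == 1L) 0.005 else
      exp(seq(log(0.005), log(0.0003), length.out = n_groups))
  }
  within_theta <- rep_len(within_theta, n_groups)
  cfg <- list(n_samples = as.integer(n_samples),
              n_groups = as.integer(n_groups),
              seq_length = as.integer(seq_length),
              between_group_div = between_group_div,
              within_theta = within_theta,
              landscape = landscape,
              contact_band_km = contact_band_km,
              n_basins = as.integer(n_basins),
              basin_effect = basin_effect,
              dloop_fraction = dloop_fraction,
              dloop_length = as.integer(dloop_length),
              dloop_core = as.integer(dloop_core),
              genealogy = genealogy,
              seed = as.integer(seed))
  rates <- c(cfg$between_group_div, cfg$within_theta, cfg$basin_effect,
             cfg$dloop_fraction)
  if (any(rates < 0) || any(rates > 1) || cfg$basin_effect >= 1) {
    ds_stop("rates must lie in [0, 1] (basin_effect < 1)", "parameter_error")
  }
  if (cfg$n_samples < cfg$n_groups || cfg$n_groups < 1L ||
      cfg$seq_length < 1L || cfg$n_basins < 1L ||
      cfg$contact_band_km < 0 || cfg$dloop_core > cfg$dloop_length) {
    ds_stop("infeasible configuration", "parameter_error")
  }
  if (cfg$between_group_div * cfg$seq_length > cfg$seq_length) {
    ds_stop("expected substitutions exceed sequence length",
            "parameter_error")
  }
  structure(cfg, class = "sim_config")
}

# Per-site basin-branch substitution rate giving a target among-basin
# variance fraction f for ONE simulated group, calibrated conditionally on
# the realized within-group distances (coalescent genealogies vary so much
# between replicates that an unconditional calibration would leave the
# realized fraction far from f). With m1/m2 the realized mean and mean
# square of the pairwise p-distances before basin substitutions, adding
# independent Binomial(L, beta) basin branches to two different basins
# inflates a cross-basin pair's expected squared distance to
#   m2 + 4*beta*m1 + 2*beta*(1-beta)/L + 4*beta^2,
# and the among-basin variance fraction of the group is f when that equals
# m2 / (1 - f).
solve_basin_rate <- function(f, m1, m2, L) {
  if (f <= 0 || m2 <= 0) return(0)
  delta <- m2 * f / (1 - f)
  gap <- function(beta) {
    4 * beta * m1 + 2 * beta * (1 - beta) / L + 4 * beta^2 - delta
  }
  stats::uniroot(gap, c(0, 0.75), tol = 1e-14)$root
}

# Apply `n_sub` substitutions at random sites of a character vector,
# each to a uniformly chosen different base.
.mutate_sites <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  sites <- sample.int(length(seq), min(n_sub, length(seq)))
  seq[sites] <- vapply(seq[sites], function(b)
    sample(setdiff(DNA_BASES, b), 1L), character(1))
  seq
}

.group_labels <- function(k) {
  if (k == 1L) "A"
  else if (k == 2L) c("A", "B")
  else if (k == 4L) c("A1", "A2a", "A2b", "B")
  else paste0("G", seq_len(k))
}

# Sample sequences for one group at per-lineage per-site rate mu
# (= pi_group / 2, so E[pairwise p-distance] ~ 2*mu = target group pi).
# star: independent Binomial(L, mu) substitutions from the ancestor.
# coalescent: rcoal genealogy (branch lengths in coalescent units) with
# simSeq mutations at rate mu.
.simulate_group_seqs <- function(n, L, mu, ancestor, tip_names,
                                 genealogy = "star") {
  if (n == 1L || mu <= 0) {
    m <- matrix(rep(ancestor, each = n), nrow = n)
    rownames(m) <- tip_names
    return(m)
  }
  if (genealogy == "star") {
    m <- t(vapply(seq_len(n), function(i)
      .mutate_sites(ancestor, stats::rbinom(1L, L, mu)), character(L)))
    rownames(m) <- tip_names
    return(m)
  }
  tree <- ape::rcoal(n, tip.label = tip_names)
  sim <- phangorn::simSeq(tree, l = L, rootseq = tolower(ancestor),
                          rate = mu, type = "DNA")
  toupper(as.character(sim))[tip_names, , drop = FALSE]
}

#' Simulate a georeferenced two-phylogroup sequence dataset
#'
#' Phylogroup ranges are adjacent longitude slabs, each widened by half the
#' contact-band width so neighbouring groups overlap in narrow contact
#' zones; sample coordinates are uniform within the group range. Basins are
#' equal-width longitude bands. Group ancestors sit on a star whose arm
#' length is calibrated so the expected sample-level between-group
#' p-distance equals `between_group_div`; within-group variation evolves
#' from the group ancestor at per-lineage rate `within_theta/2` under the
#' configured genealogy model (so expected within-group pi equals
#' `within_theta`); `basin_effect`
#' adds substitutions shared by all of a basin's members within a group,
#' at a rate solved so the expected among-basin AMOVA variance fraction
#' within a group equals `basin_effect`. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param dloop also simulate the gappy D-loop fragment (default TRUE).
#' @return List with `alignment` (cytochrome-b `dna_alignment`, all
#'   samples), `samples` (sample data.frame), `dloop` (`dna_alignment` for
#'   the D-loop subset, gap-containing flanks plus a `dloop_core` bp clean
#'   core, or NULL), and `config`.
#' @export
simulate_dataset <- function(cfg, dloop = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  k <- cfg$n_groups
  L <- cfg$seq_length
  box <- cfg$landscape
  labels <- .group_labels(k)

  # group sizes: near-equal split
  sizes <- diff(round(seq(0, cfg$n_samples, length.out = k + 1)))
  mu <- cfg$within_theta / 2

  # phylogroup ancestors on a star, arm length calibrated so the expected
  # SAMPLE-level between-group p-distance hits the target: subtract each
  # group's expected leaf-to-ancestor distance (mu for star descent,
  # 2*mu*(1 - 1/n) = expected tree height for coalescent descent)
  h <- if (cfg$genealogy == "star") mu else
    2 * mu * (1 - 1 / pmax(sizes, 2))
  delta <- if (k > 1) {
    pairs <- utils::combn(k, 2)
    max(0, cfg$between_group_div -
           mean(h[pairs[1, ]] + h[pairs[2, ]]))
  } else 0
  root <- sample(DNA_BASES, L, replace = TRUE)
  ancestors <- lapply(seq_len(k), function(g)
    .mutate_sites(root, stats::rbinom(1L, L, delta / 2)))

  # geography: longitude slabs + contact bands
  lat_mid <- (box["lat_min"] + box["lat_max"]) / 2
  km_per_deg_lon <- 111.32 * cos(lat_mid * pi / 180)
  half_band_deg <- (cfg$contact_band_km / 2) / km_per_deg_lon
  edges <- seq(box["lon_min"], box["lon_max"], length.out = k + 1)

  ids <- sprintf("s%03d", seq_len(cfg$n_samples))
  grp_idx <- rep.int(seq_len(k), sizes)
  lon <- numeric(cfg$n_samples)
  lat <- stats::runif(cfg$n_samples, box["lat_min"], box["lat_max"])
  for (g in seq_len(k)) {
    lo <- max(box["lon_min"], edges[g] - if (g > 1) half_band_deg else 0)
    hi <- min(box["lon_max"], edges[g + 1] + if (g < k) half_band_deg else 0)
    lon[grp_idx == g] <- stats::runif(sizes[g], lo, hi)
  }
  basin_edges <- seq(box["lon_min"], box["lon_max"],
                     length.out = cfg$n_basins + 1)
  basin <- paste0("basin", pmin(cfg$n_basins, pmax(1L, findInterval(
    lon, basin_edges, rightmost.closed = TRUE))))

  # sequences: coalescent within groups, then basin-shared substitutions
  rows <- matrix("", nrow = cfg$n_samples, ncol = L,
                 dimnames = list(ids, NULL))
  for (g in seq_len(k)) {
    members <- which(grp_idx == g)
    rows[members, ] <- .simulate_group_seqs(sizes[g], L, mu[g],
                                            ancestors[[g]], ids[members],
                                            cfg$genealogy)
    if (cfg$basin_effect > 0 && cfg$n_basins > 1L && mu[g] > 0 &&
        sizes[g] >= 2L) {
      pm <- .p_matrix(rows[members, , drop = FALSE])
      pv <- pm[upper.tri(pm)]
      beta <- solve_basin_rate(cfg$basin_effect, mean(pv), mean(pv^2), L)
      for (b in unique(basin[members])) {
        cell <- members[basin[members] == b]
        n_sub <- stats::rbinom(1L, L, beta)
        if (n_sub > 0L) {
          sites <- sample.int(L, n_sub)
          repl <- vapply(ancestors[[g]][sites], function(x)
            sample(setdiff(DNA_BASES, x), 1L), character(1))
          rows[cell, sites] <- rep(repl, each = length(cell))
        }
      }
    }
  }

  samples <- data.frame(id = ids, lat = lat, lon = lon, basin = basin,
                        phylogroup = labels[grp_idx], seq_name = ids,
                        stringsAsFactors = FALSE)
  aln <- dna_alignment(rows)

  dloop_aln <- NULL
  if (isTRUE(dloop) && cfg$dloop_fraction > 0) {
    n_d <- max(2L, round(cfg$dloop_fraction * cfg$n_samples))
    sub <- sort(sample.int(cfg$n_samples, min(n_d, cfg$n_samples)))
    dloop_aln <- .simulate_dloop(cfg, grp_idx[sub], ids[sub], mu, delta)
  }

  list(alignment = aln, samples = samples, dloop = dloop_aln, config = cfg)
}

# D-loop fragment: clean simulated core of dloop_core bp flanked by columns
# that each contain at least one gap, so gap-position elimination recovers
# exactly the core.
.simulate_dloop <- function(cfg, grp_idx, ids, mu, delta) {
  n <- length(ids)
  core_len <- cfg$dloop_core
  root <- sample(DNA_BASES, core_len, replace = TRUE)
  k <- cfg$n_groups
  core <- matrix("", n, core_len, dimnames = list(ids, NULL))
  for (g in seq_len(k)) {
    members <- which(grp_idx == g)
    if (length(members) == 0L) next
    anc <- .mutate_sites(root, stats::rbinom(1L, core_len, delta / 2))
    core[members, ] <- .simulate_group_seqs(length(members), core_len,
                                            mu[g], anc, ids[members],
                                            cfg$genealogy)
  }
  flank_total <- cfg$dloop_length - core_len
  left_len <- flank_total %/% 2L
  right_len <- flank_total - left_len
  flank <- function(len) {
    if (len == 0L) return(NULL)
    f <- matrix(sample(DNA_BASES, n * len, replace = TRUE), n, len)
    gap <- matrix(stats::runif(n * len) < 0.5, n, len)
    none <- which(colSums(gap) == 0L)
    for (j in none) gap[sample.int(n, 1L), j] <- TRUE
    f[gap] <- "-"
    f
  }
  m <- cbind(flank(left_len), core, flank(right_len))
  rownames(m) <- ids
  dna_alignment(m)
}

#' Simulate habitat-suitability rasters and presence points
#'
#' Generates `n_models` continuous suitability fields over the
#' configuration's landscape: a shared smooth "true" field (Gaussian
#' optimum at a random interior center) plus smooth model-specific noise,
#' clamped to `[0, 1]`, with a one-cell no-data border. Presence points
#' are cells sampled with probability proportional to the true field.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param n_models number of model replicates (default 3, as for multiple
#'   palaeoclimate scenarios).
#' @param n_presence number of presence points (default 100).
#' @param cellsize cell edge in degrees (default 0.2).
#' @param noise_sd standard deviation of the smooth model-specific noise
#'   (default 0.15).
#' @return List with `rasters` (list of `suit_raster`), `presence`
#'   (data.frame `lon`, `lat`, `true_suitability`), `true_center`
#'   (`c(lon, lat)` of the optimum) and `true_field` (`suit_raster`).
#' @export
simulate_rasters <- function(cfg, n_models = 3, n_presence = 100,
                             cellsize = 0.2, noise_sd = 0.15) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_models < 1L) ds_stop("n_models must be >= 1", "parameter_error")
  set.seed(cfg$seed + 1000003L)
  box <- cfg$landscape
  nc <- max(8L, floor((box["lon_max"] - box["lon_min"]) / cellsize))
  nr <- max(8L, floor((box["lat_max"] - box["lat_min"]) / cellsize))
  cx_grid <- box["lon_min"] + (seq_len(nc) - 0.5) * cellsize
  cy_grid <- box["lat_max"] - (seq_len(nr) - 0.5) * cellsize  # row 1 = north

  cx <- stats::runif(1, box["lon_min"] + 2, box["lon_max"] - 2)
  cy <- stats::runif(1, box["lat_min"] + 1.5, box["lat_max"] - 1.5)
  sc <- 1.8
  true <- outer(cy_grid, cx_grid, function(y, x)
    exp(-((x - cx)^2 + (y - cy)^2) / (2 * sc^2)))

  smooth_noise <- function() {
    coarse <- matrix(stats::rnorm(6 * 8, 0, noise_sd), 6, 8)
    ri <- seq(1, 6, length.out = nr)
    ci <- seq(1, 8, length.out = nc)
    r0 <- pmin(5, floor(ri)); c0 <- pmin(7, floor(ci))
    fr <- ri - r0; fc <- ci - c0
    # bilinear upsample
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) {
      w1 <- (1 - fr[i]) * coarse[r0[i], ] + fr[i] * coarse[r0[i] + 1, ]
      out[i, ] <- (1 - fc) * w1[c0] + fc * w1[c0 + 1]
    }
    out
  }

  border_na <- function(g) {
    g[1, ] <- NA; g[nrow(g), ] <- NA; g[, 1] <- NA; g[, ncol(g)] <- NA
    g
  }
  rasters <- lapply(seq_len(n_models), function(m) {
    g <- true + if (noise_sd > 0) smooth_noise() else 0
    g[] <- pmin(1, pmax(0, g))
    suit_raster(border_na(g), xll = unname(box["lon_min"]),
                yll = unname(box["lat_min"]), cellsize = cellsize)
  })

  truth <- suit_raster(border_na(true), xll = unname(box["lon_min"]),
                       yll = unname(box["lat_min"]), cellsize = cellsize)
  interior <- which(!is.na(truth$grid))
  pr <- truth$grid[interior]
  pick <- sample(interior, n_presence, replace = TRUE,
                 prob = pr / sum(pr))
  pick_r <- (pick - 1L) %% nr + 1L
  pick_c <- (pick - 1L) %/% nr + 1L
  presence <- data.frame(lon = cx_grid[pick_c], lat = cy_grid[pick_r],
                         true_suitability = truth$grid[pick])

  list(rasters = rasters, presence = presence,
       true_center = c(lon = cx, lat = cy), true_field = truth)
}

#' Thin occurrence points to one per grid cell
#'
#' Keeps the first point (input order) in each `cell_km` x `cell_km`
#' latitude/longitude cell — the usual pre-modelling thinning that avoids
#' unbalanced sampling.
#'
#' @param points data.frame with `lat`, `lon`.
#' @param cell_km cell edge in km (default 1).
#' @return The retained rows of `points`.
#' @export
snap_to_grid <- function(points, cell_km = 1) {
  deg_lat <- cell_km / 111.32
  key <- paste(floor(points$lat / deg_lat),
               floor(points$lon * cos(points$lat * pi / 180) / deg_lat))
  points[!duplicated(key), , drop = FALSE]
}
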