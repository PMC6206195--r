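#' One-way analysis of molecular variance (AMOVA)
#'
#' Partitions squared pairwise genetic distances into among-group and
#' within-group variance components (Excoffier-Smouse-Quattro one-level
#' AMOVA), here with river basin as the single grouping factor.
#' Significance of the Phi-statistic is assessed by permuting group labels
#' (group sizes fixed) and recomputing Phi.
#'
#' With `d2[i, j]` the squared distances, `n` samples and `k` groups of
#' sizes `n_g`:
#' \deqn{SS_{tot} = \frac{1}{n}\sum_{i<j} d^2_{ij},\quad
#'       SS_{w} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij},\quad
#'       SS_{a} = SS_{tot} - SS_{w}}
#' Mean squares are SS/df with `df_a = k - 1`, `df_w = n - k`;
#' `sigma2_w = MS_w`, `sigma2_a = (MS_a - MS_w) / n_c` with
#' `n_c = (n - sum(n_g^2)/n) / (k - 1)`, and
#' `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)`. The permutation p-value is
#' `(1 + #\{Phi* >= Phi\}) / (1 + n_perm)`, the observed configuration
#' counting once in numerator and denominator.
#'
#' A negative `sigma2_a` (possible by method-of-moments) is reported as
#' computed; only the displayed percent variation is clamped to [0, 100].
#'
#' @param dist symmetric distance matrix (e.g. from [distance_matrix()])
#'   or a [stats::dist] object.
#' @param groups group label per sample (length n, at least 2 distinct
#'   labels each with at least 1 sample; n >= 3).
#' @param n_perm number of label permutations (default 999; 0 skips the
#'   test).
#' @param seed RNG seed for the permutations (default 1, for
#'   reproducibility).
#' @return An object of class `amova_oneway` with fields `ss_among`,
#'   `ss_within`, `ss_total`, `df_among`, `df_within`, `ms_among`,
#'   `ms_within`, `sigma2_among`, `sigma2_within`, `n_c`, `phi_st`,
#'   `pct_among` (sigma^2-based, raw), `ss_pct_among` (SS-ratio
#'   alternative), `p_value`, `n_perm`, `group_sizes`.
#' @examples
#' d <- distance_matrix(dna_alignment(c(a1 = "AAAA", a2 = "AAAT",
#'                                      b1 = "GGGG", b2 = "GGGC")))
#' amova_oneway(d, c("x", "x", "y", "y"), n_perm = 99)
#' @export
amova_oneway <- function(dist, groups, n_perm = 999, seed = 1L) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist) ||
      any(abs(dist - t(dist)) > 1e-12) || any(dist < 0)) {
    ds_stop("dist must be a symmetric non-negative square matrix",
            "parameter_error")
  }
  n <- nrow(dist)
  groups <- as.character(groups)
  if (length(groups) != n) {
    ds_stop("one group label per sample is required", "parameter_error")
  }
  if (n < 3L) ds_stop("AMOVA needs at least 3 samples", "parameter_error")
  sizes <- table(groups)
  k <- length(sizes)
  if (k < 2L) {
    ds_stop("AMOVA needs at least 2 non-empty groups",
            "degenerate_grouping_error")
  }
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 0) {
    ds_stop("n_perm must be a single non-negative number", "parameter_error")
  }
  n_perm <- as.integer(n_perm)

  d2 <- dist^2
  idx_by_group <- split(seq_len(n), groups)

  ss_parts <- function(member_idx) {
    # sum over i<j within each index set of d2, weighted 1/n_g
    sum(vapply(member_idx, function(ix) {
      sub <- d2[ix, ix, drop = FALSE]
      sum(sub[upper.tri(sub)]) / length(ix)
    }, numeric(1)))
  }

  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- ss_parts(idx_by_group)
  ss_among <- ss_total - ss_within
  df_among <- k - 1L
  df_within <- n - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_c <- (n - sum(sizes^2) / n) / (k - 1)
  sigma2_among <- (ms_among - ms_within) / n_c
  sigma2_within <- ms_within
  denom <- sigma2_among + sigma2_within
  if (denom == 0) {
    ds_stop("both variance components are zero; Phi undefined",
            "undefined_percentage_error")
  }
  phi <- sigma2_among / denom

  phi_from_ssw <- function(ssw) {
    msa <- (ss_total - ssw) / df_among
    msw <- ssw / df_within
    s2a <- (msa - msw) / n_c
    s2a / (s2a + msw)
  }

  p_value <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old_seed))
          assign(".Random.seed", old_seed, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    sz <- as.integer(sizes)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      member_idx <- split(perm, rep.int(seq_len(k), sz))
      phi_b <- phi_from_ssw(ss_parts(member_idx))
      if (phi_b >= phi - 1e-12) exceed <- exceed + 1L
    }
    p_value <- (1 + exceed) / (1 + n_perm)
  }

  structure(list(
    ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
    df_among = df_among, df_within = df_within,
    ms_among = ms_among, ms_within = ms_within,
    sigma2_among = sigma2_among, sigma2_within = sigma2_within,
    n_c = n_c, phi_st = phi,
    pct_among = 100 * sigma2_among / denom,
    ss_pct_among = 100 * ss_among / ss_total,
    p_value = p_value, n_perm = n_perm,
    group_sizes = sizes, seed = seed
  ), class = "amova_oneway")
}

#' Percent variation among groups
#'
#' `100 * sigma2_among / (sigma2_among + sigma2_within)` — the share of the
#' molecular variance explained by the grouping factor. The raw value is
#' returned; display rounding to whole percent happens in `print()`.
#'
#' @param result an `amova_oneway` object.
#' @return Percent (numeric scalar, possibly negative if the among-group
#'   component was estimated negative).
#' @export
pct_variation <- function(result) {
  stopifnot(inherits(result, "amova_oneway"))
  denom <- result$sigma2_among + result$sigma2_within
  if (denom == 0) {
    ds_stop("both variance components are zero; percentage undefined",
            "undefined_percentage_error")
  }
  100 * result$sigma2_among / denom
}

#' @export
print.amova_oneway <- function(x, ...) {
  cat("One-way AMOVA\n")
  tab <- data.frame(
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    SS = c(x$ss_among, x$ss_within, x$ss_total),
    MS = c(x$ms_among, x$ms_within, NA),
    sigma2 = c(x$sigma2_among, x$sigma2_within, NA),
    row.names = c("Among groups", "Within groups", "Total"))
  print(format(tab, digits = 6))
  pct <- min(100, max(0, pct_variation(x)))
  cat(sprintf("Phi_ST = %.6f  (%.0f%% of variation among groups)\n",
              x$phi_st, pct))
  if (!is.na(x$p_value)) {
    cat(sprintf("Permutation p-value = %.4g  (%d permutations, seed %s)\n",
                x$p_value, x$n_perm, format(x$seed)))
  }
  invisible(x)
}

#' @export
summary.amova_oneway <- function(object, ...) {
  print(object)
  cat(sprintf("Groups (%d): %s\n", length(object$group_sizes),
              paste(sprintf("%s=%d", names(object$group_sizes),
                            object$group_sizes), collapse = ", ")))
  cat(sprintf("SS-ratio percent among groups: %.1f%%\n", object$ss_pct_among))
  invisible(object)
}

#' Write an AMOVA result as TSV
#'
#' @param result an `amova_oneway` object.
#' @param path output path.
#' @export
write_amova_table <- function(result, path) {
  stopifnot(inherits(result, "amova_oneway"))
  flat <- result[c("ss_among", "ss_within", "ss_total", "df_among",
                   "df_within", "sigma2_among", "sigma2_within", "phi_st",
                   "pct_among", "ss_pct_among", "p_value", "n_perm")]
  df <- data.frame(field = names(flat),
                   value = vapply(flat, function(v) format(v, digits = 10),
                                  character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
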