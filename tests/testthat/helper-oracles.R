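# Independent brute-force oracles and small random-data generators used
# across the suite. Everything here enumerates definitions directly and
# shares no code with the package internals.

BASES <- c("A", "C", "G", "T")

# random gapped/ambiguous alignment as a character matrix
random_alignment <- function(n, L, p_missing = 0.05) {
  pool <- c(rep(BASES, each = 6), "N", "-")
  if (p_missing == 0) pool <- BASES
  m <- matrix(sample(pool, n * L, replace = TRUE), n, L)
  rownames(m) <- paste0("s", seq_len(n))
  m
}

oracle_p_distance <- function(a, b) {
  comp <- which(a %in% BASES & b %in% BASES)
  if (length(comp) == 0) return(NA_real_)
  sum(a[comp] != b[comp]) / length(comp)
}

oracle_pi <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + oracle_p_distance(m[i, ], m[j, ])
  }
  tot / choose(n, 2)
}

oracle_theta_w <- function(m) {
  keep <- apply(m, 2, function(col) all(col %in% BASES))
  mm <- m[, keep, drop = FALSE]
  if (ncol(mm) == 0) return(NA_real_)
  S <- sum(apply(mm, 2, function(col) length(unique(col)) > 1))
  S / (sum(1 / seq_len(nrow(m) - 1)) * ncol(mm))
}

oracle_hap_div <- function(m) {
  n <- nrow(m)
  counts <- table(apply(m, 1, paste0, collapse = ""))
  (n / (n - 1)) * (1 - sum((counts / n)^2))
}

oracle_between <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    tot <- tot + oracle_p_distance(a[i, ], b[j, ])
  }
  tot / (nrow(a) * nrow(b))
}

# spherical law-of-cosines haversine, written independently
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad; dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * r * asin(sqrt(a))
}

# direct AMOVA arithmetic from the defining sums, no shared code
oracle_amova_ss <- function(d, groups) {
  d2 <- d^2
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    ix <- which(groups == g)
    sub <- d2[ix, ix, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(ix)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# random coordinates in the Iberian box
random_points <- function(n) {
  data.frame(lat = runif(n, 36, 44), lon = runif(n, -9, 3))
}
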