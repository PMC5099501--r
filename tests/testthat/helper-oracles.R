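# Independent oracles, deliberately implemented with different algorithms
# than the package: full-matrix dynamic-programming edit distance, spherical
# law-of-cosines distance, closed-form Pearson, exhaustive-enumeration rank
# tests, and a brute-force relative-cost computation with explicit loops.

# Full-matrix DP Levenshtein distance.
lev_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n; D[1L, ] <- 0:m
  if (n > 0 && m > 0)
    for (i in 1:n) for (j in 1:m)
      D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L,
                               D[i, j] + (x[i] != y[j]))
  D[n + 1L, m + 1L]
}

# Spherical law of cosines great-circle distance (miles, R = 3958.8).
slc_miles <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  arg <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  3958.8 * acos(pmin(1, pmax(-1, arg)))
}

# Closed-form Pearson r and t-transform p-value.
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Exhaustive signed-rank two-sided p over all 2^n sign assignments
# (distinct nonzero |differences| assumed).
signrank_oracle_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% rk)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Exhaustive Mann-Whitney two-sided p over all rank assignments
# (no ties assumed).
ranksum_oracle_p <- function(a, b) {
  m <- length(a); n <- length(b)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  all_rk <- seq_len(m + n)
  u_all <- apply(combos, 2, function(ix) sum(all_rk[ix])) - m * (m + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Brute-force relative cost: explicit all-pairs distances (law of cosines),
# explicit neighborhood sort, explicit min-max, explicit weighted average.
relative_cost_oracle <- function(charges, providers, k, radius) {
  # collapse duplicate (provider, code) rows by procedure-weighted mean
  key <- paste(charges$provider_id, charges$hcpcs_code)
  rows <- list()
  for (kk in unique(key)) {
    sub <- charges[key == kk, , drop = FALSE]
    rows[[kk]] <- data.frame(
      provider_id = sub$provider_id[1], hcpcs_code = sub$hcpcs_code[1],
      avg_charged = sum(sub$avg_charged * sub$n_procedures) / sum(sub$n_procedures),
      n_procedures = sum(sub$n_procedures), stringsAsFactors = FALSE)
  }
  ch <- do.call(rbind, rows)
  out <- numeric(0)
  for (p in unique(ch$provider_id)) {
    prow <- providers[providers$provider_id == p, ]
    if (is.na(prow$lat) || is.na(prow$lon)) { out[p] <- NA_real_; next }
    mine <- ch[ch$provider_id == p, , drop = FALSE]
    rels <- numeric(nrow(mine)); wts <- mine$n_procedures
    for (i in seq_len(nrow(mine))) {
      peers <- ch[ch$hcpcs_code == mine$hcpcs_code[i], , drop = FALSE]
      pr <- providers[match(peers$provider_id, providers$provider_id), ]
      keep <- pr$specialty == prow$specialty & !is.na(pr$lat) & !is.na(pr$lon)
      peers <- peers[keep, , drop = FALSE]; pr <- pr[keep, , drop = FALSE]
      d <- slc_miles(prow$lat, prow$lon, pr$lat, pr$lon)
      inside <- d <= radius
      peers <- peers[inside, , drop = FALSE]; d <- d[inside]
      ord <- order(d, peers$provider_id)
      nb <- peers[ord[seq_len(min(k, length(ord)))], , drop = FALSE]
      if (!p %in% nb$provider_id)
        nb <- rbind(nb, mine[i, names(nb), drop = FALSE])
      lo <- min(nb$avg_charged); hi <- max(nb$avg_charged)
      rels[i] <- if (hi == lo) 100 else
        100 * (mine$avg_charged[i] - lo) / (hi - lo)
    }
    out[p] <- sum(rels * wts) / sum(wts)
  }
  out
}

random_string <- function(len, alphabet = letters[1:6]) {
  if (len == 0) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A tiny fully-specified directory for linkage unit tests.
toy_directory <- function(n = 6, seed = 99) {
  set.seed(seed)
  data.frame(
    provider_id = sprintf("A%02d", seq_len(n)),
    first_name = c("alice", "bob", "carol", "dan", "erin", "frank")[seq_len(n)],
    middle_name = letters[seq_len(n)],
    last_name = c("archer", "baker", "cooper", "draper", "fisher", "glover")[seq_len(n)],
    address = paste(101:(100 + n), "main st"),
    state = rep(c("CA", "NY"), length.out = n),
    medical_school = rep("state medical school", n),
    graduation_year = 1990 + seq_len(n),
    affiliated_hospitals = rep("H1;H2", n),
    specialties = rep("Internal Medicine", n),
    specialty = rep("Internal Medicine", n),
    lat = runif(n, 30, 31), lon = runif(n, -120, -119),
    stringsAsFactors = FALSE)
}
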