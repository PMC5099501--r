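# Derivation of per-provider attributes: review-rating averages, hospital
# scores via the specialty->ranking-category map, rank imputation for
# unranked hospitals, and the geographic relative-cost score.

#' Review-count-weighted average rating
#'
#' Combines review scores from several linked source profiles into one
#' 0-100 rating, weighting each source by its review count. Absent (NA) when
#' the total review count is zero.
#'
#' @param ratings numeric vector of source ratings in \[0, 100\].
#' @param counts nonnegative integer vector of review counts per source.
#' @return numeric scalar or NA.
#' @export
#' @examples
#' average_rating(c(80, 90), c(3, 1))  # 82.5
average_rating <- function(ratings, counts) {
  keep <- !is.na(ratings) & !is.na(counts)
  ratings <- ratings[keep]; counts <- counts[keep]
  if (any(ratings < 0 | ratings > 100))
    stop("average_rating: ratings must be in [0, 100]", call. = FALSE)
  if (any(counts < 0))
    stop("average_rating: review counts must be >= 0", call. = FALSE)
  if (length(counts) == 0L || sum(counts) == 0) return(NA_real_)
  sum(ratings * counts) / sum(counts)
}

#' Hospital score for a provider's specialty
#'
#' Mean of the hospital's ranking-category scores over the categories the
#' provider's specialty maps to; NA if the specialty is unmapped or the
#' hospital is scored in none of the mapped categories.
#'
#' @param hospital_scores named numeric vector: ranking category -> score,
#'   for one hospital.
#' @param provider_specialty specialty name.
#' @param smap a [build_specialty_map()] object.
#' @return numeric scalar or NA.
#' @export
hospital_category_score <- function(hospital_scores, provider_specialty, smap) {
  cats <- smap$entries[[provider_specialty]]
  if (is.null(cats)) return(NA_real_)
  sc <- hospital_scores[intersect(cats, names(hospital_scores))]
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0L) return(NA_real_)
  mean(sc)
}

#' Provider hospital score: maximum over affiliations
#'
#' The provider's hospital score is the maximum of
#' [hospital_category_score()] over affiliated hospitals; NA when no
#' affiliation yields a score.
#'
#' @param affiliation_scores list of named numeric vectors (one per
#'   affiliated hospital: category -> score).
#' @inheritParams hospital_category_score
#' @return numeric scalar or NA.
#' @export
provider_hospital_score <- function(affiliation_scores, provider_specialty, smap) {
  vals <- vapply(affiliation_scores, hospital_category_score,
                 numeric(1), provider_specialty = provider_specialty, smap = smap)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  max(vals)
}

#' Impute ranks for unranked hospitals
#'
#' Ranked hospitals keep their ranks 1..m; every unranked hospital is placed
#' at the bottom of the list and receives the median of the bottom positions
#' m+1..N, i.e. (m + 1 + N) / 2 rounded half-up.
#'
#' @param hospitals data.frame with columns `hospital_id` and `rank`
#'   (NA for unranked).
#' @return the input with an integer `rank_imputed` column.
#' @export
#' @examples
#' h <- data.frame(hospital_id = 1:4, rank = c(1, NA, NA, 2))
#' impute_hospital_ranks(h)$rank_imputed  # 1 4 4 2  (median of 3..4 -> 3.5 -> 4)
impute_hospital_ranks <- function(hospitals) {
  ranked <- hospitals$rank[!is.na(hospitals$rank)]
  if (anyDuplicated(ranked))
    stop("impute_hospital_ranks: duplicate ranks among ranked hospitals", call. = FALSE)
  if (length(ranked) && any(ranked < 1))
    stop("impute_hospital_ranks: ranks must be positive", call. = FALSE)
  m <- length(ranked); N <- nrow(hospitals)
  fill <- if (m == N) NA_integer_ else as.integer(round_half_up((m + 1 + N) / 2))
  hospitals$rank_imputed <- ifelse(is.na(hospitals$rank), fill,
                                   as.integer(hospitals$rank))
  hospitals
}

#' Great-circle distance in miles
#'
#' Haversine distance with Earth radius 3958.8 miles. Vectorized.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees.
#' @return numeric vector of distances in miles.
#' @export
haversine_miles <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("haversine_miles: latitude out of [-90, 90]", call. = FALSE)
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("haversine_miles: longitude out of [-180, 180]", call. = FALSE)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  geosphere::distHaversine(
    cbind(rep_len(lon1, n), rep_len(lat1, n)),
    cbind(rep_len(lon2, n), rep_len(lat2, n)),
    r = 3958.8)
}

# Collapse multiple charge rows per (provider, code) to one: procedure-count
# weighted mean charge, summed procedure count.
collapse_charges <- function(charges) {
  key <- paste(charges$provider_id, charges$hcpcs_code, sep = "\r")
  tot <- rowsum(charges$n_procedures, key)
  amt <- rowsum(charges$avg_charged * charges$n_procedures, key) / tot
  first <- !duplicated(key)
  out <- data.frame(provider_id = charges$provider_id[first],
                    hcpcs_code = charges$hcpcs_code[first],
                    stringsAsFactors = FALSE)
  ord <- match(paste(out$provider_id, out$hcpcs_code, sep = "\r"), rownames(tot))
  out$avg_charged <- as.numeric(amt[ord])
  out$n_procedures <- as.numeric(tot[ord])
  out
}

#' Relative cost with respect to area
#'
#' For each provider and each of its HCPCS procedure codes, compares the
#' provider's average charged amount with those of same-specialty providers
#' billing the same code within `radius_miles` (the `k` nearest by haversine
#' distance, ties broken by ascending provider id, the provider itself always
#' included). The charge is min-max normalized to 0-100 over that
#' neighborhood (100 = most expensive; degenerate neighborhoods with
#' max = min score 100). Per-code relative charges are then averaged with
#' weights proportional to the provider's procedure counts.
#'
#' @param charges data.frame with `provider_id`, `hcpcs_code`, `avg_charged`
#'   (> 0), `n_procedures` (>= 1). Multiple rows per (provider, code) are
#'   collapsed by procedure-count-weighted mean first.
#' @param providers geolocated directory: data.frame with `provider_id`,
#'   `lat`, `lon`, `specialty`.
#' @param k neighborhood size (default 1000).
#' @param radius_miles neighborhood radius (default 30).
#' @return data.frame with `provider_id` and `relative_cost` in \[0, 100\]
#'   (NA for providers without charges or geolocation), one row per provider
#'   appearing in `charges`.
#' @export
relative_costs <- function(charges, providers, k = 1000, radius_miles = 30) {
  if (any(charges$avg_charged <= 0))
    stop("relative_costs: avg_charged must be > 0", call. = FALSE)
  if (any(charges$n_procedures < 1))
    stop("relative_costs: n_procedures must be >= 1", call. = FALSE)
  ch <- collapse_charges(charges)
  geo <- providers[match(ch$provider_id, providers$provider_id),
                   c("provider_id", "lat", "lon", "specialty")]
  ch$lat <- geo$lat; ch$lon <- geo$lon; ch$specialty <- geo$specialty
  no_geo <- is.na(ch$lat) | is.na(ch$lon)
  if (any(no_geo))
    warning(sprintf("relative_costs: %d charge rows dropped for missing geolocation",
                    sum(no_geo)))
  ch$rel <- NA_real_
  groups <- split(seq_len(nrow(ch)), paste(ch$specialty, ch$hcpcs_code, sep = "\r"))
  for (idx in groups) {
    sub <- ch[idx, , drop = FALSE]
    usable <- which(!(is.na(sub$lat) | is.na(sub$lon)))
    if (length(usable) == 0L) next
    g <- sub[usable, , drop = FALSE]
    dm <- outer_haversine(g$lat, g$lon)
    for (j in seq_len(nrow(g))) {
      within <- which(dm[j, ] <= radius_miles)
      ord <- within[order(dm[j, within], g$provider_id[within])]
      nb <- utils::head(ord, max(k, 1L))
      if (!(j %in% nb)) nb <- c(j, nb)  # the provider itself is always in scope
      amounts <- g$avg_charged[nb]
      lo <- min(amounts); hi <- max(amounts)
      ch$rel[idx[usable[j]]] <-
        if (hi == lo) 100 else 100 * (g$avg_charged[j] - lo) / (hi - lo)
    }
  }
  ids <- unique(ch$provider_id)
  out <- data.frame(provider_id = ids, relative_cost = NA_real_,
                    stringsAsFactors = FALSE)
  ok <- !is.na(ch$rel)
  if (any(ok)) {
    w <- rowsum(ch$n_procedures[ok], ch$provider_id[ok])
    v <- rowsum(ch$rel[ok] * ch$n_procedures[ok], ch$provider_id[ok]) / w
    out$relative_cost <- as.numeric(v[match(ids, rownames(v))])
  }
  out
}

# Symmetric haversine distance matrix for one set of points.
outer_haversine <- function(lat, lon) {
  n <- length(lat)
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  matrix(haversine_miles(lat[i], lon[i], lat[j], lon[j]), n, n)
}

#' Relative cost for a single provider
#'
#' Convenience wrapper around [relative_costs()].
#'
#' @param provider_id provider identifier.
#' @inheritParams relative_costs
#' @return numeric scalar or NA.
#' @export
relative_cost <- function(provider_id, charges, providers, k = 1000,
                          radius_miles = 30) {
  out <- relative_costs(charges, providers, k = k, radius_miles = radius_miles)
  out$relative_cost[match(provider_id, out$provider_id)]
}

#' Derive the provider attribute table
#'
#' Joins linked review-site profiles onto the base directory and derives one
#' attribute row per linked provider: review-count-weighted rating, total
#' review count, Castle Connolly flag, referral count (optionally z-scored
#' within specialty), specialty-mapped hospital score (max over
#' affiliations), mean imputed hospital rank over affiliations, and the
#' geographic relative-cost score.
#'
#' @param links accepted link pairs: data.frame with `id_a` (directory id)
#'   and `id_b` (site profile id), e.g. `link_set$accepted` or ground-truth
#'   pairs.
#' @param cms_providers base directory with `provider_id`, `state`,
#'   `specialty`, `lat`, `lon`, `affiliated_hospitals`.
#' @param reviews data.frame `site_id`, `rating`, `n_reviews`.
#' @param site_providers site directory with `provider_id` and
#'   `castle_connolly`.
#' @param referrals data.frame `provider_id`, `n_referrals`.
#' @param charges charge records (see [relative_costs()]).
#' @param hospitals hospital table with `hospital_id`, `rank`.
#' @param hospital_scores long table `hospital_id`, `category`, `score`.
#' @param smap a [build_specialty_map()] object.
#' @param k,radius_miles neighborhood parameters for [relative_costs()].
#' @param referral_norm `"none"` (raw counts, default) or `"specialty_z"`
#'   (z-score within specialty).
#' @return data.frame of class `provider_attributes`, one row per linked
#'   provider.
#' @export
derive_attributes <- function(links, cms_providers, reviews, site_providers,
                              referrals, charges, hospitals, hospital_scores,
                              smap, k = 1000, radius_miles = 30,
                              referral_norm = c("none", "specialty_z")) {
  referral_norm <- match.arg(referral_norm)
  ids <- unique(links$id_a)
  cms <- cms_providers[match(ids, cms_providers$provider_id), , drop = FALSE]
  out <- data.frame(provider_id = ids, state = cms$state,
                    specialty = cms$specialty, stringsAsFactors = FALSE)
  if (length(ids) == 0L) {
    out <- cbind(out, user_rating = numeric(0), n_reviews = numeric(0),
                 castle_connolly = logical(0), num_referrals = numeric(0),
                 hospital_score = numeric(0), hospital_rank = numeric(0),
                 relative_cost = numeric(0))
    class(out) <- c("provider_attributes", "data.frame")
    return(out)
  }

  # ratings / reviews / award over all site profiles linked to each provider
  # (review-count-weighted mean, same rule as average_rating(), vectorized)
  rv <- reviews[match(links$id_b, reviews$site_id), , drop = FALSE]
  cc <- site_providers$castle_connolly[match(links$id_b, site_providers$provider_id)]
  if (any(rv$rating < 0 | rv$rating > 100, na.rm = TRUE))
    stop("derive_attributes: ratings must be in [0, 100]", call. = FALSE)
  w <- ifelse(is.na(rv$rating) | is.na(rv$n_reviews), 0, rv$n_reviews)
  rsum <- rowsum(w * ifelse(w > 0, rv$rating, 0), links$id_a)
  wsum <- rowsum(w, links$id_a)
  rate <- ifelse(wsum > 0, rsum / wsum, NA_real_)
  out$user_rating <- as.numeric(rate[match(ids, rownames(rsum))])
  nrev <- rowsum(ifelse(is.na(rv$n_reviews), 0, rv$n_reviews), links$id_a)
  out$n_reviews <- as.numeric(nrev[match(ids, rownames(nrev))])
  ccs <- rowsum(ifelse(is.na(cc), 0, as.numeric(cc)), links$id_a)
  out$castle_connolly <- as.numeric(ccs[match(ids, rownames(ccs))]) > 0

  nr <- referrals$n_referrals[match(ids, referrals$provider_id)]
  nr[is.na(nr)] <- 0
  if (referral_norm == "specialty_z") {
    for (sp in unique(out$specialty)) {
      sel <- out$specialty == sp
      s <- stats::sd(nr[sel])
      nr[sel] <- if (is.na(s) || s == 0) 0 else (nr[sel] - mean(nr[sel])) / s
    }
  }
  out$num_referrals <- nr

  # hospital score (max over affiliations of the category mean) and mean
  # imputed affiliation rank
  hosp <- impute_hospital_ranks(hospitals)
  score_list <- split(setNames(hospital_scores$score, hospital_scores$category),
                      hospital_scores$hospital_id)
  aff <- lapply(cms$affiliated_hospitals, split_set)
  out$hospital_score <- vapply(seq_along(ids), function(i) {
    provider_hospital_score(score_list[intersect(aff[[i]], names(score_list))],
                            out$specialty[i], smap)
  }, numeric(1))
  rank_of <- setNames(hosp$rank_imputed, hosp$hospital_id)
  out$hospital_rank <- vapply(aff, function(a) {
    r <- rank_of[intersect(a, names(rank_of))]
    if (length(r) == 0L) NA_real_ else mean(r)
  }, numeric(1))

  rc <- relative_costs(charges, cms_providers, k = k, radius_miles = radius_miles)
  out$relative_cost <- rc$relative_cost[match(ids, rc$provider_id)]

  class(out) <- c("provider_attributes", "data.frame")
  out
}
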