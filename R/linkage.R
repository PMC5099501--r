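# Fuzzy record linkage of provider directories: edit-distance similarity,
# insurance-name mapping, weighted multi-attribute matching with blocking,
# greedy one-to-at-most-one assignment, and threshold calibration.

MATCH_ATTRIBUTES <- c("first_name", "middle_name", "last_name", "address",
                      "medical_school", "graduation_year",
                      "affiliated_hospitals", "specialties")

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and substitutions
#' transforming `a` into `b`. Vectorized elementwise with recycling.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
#' @examples
#' levenshtein("kitten", "sitting")  # 3
levenshtein <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    if (is.na(a[i]) || is.na(b[i])) return(NA_integer_)
    as.integer(utils::adist(a[i], b[i]))
  }, integer(1))
}

#' Normalized name similarity
#'
#' `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`, computed after
#' canonicalization (case-fold, strip punctuation, collapse whitespace) when
#' `canonicalize = TRUE`. Two empty strings have similarity 1.
#'
#' @param a,b character vectors (recycled).
#' @param canonicalize canonicalize before comparing?
#' @return numeric vector in \[0, 1\]; NA where either input is NA.
#' @export
#' @examples
#' name_similarity("smith", "smith")  # 1
name_similarity <- function(a, b, canonicalize = TRUE) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (canonicalize) {
    a <- ifelse(is.na(a), NA, canonicalize_string(a))
    b <- ifelse(is.na(b), NA, canonicalize_string(b))
  }
  d <- levenshtein(a, b)
  len <- pmax(nchar(a), nchar(b))
  out <- ifelse(len == 0L, 1, 1 - d / len)
  ifelse(is.na(a) | is.na(b), NA_real_, out)
}

#' Map insurance-name strings between two sources
#'
#' Maps each name in `names_a` to its most similar name in `names_b` by
#' normalized Levenshtein similarity, subject to `min_similarity`.
#' A trailing two-letter state code (", CA") is compared exactly: names are
#' never mapped across states. Similarity is computed on the canonicalized
#' name part. Ties are broken by the lexicographically smallest candidate.
#'
#' @param names_a,names_b character vectors of insurance names.
#' @param min_similarity minimal similarity in \[0, 1\] for a mapping.
#' @return data.frame with columns `name_a`, `name_b`, `similarity`; unmapped
#'   names of `names_a` are in `attr(, "unmapped")`.
#' @export
#' @examples
#' match_insurance_names("Aetna Life Insurance, AR",
#'                       c("Aetna HMO, AR", "Aetna HMO, CA"))
match_insurance_names <- function(names_a, names_b, min_similarity = 0.6) {
  if (!is.numeric(min_similarity) || min_similarity < 0 || min_similarity > 1)
    config_error("min_similarity", "must be in [0, 1]")
  names_a <- unique(as.character(names_a))
  names_b <- unique(as.character(names_b))
  pa <- split_state_suffix(names_a)
  pb <- split_state_suffix(names_b)
  ca <- canonicalize_string(pa$name)
  cb <- canonicalize_string(pb$name)
  sa <- ifelse(is.na(pa$state), "<none>", pa$state)
  sb <- ifelse(is.na(pb$state), "<none>", pb$state)

  map_b <- rep(NA_integer_, length(names_a))
  map_sim <- rep(NA_real_, length(names_a))
  for (st in intersect(unique(sa), unique(sb))) {
    ia <- which(sa == st); ib <- which(sb == st)
    d <- utils::adist(ca[ia], cb[ib])
    len <- outer(nchar(ca[ia]), nchar(cb[ib]), pmax)
    sims <- ifelse(len == 0L, 1, 1 - d / len)
    for (r in seq_along(ia)) {
      ok <- which(sims[r, ] >= min_similarity)
      if (length(ok) == 0L) next
      best <- ok[order(-sims[r, ok], names_b[ib][ok])][1L]
      map_b[ia[r]] <- ib[best]
      map_sim[ia[r]] <- sims[r, best]
    }
  }
  hit <- !is.na(map_b)
  out <- data.frame(name_a = names_a[hit], name_b = names_b[map_b[hit]],
                    similarity = map_sim[hit], stringsAsFactors = FALSE)
  attr(out, "unmapped") <- names_a[!hit]
  out
}

#' Default attribute weights for provider matching
#'
#' Nonnegative weights over the eight matching attributes (first, middle and
#' last name, address, medical school, graduation year, affiliated hospitals,
#' specialties), normalized to sum 1. Name fields dominate.
#'
#' @return named numeric vector of length 8 summing to 1.
#' @export
default_weights <- function() {
  w <- c(first_name = 0.2, middle_name = 0.05, last_name = 0.3,
         address = 0.15, medical_school = 0.1, graduation_year = 0.05,
         affiliated_hospitals = 0.075, specialties = 0.075)
  w / sum(w)
}

validate_weights <- function(weights) {
  if (!is.numeric(weights) || is.null(names(weights)) ||
      !setequal(names(weights), MATCH_ATTRIBUTES))
    config_error("weights", "must be a named numeric vector over the eight matching attributes")
  if (any(weights < 0)) config_error("weights", "must be nonnegative")
  if (sum(weights) <= 0) config_error("weights", "must have positive sum")
  weights[MATCH_ATTRIBUTES] / sum(weights)
}

#' Per-attribute match scores for a pair of provider records
#'
#' Name-like fields (first, middle, last name, address, medical school) are
#' scored by normalized Levenshtein similarity; graduation year scores 1 on
#' equality and 0 otherwise; affiliated hospitals and specialties (";"
#' separated sets) score their Jaccard overlap. A field absent on either side
#' yields NA (missing evidence, excluded from the weighted combination).
#'
#' @param rec_a,rec_b provider records: lists or one-row data.frames with
#'   (any of) the eight matching attributes.
#' @return named numeric vector of length 8 in \[0, 1\], NA where missing.
#' @export
attribute_scores <- function(rec_a, rec_b) {
  rec_a <- as.list(rec_a); rec_b <- as.list(rec_b)
  get1 <- function(r, f) {
    v <- r[[f]]
    if (is.null(v) || length(v) == 0L) return(NA)
    v[[1L]]
  }
  out <- setNames(rep(NA_real_, 8L), MATCH_ATTRIBUTES)
  for (f in c("first_name", "middle_name", "last_name", "address", "medical_school")) {
    va <- get1(rec_a, f); vb <- get1(rec_b, f)
    if (!is.na(va) && !is.na(vb)) out[f] <- name_similarity(va, vb)
  }
  ya <- get1(rec_a, "graduation_year"); yb <- get1(rec_b, "graduation_year")
  if (!is.na(ya) && !is.na(yb)) out["graduation_year"] <- as.numeric(ya == yb)
  for (f in c("affiliated_hospitals", "specialties")) {
    va <- rec_a[[f]]; vb <- rec_b[[f]]
    sa <- if (is.character(va) && length(va) == 1L) split_set(va) else as.character(va %||% character(0))
    sb <- if (is.character(vb) && length(vb) == 1L) split_set(vb) else as.character(vb %||% character(0))
    out[f] <- jaccard(sa, sb)
  }
  out
}

#' Combine per-attribute scores into a single match score
#'
#' Weighted mean over the non-missing scores, with the weights renormalized
#' to sum 1 over those scores.
#'
#' @param scores named numeric vector as from [attribute_scores()].
#' @param weights named nonnegative weights; normalized internally.
#' @return numeric scalar in \[0, 1\].
#' @export
#' @examples
#' combined_score(c(a = 1, b = 0), c(a = 0.5, b = 0.5))  # 0.5
combined_score <- function(scores, weights = default_weights()) {
  if (is.null(names(scores))) names(scores) <- names(weights)
  if (any(weights < 0)) config_error("weights", "must be nonnegative")
  keep <- !is.na(scores)
  if (!any(keep)) stop("combined_score: all attribute scores are missing", call. = FALSE)
  w <- weights[names(scores)[keep]]
  sum(w * scores[keep]) / sum(w)
}

# Incidence-matrix Jaccard between two lists of ";"-set strings.
# Returns an n_a x n_b matrix; rows/cols with empty sets are NA.
jaccard_matrix <- function(sets_a, sets_b) {
  la <- lapply(sets_a, split_set)
  lb <- lapply(sets_b, split_set)
  items <- unique(c(unlist(la), unlist(lb)))
  na <- length(la); nb <- length(lb)
  if (length(items) == 0L) return(matrix(NA_real_, na, nb))
  A <- matrix(0L, na, length(items))
  B <- matrix(0L, nb, length(items))
  for (i in seq_len(na)) A[i, match(la[[i]], items)] <- 1L
  for (i in seq_len(nb)) B[i, match(lb[[i]], items)] <- 1L
  inter <- A %*% t(B)
  sa <- rowSums(A); sb <- rowSums(B)
  uni <- outer(sa, sb, "+") - inter
  out <- inter / uni
  out[sa == 0L, ] <- NA_real_
  out[, sb == 0L] <- NA_real_
  out
}

# Normalized-similarity matrix between two character vectors (NA propagates).
similarity_matrix <- function(a, b) {
  ca <- ifelse(is.na(a), NA, canonicalize_string(a))
  cb <- ifelse(is.na(b), NA, canonicalize_string(b))
  d <- utils::adist(ca, cb)
  len <- outer(nchar(ca), nchar(cb), pmax)
  out <- ifelse(len == 0L, 1, 1 - d / len)
  out[is.na(ca), ] <- NA_real_
  out[, is.na(cb)] <- NA_real_
  out
}

# Score all candidate pairs between two directory blocks. Returns a
# data.frame of id pairs, per-attribute scores and the combined score.
score_block <- function(dir_a, dir_b, weights) {
  na <- nrow(dir_a); nb <- nrow(dir_b)
  mats <- list(
    first_name = similarity_matrix(dir_a$first_name, dir_b$first_name),
    middle_name = similarity_matrix(dir_a$middle_name, dir_b$middle_name),
    last_name = similarity_matrix(dir_a$last_name, dir_b$last_name),
    address = similarity_matrix(dir_a$address, dir_b$address),
    medical_school = similarity_matrix(dir_a$medical_school, dir_b$medical_school),
    graduation_year = {
      m <- outer(dir_a$graduation_year, dir_b$graduation_year,
                 function(x, y) as.numeric(x == y))
      m
    },
    affiliated_hospitals = jaccard_matrix(dir_a$affiliated_hospitals,
                                          dir_b$affiliated_hospitals),
    specialties = jaccard_matrix(dir_a$specialties, dir_b$specialties)
  )
  wsum <- matrix(0, na, nb); wtot <- matrix(0, na, nb)
  for (f in MATCH_ATTRIBUTES) {
    m <- mats[[f]]
    ok <- !is.na(m)
    wsum[ok] <- wsum[ok] + weights[f] * m[ok]
    wtot[ok] <- wtot[ok] + weights[f]
  }
  score <- ifelse(wtot > 0, wsum / wtot, NA_real_)
  out <- data.frame(
    id_a = rep(dir_a$provider_id, times = nb),
    id_b = rep(dir_b$provider_id, each = na),
    stringsAsFactors = FALSE
  )
  for (f in MATCH_ATTRIBUTES) out[[paste0("s_", f)]] <- as.vector(mats[[f]])
  out$score <- as.vector(score)
  out[!is.na(out$score), , drop = FALSE]
}

blocking_keys <- function(dir, blocking) {
  init <- function(x) {
    x <- canonicalize_string(ifelse(is.na(x), "", x))
    substr(x, 1L, 1L)
  }
  switch(blocking,
    none = list(rep("", nrow(dir))),
    last_initial_state = list(paste(init(dir$last_name), dir$state, sep = "|")),
    either_initial_state = list(
      paste("L", init(dir$last_name), dir$state, sep = "|"),
      paste("F", init(dir$first_name), dir$state, sep = "|")
    ),
    config_error("blocking", "must be one of 'last_initial_state', 'either_initial_state', 'none'")
  )
}

#' Link two provider directories
#'
#' Scores candidate record pairs restricted to shared blocking keys (default:
#' first letter of the last name plus state), combines per-attribute
#' similarities with `weights`, and accepts pairs greedily in descending
#' combined score, skipping pairs whose b-side record is already matched, so
#' each b-side record maps to at most one a-side record. Only pairs with
#' combined score at or above `threshold` are accepted. Score ties are broken
#' by the smaller (id_a, id_b) pair for determinism.
#'
#' @param dir_a,dir_b data.frames with columns `provider_id`, `state` and the
#'   eight matching attributes (`affiliated_hospitals` and `specialties` as
#'   ";"-separated set strings).
#' @param weights named attribute weights, normalized internally.
#' @param threshold minimal accepted combined score, in \[0, 1\].
#' @param blocking `"last_initial_state"` (default), `"either_initial_state"`
#'   (union of last- and first-initial blocks, for heavily perturbed names)
#'   or `"none"`.
#' @return an object of class `link_set`: list with `scored_pairs` (all
#'   scored candidate pairs), `accepted` (the accepted mapping id_b -> id_a),
#'   `threshold`, `weights`, `blocking`.
#' @export
link_directories <- function(dir_a, dir_b, weights = default_weights(),
                             threshold = 0.85,
                             blocking = c("last_initial_state",
                                          "either_initial_state", "none")) {
  blocking <- match.arg(blocking)
  weights <- validate_weights(weights)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    config_error("threshold", "must be in [0, 1]")
  for (d in list(dir_a, dir_b))
    if (!all(c("provider_id", "state") %in% names(d)))
      stop("directories need 'provider_id' and 'state' columns", call. = FALSE)

  keys_a <- blocking_keys(dir_a, blocking)
  keys_b <- blocking_keys(dir_b, blocking)
  pieces <- list()
  for (ki in seq_along(keys_a)) {
    ka <- keys_a[[ki]]; kb <- keys_b[[ki]]
    for (key in intersect(unique(ka), unique(kb))) {
      pieces[[length(pieces) + 1L]] <-
        score_block(dir_a[ka == key, , drop = FALSE],
                    dir_b[kb == key, , drop = FALSE], weights)
    }
  }
  scored <- if (length(pieces)) do.call(rbind, pieces) else
    score_block(dir_a[0, ], dir_b[0, ], weights)
  # union blocking can score a pair under both keys
  scored <- scored[!duplicated(scored[c("id_a", "id_b")]), , drop = FALSE]
  scored <- scored[order(-scored$score, scored$id_a, scored$id_b), , drop = FALSE]
  rownames(scored) <- NULL

  accepted <- greedy_accept(scored, threshold)
  structure(list(scored_pairs = scored, accepted = accepted,
                 threshold = threshold, weights = weights,
                 blocking = blocking),
            class = "link_set")
}

# Greedy descending-score assignment with b-side at-most-one constraint.
# `scored` must already be sorted by (-score, id_a, id_b).
greedy_accept <- function(scored, threshold) {
  keep <- scored$score >= threshold
  sub <- scored[keep, c("id_a", "id_b", "score"), drop = FALSE]
  first <- !duplicated(sub$id_b)
  out <- sub[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.link_set <- function(x, ...) {
  cat("Provider directory linkage (blocking:", x$blocking, ")\n")
  cat(sprintf("  scored pairs: %d\n  accepted:     %d (threshold %.3f)\n",
              nrow(x$scored_pairs), nrow(x$accepted), x$threshold))
  invisible(x)
}

#' Calibrate the acceptance threshold against ground truth
#'
#' Sweeps every distinct observed combined score of the greedily accepted
#' candidate ranking and returns the threshold maximizing F1 against the true
#' pairs, with precision and recall at the optimum. Greedy acceptance is
#' prefix-stable in the score ordering, so the accepted set at threshold t is
#' the set of greedily accepted pairs with score >= t.
#'
#' @param scored_pairs data.frame with `id_a`, `id_b`, `score` (e.g.
#'   `link_set$scored_pairs`).
#' @param truth data.frame of true pairs with columns `id_a`, `id_b`.
#' @return list with `threshold`, `precision`, `recall`, `f1` and the sweep
#'   table, of class `threshold_calibration`.
#' @export
calibrate_threshold <- function(scored_pairs, truth) {
  if (is.null(truth) || nrow(truth) == 0L)
    stop("calibrate_threshold: truth pairs must be nonempty", call. = FALSE)
  scored <- scored_pairs[order(-scored_pairs$score, scored_pairs$id_a,
                               scored_pairs$id_b), , drop = FALSE]
  acc <- greedy_accept(scored, threshold = -Inf)
  truth_key <- paste(truth$id_a, truth$id_b, sep = "\r")
  is_true <- paste(acc$id_a, acc$id_b, sep = "\r") %in% truth_key
  # descending scores: cumulative TP / accepted counts give the sweep
  n_acc <- seq_len(nrow(acc))
  tp <- cumsum(is_true)
  precision <- tp / n_acc
  recall <- tp / nrow(truth)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  # candidate thresholds: each distinct accepted score (take the last index
  # at each score, i.e. the full prefix at that score)
  last_at_score <- !duplicated(acc$score, fromLast = TRUE)
  idx <- which(last_at_score)
  best <- idx[order(-f1[idx], -acc$score[idx])][1L]
  sweep <- data.frame(threshold = acc$score[idx], precision = precision[idx],
                      recall = recall[idx], f1 = f1[idx])
  structure(list(threshold = acc$score[best], precision = precision[best],
                 recall = recall[best], f1 = f1[best], sweep = sweep),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("Calibrated threshold %.4f (precision %.3f, recall %.3f, F1 %.3f)\n",
              x$threshold, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Build a specialty-to-ranking-category map with a frequency filter
#'
#' Retains only specialties occurring strictly more than `min_occurrences`
#' times in the provider population; their (possibly one-to-many) category
#' sets are passed through. Providers whose specialty is filtered out receive
#' no hospital score downstream.
#'
#' @param specialty_counts named integer vector: specialty -> occurrence count.
#' @param raw_entries named list: specialty -> character vector of
#'   ranking-category names.
#' @param min_occurrences strict lower bound on occurrences (default 100).
#' @return object of class `specialty_map`.
#' @export
build_specialty_map <- function(specialty_counts, raw_entries,
                                min_occurrences = 100) {
  if (any(specialty_counts < 0)) config_error("specialty_counts", "must be >= 0")
  keep <- names(specialty_counts)[specialty_counts > min_occurrences]
  entries <- raw_entries[intersect(keep, names(raw_entries))]
  structure(list(entries = entries, min_occurrences = min_occurrences),
            class = "specialty_map")
}

#' @export
print.specialty_map <- function(x, ...) {
  cat(sprintf("Specialty map: %d specialties (min occurrences > %d)\n",
              length(x$entries), x$min_occurrences))
  invisible(x)
}
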