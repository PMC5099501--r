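# The correlation/statistical battery: Pearson correlations with
# significance, paired Wilcoxon signed-rank, Mann-Whitney U versus the union
# of the other plan types, state-wise stratified correlations, and
# condition-to-specialty treatment-score correlations.

#' Pearson correlation with significance
#'
#' Sample Pearson correlation with a two-sided p-value from the t transform
#' on n - 2 degrees of freedom. Pairs with a missing value in either vector
#' are dropped listwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("pearson_cor: vectors must have equal length", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("pearson_cor: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_cor: zero variance in x or y", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences; zero differences are dropped and
#' tied absolute differences are mid-ranked. The exact null distribution is
#' used for up to 25 untied nonzero differences, otherwise the tie-corrected
#' normal approximation.
#'
#' @param x numeric vector of differences, or the first member of the pair.
#' @param y optional second member; differences are `x - y`.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic`, `p_value`, `n` (nonzero differences).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  if (length(d) > 0 && all(d == 0))
    stop("wilcoxon_signed_rank: all differences are zero", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n < 6)
    stop("wilcoxon_signed_rank: need at least 6 nonzero differences", call. = FALSE)
  exact <- n <= exact_max && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of two independent groups; ties are mid-ranked.
#' Exact for small untied samples (product of group sizes <= `exact_max`),
#' otherwise the tie-corrected normal approximation.
#'
#' @param group_a,group_b numeric vectors.
#' @param exact_max largest size product for the exact path.
#' @return list with `statistic` (U for `group_a`), `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 400) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("mann_whitney: both groups must be nonempty", call. = FALSE)
  exact <- length(a) * length(b) <= exact_max && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b))
}

PLAN_TYPE_LABELS <- c("private PPO", "private HMO", "Medicaid",
                      "Medicare PPO", "Medicare HMO")

plan_type_label <- function(category, plan_type) {
  ifelse(category == "Medicaid", "Medicaid", paste(category, plan_type))
}

#' Per-plan-type statistics
#'
#' One row per plan type (private PPO, private HMO, Medicaid, Medicare PPO,
#' Medicare HMO): mean member patient review score, mean consumer
#' satisfaction score, the paired Wilcoxon signed-rank p-value between the
#' two within plans, and Mann-Whitney p-values of each column against the
#' union of the other four types. Types with no plans yield NA rows with a
#' warning.
#'
#' @param agg a [plan_aggregates()] table.
#' @return data.frame of class `plan_type_stats`.
#' @export
plan_type_table <- function(agg) {
  lab <- plan_type_label(agg$category, agg$plan_type)
  out <- data.frame(plan_type = PLAN_TYPE_LABELS, n_plans = 0L,
                    mean_patient_review = NA_real_,
                    mean_consumer_satisfaction = NA_real_,
                    wilcoxon_paired_p = NA_real_,
                    mw_review_vs_rest_p = NA_real_,
                    mw_satisfaction_vs_rest_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(PLAN_TYPE_LABELS)) {
    sel <- lab == PLAN_TYPE_LABELS[i]
    out$n_plans[i] <- sum(sel)
    if (!any(sel)) {
      warning(sprintf("plan_type_table: no plans of type '%s'", PLAN_TYPE_LABELS[i]))
      next
    }
    rating <- agg$mean_rating[sel]
    satis <- agg$OverallConsumerSatisfactionScore[sel]
    out$mean_patient_review[i] <- mean(rating, na.rm = TRUE)
    out$mean_consumer_satisfaction[i] <- mean(satis, na.rm = TRUE)
    d <- rating - satis
    d <- d[!is.na(d)]
    if (length(d[d != 0]) >= 6)
      out$wilcoxon_paired_p[i] <- wilcoxon_signed_rank(d)$p_value
    if (any(!sel)) {
      rest_rating <- agg$mean_rating[!sel]
      rest_satis <- agg$OverallConsumerSatisfactionScore[!sel]
      if (sum(!is.na(rating)) && sum(!is.na(rest_rating)))
        out$mw_review_vs_rest_p[i] <- mann_whitney(rating, rest_rating)$p_value
      if (sum(!is.na(satis)) && sum(!is.na(rest_satis)))
        out$mw_satisfaction_vs_rest_p[i] <- mann_whitney(satis, rest_satis)$p_value
    }
  }
  class(out) <- c("plan_type_stats", "data.frame")
  out
}

correlation_row <- function(x_attribute, y_attribute, stratum, x, y) {
  res <- tryCatch(pearson_cor(x, y), error = function(e) NULL)
  if (is.null(res)) return(NULL)
  data.frame(x_attribute = x_attribute, y_attribute = y_attribute,
             stratum = stratum, n = res$n, r = res$r, p_value = res$p_value,
             stringsAsFactors = FALSE)
}

#' State-wise stratified correlations
#'
#' One pooled ("overall") correlation row plus one row per state having at
#' least `min_plans` complete plan aggregates.
#'
#' @param agg a [plan_aggregates()] table.
#' @param x,y column names to correlate (default: mean member rating vs
#'   consumer satisfaction score).
#' @param min_plans minimal per-state plan count (>= 3).
#' @param bh append a Benjamini-Hochberg adjusted p-value column?
#' @return data.frame of correlation results (x/y attribute, stratum, n, r,
#'   p_value).
#' @export
statewise_correlations <- function(agg, x = "mean_rating",
                                   y = "OverallConsumerSatisfactionScore",
                                   min_plans = 3, bh = FALSE) {
  if (min_plans < 3) config_error("min_plans", "must be >= 3")
  rows <- list(correlation_row(x, y, "overall", agg[[x]], agg[[y]]))
  for (s in sort(unique(agg$state))) {
    sel <- agg$state == s & !is.na(agg[[x]]) & !is.na(agg[[y]])
    if (sum(sel) < min_plans) next
    rows[[length(rows) + 1L]] <-
      correlation_row(x, y, s, agg[[x]][sel], agg[[y]][sel])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (isTRUE(bh)) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Default condition-to-specialty map
#'
#' The six condition groups used for the specialty-restricted treatment-score
#' analysis (women's health, mental and behavioral health, cancer screening,
#' heart disease, children and adolescent health, diabetes), each naming its
#' member specialties and its plan treatment-score column. Shipped as an
#' editable CSV in `inst/extdata/condition_specialties.csv`.
#'
#' @param path optional path to an alternative CSV with columns `condition`,
#'   `score_column`, `specialty`.
#' @return object of class `condition_map`: list of conditions, each with
#'   `specialties` and `score_column`.
#' @export
default_condition_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "condition_specialties.csv",
                        package = "planlink", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  conditions <- unique(df$condition)
  entries <- lapply(conditions, function(cn) {
    sub <- df[df$condition == cn, ]
    list(specialties = unique(sub$specialty),
         score_column = sub$score_column[1L])
  })
  names(entries) <- conditions
  structure(entries, class = "condition_map")
}

#' @export
print.condition_map <- function(x, ...) {
  cat("Condition-to-specialty map:\n")
  for (cn in names(x))
    cat(sprintf("  %s -> %s [%d specialties]\n", cn, x[[cn]]$score_column,
                length(x[[cn]]$specialties)))
  invisible(x)
}

#' Condition-specific treatment-score correlations
#'
#' For each condition in the map, restricts plan members to the condition's
#' specialties, recomputes each plan's mean member rating over that subset,
#' and correlates it with the plan's condition treatment score. Conditions
#' with no matching providers (or fewer than 3 usable plans) are skipped
#' with a warning.
#'
#' @param attrs provider attribute table from [derive_attributes()].
#' @param membership data.frame `plan_id`, `provider_id`.
#' @param plans plan table carrying the treatment-score columns.
#' @param cmap a [default_condition_map()] object.
#' @return data.frame of correlation results, one row per usable condition
#'   (stratum = condition name).
#' @export
condition_correlations <- function(attrs, membership, plans,
                                   cmap = default_condition_map()) {
  bad <- vapply(cmap, function(e) !(e$score_column %in% names(plans)), logical(1))
  if (any(bad))
    stop(sprintf("condition_correlations: score column(s) missing from plans: %s",
                 paste(vapply(cmap[bad], `[[`, "", "score_column"), collapse = ", ")),
         call. = FALSE)
  rows <- list()
  for (cn in names(cmap)) {
    sub_ids <- attrs$provider_id[attrs$specialty %in% cmap[[cn]]$specialties &
                                   !is.na(attrs$user_rating)]
    if (length(sub_ids) == 0L) {
      warning(sprintf("condition_correlations: no rated providers for '%s'; skipped", cn))
      next
    }
    mem <- membership[membership$provider_id %in% sub_ids, , drop = FALSE]
    if (nrow(mem) == 0L) {
      warning(sprintf("condition_correlations: no plan members for '%s'; skipped", cn))
      next
    }
    rt <- attrs$user_rating[match(mem$provider_id, attrs$provider_id)]
    means <- rowsum(rt, mem$plan_id) / as.integer(table(mem$plan_id))
    y <- plans[[cmap[[cn]]$score_column]][match(rownames(means), plans$plan_id)]
    row <- correlation_row("mean_specialty_rating", cmap[[cn]]$score_column,
                           cn, as.numeric(means), y)
    if (is.null(row))
      warning(sprintf("condition_correlations: too few usable plans for '%s'; skipped", cn))
    else rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(x_attribute = character(0), y_attribute = character(0),
                      stratum = character(0), n = integer(0), r = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Overall attribute correlations
#'
#' Pearson correlation of each plan-level aggregated provider attribute with
#' a plan quality score (default: the consumer satisfaction score), pooled
#' over all plans.
#'
#' @param agg a [plan_aggregates()] table.
#' @param x_attributes aggregate columns to correlate.
#' @param y plan score column.
#' @param bh append a Benjamini-Hochberg adjusted p-value column?
#' @return data.frame of correlation results.
#' @export
attribute_correlations <- function(agg,
                                   x_attributes = c("mean_rating",
                                                    "mean_referrals",
                                                    "cc_ratio",
                                                    "mean_hospital_rank",
                                                    "mean_relative_cost"),
                                   y = "OverallConsumerSatisfactionScore",
                                   bh = FALSE) {
  rows <- lapply(x_attributes, function(xa)
    correlation_row(xa, y, "overall", agg[[xa]], agg[[y]]))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (isTRUE(bh) && !is.null(out))
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
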