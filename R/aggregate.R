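# Plan-level aggregation: membership resolution through the insurance-name
# mapping, per-plan means of member-provider attributes joined to plan
# quality scores, and per-state summary tables.

PLAN_SCORE_COLUMNS <- c(
  "OverallScore", "OverallConsumerSatisfactionScore", "GettingCareScore",
  "SatisfactionWithPhysiciansScore", "SatisfactionWithHealthPlanServicesScore",
  "OverallPreventionScore", "ChildrenAndAdolescentsScore",
  "WomensReproductiveHealthScore", "CancerScreeningScore",
  "OtherPreventiveServicesScore", "OverallTreatmentScore",
  "AsthmaTreatmentScore", "DiabetesTreatmentScore",
  "HeartDiseaseTreatmentScore", "MentalAndBehavioralHealthScore",
  "OtherTreatmentMeasuresScore")

# Score columns whose completeness gates a plan's entry into correlations.
CORE_SCORE_COLUMNS <- c("OverallScore", "OverallConsumerSatisfactionScore",
                        "OverallPreventionScore", "OverallTreatmentScore")

#' Resolve plan membership from accepted-insurance strings
#'
#' A provider belongs to every plan that one of its accepted-insurance name
#' strings maps to under the insurance-name mapping; providers with no
#' mapped string belong to no plan.
#'
#' @param plans plan table with `plan_id`, `plan_name`.
#' @param provider_insurances data.frame `provider_id`, `insurance_name`
#'   (one row per accepted-insurance string).
#' @param insurance_map mapping as returned by [match_insurance_names()]
#'   (`name_a` = accepted string, `name_b` = plan name).
#' @return data.frame `plan_id`, `provider_id`, one row per membership.
#' @export
plan_membership <- function(plans, provider_insurances, insurance_map) {
  mapped <- insurance_map$name_b[match(provider_insurances$insurance_name,
                                       insurance_map$name_a)]
  plan_id <- plans$plan_id[match(mapped, plans$plan_name)]
  out <- data.frame(plan_id = plan_id,
                    provider_id = provider_insurances$provider_id,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$plan_id), , drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate member-provider attributes per plan
#'
#' Computes, for each plan, arithmetic means of its member providers'
#' attributes: mean rating (over rated members only), mean referral count,
#' ratio of Castle Connolly award holders, mean hospital score and imputed
#' hospital rank (over members with values), and mean relative cost (over
#' members with costs). Plans with fewer than `min_members` members, and
#' plans with incomplete core quality scores, are excluded from the result
#' (counts of both exclusions are attached as attributes).
#'
#' @param plans plan table with `plan_id`, `plan_name`, `state`, `category`,
#'   `plan_type` and the quality-score columns.
#' @param membership data.frame `plan_id`, `provider_id` from
#'   [plan_membership()].
#' @param attrs provider attribute table from [derive_attributes()].
#' @param min_members minimal member count for inclusion (default 5).
#' @return data.frame of class `plan_aggregates`.
#' @export
plan_aggregates <- function(plans, membership, attrs, min_members = 5) {
  means <- plan_attribute_means(membership, attrs)
  ids <- means$plan_id
  out <- plans[match(ids, plans$plan_id),
               c("plan_id", "plan_name", "state", "category", "plan_type"),
               drop = FALSE]
  out <- cbind(out, means[setdiff(names(means), "plan_id")])
  score_cols <- intersect(PLAN_SCORE_COLUMNS, names(plans))
  out[score_cols] <- plans[match(ids, plans$plan_id), score_cols]

  core <- intersect(CORE_SCORE_COLUMNS, names(out))
  complete <- stats::complete.cases(out[core])
  small <- out$n_members < min_members
  n_incomplete <- sum(!complete)
  n_small <- sum(small & complete)
  if (n_incomplete + n_small > 0)
    message(sprintf("plan_aggregates: excluded %d plans with incomplete scores and %d with < %d members",
                    n_incomplete, n_small, min_members))
  out <- out[complete & !small, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_incomplete") <- n_incomplete
  attr(out, "n_excluded_small") <- n_small
  class(out) <- c("plan_aggregates", "data.frame")
  out
}

# Per-plan arithmetic means of member attributes: ratings over rated
# members only, hospital score/rank and relative cost over members with
# values, referral counts and award ratio over all members. Shared by the
# pipeline and by the generator when planting plan scores, so both sides
# agree on the aggregation rule by construction.
plan_attribute_means <- function(membership, attrs) {
  mem <- membership[membership$provider_id %in% attrs$provider_id, , drop = FALSE]
  a <- attrs[match(mem$provider_id, attrs$provider_id), , drop = FALSE]
  mean_by <- function(x, keep = !is.na(x)) {
    s <- rowsum(ifelse(keep, x, 0), mem$plan_id)
    n <- rowsum(as.numeric(keep), mem$plan_id)
    v <- ifelse(n > 0, s / n, NA_real_)
    setNames(as.numeric(v), rownames(s))
  }
  n_members <- table(mem$plan_id)
  ids <- names(n_members)
  data.frame(plan_id = ids,
             n_members = as.integer(n_members),
             mean_rating = mean_by(a$user_rating)[ids],
             mean_referrals = mean_by(a$num_referrals)[ids],
             cc_ratio = mean_by(as.numeric(a$castle_connolly))[ids],
             mean_hospital_score = mean_by(a$hospital_score)[ids],
             mean_hospital_rank = mean_by(a$hospital_rank)[ids],
             mean_relative_cost = mean_by(a$relative_cost)[ids],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-state summary table
#'
#' The data behind the state heat maps: mean consumer-satisfaction score of
#' the plans in each state, providers per 1000 population, and the number of
#' plans with complete core scores.
#'
#' @param plans plan table (see [plan_aggregates()]).
#' @param providers provider directory with a `state` column.
#' @param populations data.frame `state`, `population`.
#' @return data.frame with one row per state present in either table.
#' @export
state_summaries <- function(plans, providers, populations) {
  if (any(populations$population <= 0))
    stop("state_summaries: populations must be positive", call. = FALSE)
  states <- sort(unique(c(plans$state, providers$state)))
  missing_pop <- setdiff(unique(providers$state), populations$state)
  if (length(missing_pop))
    stop(sprintf("state_summaries: no population for state(s) %s",
                 paste(missing_pop, collapse = ", ")), call. = FALSE)
  core <- intersect(CORE_SCORE_COLUMNS, names(plans))
  complete <- stats::complete.cases(plans[core])
  out <- data.frame(state = states, stringsAsFactors = FALSE)
  out$mean_consumer_satisfaction <- vapply(states, function(s) {
    v <- plans$OverallConsumerSatisfactionScore[plans$state == s]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  pop <- populations$population[match(states, populations$state)]
  out$providers_per_1000 <- vapply(states, function(s)
    sum(providers$state == s), numeric(1)) * 1000 / pop
  out$n_plans_evaluated <- vapply(states, function(s)
    sum(plans$state == s & complete), numeric(1))
  rownames(out) <- NULL
  out
}
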