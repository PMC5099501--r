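# Small hand-built tables used by the aggregation and stats tests.

make_plan_table <- function(n = 4, state = "CA") {
  out <- data.frame(
    plan_id = sprintf("PL%02d", seq_len(n)),
    plan_name = paste0("Carrier ", seq_len(n), " Health HMO, ", state),
    state = state, category = "private", plan_type = "HMO",
    stringsAsFactors = FALSE)
  for (col in planlink:::PLAN_SCORE_COLUMNS) out[[col]] <- 75
  out
}

make_attrs <- function(ids, rating = 80, referrals = 5, cc = FALSE) {
  data.frame(provider_id = ids, state = "CA", specialty = "Internal Medicine",
             user_rating = rating, n_reviews = ifelse(is.na(rating), 0, 3),
             castle_connolly = cc, num_referrals = referrals,
             hospital_score = 70, hospital_rank = 100, relative_cost = 50,
             stringsAsFactors = FALSE)
}
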