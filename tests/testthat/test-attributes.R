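test_that("average_rating weights sources by review count", {
  expect_equal(average_rating(87.5, 4), 87.5)
  expect_equal(average_rating(c(80, 90), c(2, 2)), 85)
  expect_equal(average_rating(c(80, 90), c(3, 1)), 82.5)
  expect_true(is.na(average_rating(numeric(0), numeric(0))))
  expect_true(is.na(average_rating(c(80), c(0))))
  expect_error(average_rating(101, 3), "\\[0, 100\\]")
})

test_that("hospital scores average mapped categories and take the max affiliation", {
  smap <- build_specialty_map(
    c("Internal Medicine" = 500, "Dermatology" = 500),
    list("Internal Medicine" = c("Primary Care", "Diabetes & Endocrinology")),
    min_occurrences = 100)

  expect_equal(hospital_category_score(c("Primary Care" = 70),
                                       "Internal Medicine", smap), 70)
  expect_equal(hospital_category_score(
    c("Primary Care" = 70, "Diabetes & Endocrinology" = 90),
    "Internal Medicine", smap), 80)
  expect_true(is.na(hospital_category_score(c("Primary Care" = 70),
                                            "Dermatology", smap)))
  expect_true(is.na(hospital_category_score(c("Cancer" = 70),
                                            "Internal Medicine", smap)))

  aff <- list(c("Primary Care" = 80), c("Primary Care" = 60))
  expect_equal(provider_hospital_score(aff, "Internal Medicine", smap), 80)
  expect_equal(provider_hospital_score(list(c("Primary Care" = 55)),
                                       "Internal Medicine", smap), 55)
  expect_true(is.na(provider_hospital_score(list(c("Cancer" = 55)),
                                            "Internal Medicine", smap)))
  # monotone: adding an affiliation never decreases the score
  expect_gte(provider_hospital_score(c(aff, list(c("Primary Care" = 95))),
                                     "Internal Medicine", smap),
             provider_hospital_score(aff, "Internal Medicine", smap))
})

test_that("unranked hospitals receive the bottom-median rank", {
  h <- data.frame(hospital_id = seq_len(1956),
                  rank = c(1:50, rep(NA, 1906)))
  out <- impute_hospital_ranks(h)
  expect_equal(unique(out$rank_imputed[is.na(h$rank)]), 1004)
  expect_equal(out$rank_imputed[1:50], 1:50)

  all_ranked <- data.frame(hospital_id = 1:5, rank = 1:5)
  expect_equal(impute_hospital_ranks(all_ranked)$rank_imputed, 1:5)

  tiny <- data.frame(hospital_id = 1:3, rank = c(1, NA, NA))
  expect_equal(impute_hospital_ranks(tiny)$rank_imputed, c(1, 3, 3))

  dup <- data.frame(hospital_id = 1:3, rank = c(1, 1, NA))
  expect_error(impute_hospital_ranks(dup), "duplicate")
})

test_that("haversine distance matches the spherical-trig oracle", {
  expect_equal(haversine_miles(37, -122, 37, -122), 0)
  d_eq <- haversine_miles(0, 0, 0, 1)
  expect_lt(abs(d_eq - slc_miles(0, 0, 0, 1)) / d_eq, 1e-6)
  set.seed(8)
  for (i in 1:20) {
    p <- c(runif(1, -80, 80), runif(1, -170, 170))
    q <- c(runif(1, -80, 80), runif(1, -170, 170))
    expect_equal(haversine_miles(p[1], p[2], q[1], q[2]),
                 haversine_miles(q[1], q[2], p[1], p[2]))
  }
  expect_error(haversine_miles(91, 0, 0, 0), "latitude")
  expect_error(haversine_miles(0, 181, 0, 0), "longitude")
})

test_that("relative cost follows the min-max and procedure-weighting rules", {
  providers <- data.frame(
    provider_id = c("P1", "P2", "P3"),
    lat = c(40, 40.01, 40.02), lon = c(-100, -100, -100),
    specialty = "Internal Medicine", stringsAsFactors = FALSE)
  charges <- data.frame(
    provider_id = c("P1", "P2", "P3", "P1", "P2"),
    hcpcs_code = c("A", "A", "A", "B", "B"),
    avg_charged = c(300, 200, 100, 50, 80),
    n_procedures = c(3, 5, 5, 1, 2), stringsAsFactors = FALSE)

  rc <- relative_costs(charges, providers)
  # P1: code A -> strictly most expensive (100); code B -> cheapest (0);
  # weights 3 and 1 -> 75
  expect_equal(rc$relative_cost[rc$provider_id == "P1"], 75)
  # P3 bills only code A and is cheapest there
  expect_equal(rc$relative_cost[rc$provider_id == "P3"], 0)

  # a provider alone in its neighborhood scores 100 (max = min convention)
  solo <- relative_costs(
    data.frame(provider_id = "P9", hcpcs_code = "Z", avg_charged = 10,
               n_procedures = 2),
    data.frame(provider_id = "P9", lat = 10, lon = 10,
               specialty = "Dermatology"))
  expect_equal(solo$relative_cost, 100)

  # missing geolocation -> NA with a warning; no charges -> not in output
  pg <- rbind(providers,
              data.frame(provider_id = "P4", lat = NA, lon = NA,
                         specialty = "Internal Medicine"))
  ch4 <- rbind(charges,
               data.frame(provider_id = "P4", hcpcs_code = "A",
                          avg_charged = 150, n_procedures = 1))
  expect_warning(rc4 <- relative_costs(ch4, pg), "geolocation")
  expect_true(is.na(rc4$relative_cost[rc4$provider_id == "P4"]))
  expect_error(relative_costs(
    data.frame(provider_id = "P1", hcpcs_code = "A", avg_charged = -1,
               n_procedures = 1), providers), "avg_charged")
})

test_that("relative cost matches the brute-force oracle and is affine-invariant", {
  set.seed(17)
  n <- 60
  providers <- data.frame(
    provider_id = sprintf("P%03d", 1:n),
    lat = runif(n, 40, 40.6), lon = runif(n, -100.6, -100),
    specialty = sample(c("Internal Medicine", "Cardiologist"), n, TRUE),
    stringsAsFactors = FALSE)
  nch <- sample(1:3, n, TRUE)
  idx <- rep(1:n, nch)
  charges <- data.frame(
    provider_id = providers$provider_id[idx],
    hcpcs_code = sample(c("A", "B", "C", "D"), length(idx), TRUE),
    avg_charged = exp(rnorm(length(idx), 5, 0.5)),
    n_procedures = 1 + rpois(length(idx), 5), stringsAsFactors = FALSE)

  for (k in c(5, 1000)) {
    got <- relative_costs(charges, providers, k = k, radius_miles = 30)
    want <- relative_cost_oracle(charges, providers, k = k, radius = 30)
    expect_equal(setNames(got$relative_cost, got$provider_id),
                 want[got$provider_id], tolerance = 1e-12)
  }

  # positive affine rescaling of all charges leaves the scores unchanged
  ch2 <- charges; ch2$avg_charged <- 3.5 * ch2$avg_charged + 11
  expect_equal(relative_costs(ch2, providers)$relative_cost,
               relative_costs(charges, providers)$relative_cost,
               tolerance = 1e-9)

  # with unlimited radius and k >= n the neighborhood is the whole
  # same-specialty code group: check one provider directly
  got <- relative_costs(charges, providers, k = 1000, radius_miles = 1e6)
  key <- paste(charges$provider_id, charges$hcpcs_code)
  agg <- tapply(charges$avg_charged * charges$n_procedures, key, sum) /
    tapply(charges$n_procedures, key, sum)
  p <- "P001"
  pc <- charges[charges$provider_id == p, ]
  sp <- providers$specialty[providers$provider_id == p]
  rels <- vapply(unique(pc$hcpcs_code), function(code) {
    grp <- providers$provider_id[providers$specialty == sp]
    peers <- intersect(grp, charges$provider_id[charges$hcpcs_code == code])
    vals <- agg[paste(peers, code)]
    mine <- agg[paste(p, code)]
    if (max(vals) == min(vals)) 100 else
      100 * (mine - min(vals)) / (max(vals) - min(vals))
  }, numeric(1))
  wts <- tapply(pc$n_procedures, pc$hcpcs_code, sum)[unique(pc$hcpcs_code)]
  expect_equal(got$relative_cost[got$provider_id == p],
               sum(rels * wts) / sum(wts), tolerance = 1e-12)
})

test_that("derive_attributes joins the linked sources per provider", {
  # empty links -> empty table
  w <- suppressWarnings(generate_world(
    world_config(n_providers = 150, n_plans = 20, n_hospitals = 20, seed = 13)))
  smap <- build_specialty_map(table(w$cms_providers$specialty),
                              default_specialty_category_entries(),
                              min_occurrences = 0)
  empty <- derive_attributes(w$truth_links[0, ], w$cms_providers, w$reviews,
                             w$site_providers, w$referrals, w$charges,
                             w$hospitals, w$hospital_scores, smap)
  expect_equal(nrow(empty), 0)

  attrs <- suppressWarnings(derive_attributes(
    w$truth_links, w$cms_providers, w$reviews, w$site_providers,
    w$referrals, w$charges, w$hospitals, w$hospital_scores, smap))
  expect_equal(nrow(attrs), nrow(w$truth_links))
  # with the frequency filter disabled, every mapped specialty with a scored
  # affiliation gets a hospital score
  mapped <- attrs$specialty %in% names(smap$entries)
  cats_of <- default_specialty_category_entries()
  has_score <- vapply(seq_len(nrow(attrs)), function(i) {
    if (!mapped[i]) return(NA)
    hs <- strsplit(w$cms_providers$affiliated_hospitals[
      match(attrs$provider_id[i], w$cms_providers$provider_id)], ";")[[1]]
    any(w$hospital_scores$hospital_id %in% hs &
          w$hospital_scores$category %in% cats_of[[attrs$specialty[i]]])
  }, logical(1))
  expect_true(all(!is.na(attrs$hospital_score[which(mapped & has_score)])))
  # rating is absent exactly when no linked review exists
  expect_true(all(is.na(attrs$user_rating) == (attrs$n_reviews == 0)))
})

test_that("derived ratings track the configured rating distribution", {
  attrs <- big_world()$truth_attributes
  expect_lt(abs(mean(attrs$user_rating, na.rm = TRUE) - 82), 2)
})
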