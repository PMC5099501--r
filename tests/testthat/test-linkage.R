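test_that("levenshtein matches the DP oracle and the printed examples", {
  expect_identical(levenshtein("abc", "abc"), 0L)
  expect_identical(levenshtein("", "abc"), 3L)
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  expect_identical(
    levenshtein("United Healthcare Services, CA", "United Healthcare, CA"),
    lev_oracle("United Healthcare Services, CA", "United Healthcare, CA"))
  set.seed(11)
  for (i in 1:60) {
    a <- random_string(sample(0:30, 1)); b <- random_string(sample(0:30, 1))
    expect_identical(levenshtein(a, b), lev_oracle(a, b))
  }
})

test_that("levenshtein is symmetric and satisfies the triangle inequality", {
  set.seed(12)
  for (i in 1:50) {
    a <- random_string(sample(0:15, 1)); b <- random_string(sample(0:15, 1))
    cc <- random_string(sample(0:15, 1))
    expect_identical(levenshtein(a, b), levenshtein(b, a))
    expect_lte(levenshtein(a, cc), levenshtein(a, b) + levenshtein(b, cc))
  }
})

test_that("name_similarity normalizes by the longer string", {
  expect_equal(name_similarity("smith", "smith"), 1.0)
  expect_equal(name_similarity("abcd", "wxyz"), 0.0)
  expect_equal(name_similarity("kitten", "sitting"),
               1 - lev_oracle("kitten", "sitting") / 7)
  expect_equal(name_similarity("", ""), 1.0)
  expect_equal(name_similarity("  Smith ", "smith"), 1.0)  # canonicalization
})

test_that("insurance-name matching compares state codes exactly", {
  m <- match_insurance_names("Aetna Life Insurance, AR",
                             c("Aetna HMO, AR", "Aetna HMO, CA"),
                             min_similarity = 0.3)
  expect_equal(m$name_b, "Aetna HMO, AR")

  nm <- c("Blue Cross, NY", "Humana Gold, TX")
  ident <- match_insurance_names(nm, nm)
  expect_equal(ident$name_a, ident$name_b)

  dis <- match_insurance_names(c("Alpha Plan, CA"), c("Omega Plan, CA"),
                               min_similarity = 1.0)
  expect_equal(nrow(dis), 0L)
  expect_equal(attr(dis, "unmapped"), "Alpha Plan, CA")
})

test_that("attribute scores handle identity, disagreement and missingness", {
  rec <- as.list(toy_directory(1)[1, ])
  s <- attribute_scores(rec, rec)
  expect_true(all(s == 1))

  rec2 <- rec; rec2$graduation_year <- rec$graduation_year + 1
  s2 <- attribute_scores(rec, rec2)
  expect_equal(unname(s2["graduation_year"]), 0)
  expect_true(all(s2[setdiff(names(s2), "graduation_year")] == 1))

  rec3 <- rec; rec3$affiliated_hospitals <- "H2;H3"
  expect_equal(unname(attribute_scores(rec, rec3)["affiliated_hospitals"]), 1 / 3)

  rec4 <- rec; rec4$medical_school <- NA
  expect_true(is.na(attribute_scores(rec, rec4)["medical_school"]))
})

test_that("combined_score renormalizes weights over non-missing scores", {
  expect_equal(combined_score(c(a = 1, b = 1), c(a = 0.3, b = 0.7)), 1)
  expect_equal(combined_score(c(a = 1, b = 0), c(a = 0.5, b = 0.5)), 0.5)
  expect_equal(combined_score(c(a = 0.8, b = NA, c = 0.6),
                              c(a = 0.25, b = 0.5, c = 0.25)), 0.7)
  expect_error(combined_score(c(a = NA, b = NA), c(a = 0.5, b = 0.5)),
               "missing")
})

test_that("linking a directory to an exact copy recovers the identity", {
  dir_a <- toy_directory()
  dir_b <- dir_a
  dir_b$provider_id <- sub("A", "B", dir_a$provider_id)
  ls <- link_directories(dir_a, dir_b, threshold = 1)
  expect_equal(nrow(ls$accepted), nrow(dir_a))
  expect_equal(sub("B", "A", ls$accepted$id_b), ls$accepted$id_a)
})

test_that("accepted links are invariant to input row order", {
  set.seed(21)
  cfg <- world_config(n_providers = 150, n_plans = 20, n_hospitals = 20,
                      seed = 5)
  w <- suppressWarnings(generate_world(cfg))
  ls1 <- link_directories(w$cms_providers, w$site_providers, threshold = 0.6)
  perm_a <- sample(nrow(w$cms_providers)); perm_b <- sample(nrow(w$site_providers))
  ls2 <- link_directories(w$cms_providers[perm_a, ],
                          w$site_providers[perm_b, ], threshold = 0.6)
  o1 <- ls1$accepted[order(ls1$accepted$id_b), ]
  o2 <- ls2$accepted[order(ls2$accepted$id_b), ]
  expect_equal(o1$id_a, o2$id_a)
  expect_equal(o1$score, o2$score)
})

test_that("raising the threshold never increases the accepted-pair count", {
  cfg <- world_config(n_providers = 150, n_plans = 20, n_hospitals = 20,
                      seed = 6)
  w <- suppressWarnings(generate_world(cfg))
  counts <- vapply(seq(0, 1, by = 0.1), function(t)
    nrow(link_directories(w$cms_providers, w$site_providers,
                          threshold = t)$accepted), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("blocking by last-name initial and state loses no true pair at zero noise", {
  cfg <- world_config(n_providers = 200, n_plans = 20, n_hospitals = 20,
                      name_noise = noise_config(max_edits = 0, dropout = 0,
                                                distractor_rate = 0.1),
                      seed = 7)
  w <- suppressWarnings(generate_world(cfg))
  ls <- link_directories(w$cms_providers, w$site_providers, threshold = 0)
  scored_keys <- paste(ls$scored_pairs$id_a, ls$scored_pairs$id_b)
  truth_keys <- paste(w$truth_links$id_a, w$truth_links$id_b)
  expect_true(all(truth_keys %in% scored_keys))
  # and with any nonzero noise, threshold 1 admits only unperturbed clones
  acc <- link_directories(w$cms_providers, w$site_providers,
                          threshold = 1)$accepted
  expect_true(all(paste(acc$id_a, acc$id_b) %in% truth_keys))
})

test_that("calibrate_threshold maximizes F1, matching a brute-force sweep", {
  # perfectly separated score distributions
  sp <- data.frame(id_a = sprintf("a%02d", 1:20), id_b = sprintf("b%02d", 1:20),
                   score = c(rep(0.9, 10), rep(0.2, 10)))
  truth <- sp[1:10, c("id_a", "id_b")]
  cal <- calibrate_threshold(sp, truth)
  expect_equal(cal$f1, 1)
  expect_equal(cal$precision, 1)
  expect_equal(cal$recall, 1)
  expect_gt(cal$threshold, 0.2)

  # overlapping scores: compare against an exhaustive re-greedy sweep
  set.seed(31)
  n <- 60
  true_scores <- pmin(1, pmax(0, rnorm(n, 0.75, 0.12)))
  false_scores <- pmin(1, pmax(0, rnorm(n, 0.55, 0.12)))
  sp <- data.frame(
    id_a = c(sprintf("a%03d", 1:n), sprintf("a%03d", sample(1:n))),
    id_b = c(sprintf("b%03d", 1:n), sprintf("x%03d", 1:n)),
    score = c(true_scores, false_scores))
  truth <- data.frame(id_a = sprintf("a%03d", 1:n), id_b = sprintf("b%03d", 1:n))
  cal <- calibrate_threshold(sp, truth)
  f1_at <- function(t) {
    ord <- sp[order(-sp$score, sp$id_a, sp$id_b), ]
    ord <- ord[ord$score >= t, ]
    acc <- ord[!duplicated(ord$id_b), ]
    tp <- sum(paste(acc$id_a, acc$id_b) %in% paste(truth$id_a, truth$id_b))
    prec <- if (nrow(acc)) tp / nrow(acc) else 0
    rec <- tp / nrow(truth)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  best_oracle <- max(vapply(unique(sp$score), f1_at, numeric(1)))
  expect_equal(cal$f1, best_oracle)
  expect_equal(f1_at(cal$threshold), best_oracle)
  expect_error(calibrate_threshold(sp, truth[0, ]), "nonempty")
})

test_that("specialty map applies the strictly-more-than-100 filter", {
  counts <- c("Internal Medicine" = 101, "Family Medicine" = 100,
              "Rare Specialty" = 3)
  entries <- list("Internal Medicine" = c("Primary Care"),
                  "Family Medicine" = c("Primary Care"),
                  "Rare Specialty" = c("Cancer"))
  smap <- build_specialty_map(counts, entries)
  expect_true("Internal Medicine" %in% names(smap$entries))
  expect_false("Family Medicine" %in% names(smap$entries))
  expect_false("Rare Specialty" %in% names(smap$entries))
  empty <- build_specialty_map(counts, list())
  expect_length(empty$entries, 0)
})
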