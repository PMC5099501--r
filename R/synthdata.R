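# Synthetic-data generator: emulates the five crawled source families
# (provider directory, review-site profiles, hospital rankings, procedure
# charges + referrals, plan quality table) with ground-truth cross-source
# links and configurable planted statistical structure, so every downstream
# stage is testable without any download.

FIRST_NAMES <- c(
  "james", "mary", "robert", "patricia", "john", "jennifer", "michael",
  "linda", "david", "elizabeth", "william", "barbara", "richard", "susan",
  "joseph", "jessica", "thomas", "sarah", "charles", "karen", "christopher",
  "lisa", "daniel", "nancy", "matthew", "betty", "anthony", "margaret",
  "mark", "sandra", "donald", "ashley", "steven", "kimberly", "paul",
  "emily", "andrew", "donna", "joshua", "michelle", "kenneth", "carol",
  "kevin", "amanda", "brian", "dorothy", "george", "melissa", "edward",
  "deborah", "ronald", "stephanie", "timothy", "rebecca", "jason", "sharon",
  "jeffrey", "laura", "ryan", "cynthia", "jacob", "kathleen", "gary", "amy",
  "nicholas", "angela", "eric", "shirley", "jonathan", "anna", "stephen",
  "brenda", "larry", "pamela", "justin", "emma", "scott", "nicole",
  "brandon", "helen", "benjamin", "samantha", "samuel", "katherine",
  "gregory", "christine", "alexander", "debra", "patrick", "rachel",
  "frank", "carolyn", "raymond", "janet", "jack", "catherine", "dennis",
  "maria", "jerry", "heather")

LAST_NAMES <- c(
  "smith", "johnson", "williams", "brown", "jones", "garcia", "miller",
  "davis", "rodriguez", "martinez", "hernandez", "lopez", "gonzalez",
  "wilson", "anderson", "thomas", "taylor", "moore", "jackson", "martin",
  "lee", "perez", "thompson", "white", "harris", "sanchez", "clark",
  "ramirez", "lewis", "robinson", "walker", "young", "allen", "king",
  "wright", "scott", "torres", "nguyen", "hill", "flores", "green",
  "adams", "nelson", "baker", "hall", "rivera", "campbell", "mitchell",
  "carter", "roberts", "gomez", "phillips", "evans", "turner", "diaz",
  "parker", "cruz", "edwards", "collins", "reyes", "stewart", "morris",
  "morales", "murphy", "cook", "rogers", "gutierrez", "ortiz", "morgan",
  "cooper", "peterson", "bailey", "reed", "kelly", "howard", "ramos",
  "kim", "cox", "ward", "richardson", "watson", "brooks", "chavez",
  "wood", "james", "bennett", "gray", "mendoza", "ruiz", "hughes",
  "price", "alvarez", "castillo", "sanders", "patel", "myers", "long",
  "ross", "foster", "jimenez", "powell", "jenkins", "perry", "russell",
  "sullivan", "bell", "coleman", "butler", "henderson", "barnes", "fisher",
  "vasquez", "simmons", "romero", "jordan", "patterson", "alexander",
  "hamilton", "graham", "reynolds", "griffin", "wallace", "moreno", "west",
  "cole", "hayes", "bryant", "herrera", "gibson", "ellis", "tran")

MEDICAL_SCHOOLS <- paste(
  c("harvard", "stanford", "johns hopkins", "duke", "columbia", "yale",
    "michigan", "ucla", "ucsf", "penn", "cornell", "emory", "baylor",
    "vanderbilt", "mayo", "northwestern", "georgetown", "tufts", "brown",
    "dartmouth", "nyu", "pittsburgh", "rochester", "virginia", "wisconsin",
    "minnesota", "iowa", "utah", "colorado", "oregon", "washington",
    "arizona", "florida", "ohio state", "indiana", "tulane", "miami",
    "temple", "boston", "georgia"),
  "medical school")

STREET_NAMES <- c("main", "oak", "maple", "cedar", "elm", "washington",
                  "lake", "hill", "park", "pine", "walnut", "sunset",
                  "river", "church", "spring", "center", "high", "mill",
                  "franklin", "union")

CARRIERS <- c("Aetna", "United Healthcare", "Cigna", "Humana", "Kaiser",
              "Anthem", "Wellpoint", "Centene", "Molina", "Highmark",
              "Amerigroup", "Oscar", "Tricare", "Premera", "Regence",
              "CareFirst", "Emblem", "Geisinger", "HealthNet", "Oxford",
              "Harvard Pilgrim", "Tufts Health", "Ambetter", "Bright Health")

RANKING_CATEGORIES <- c(
  "Cardiology & Heart Surgery", "Cancer", "Diabetes & Endocrinology",
  "Gynecology", "Psychiatry", "Pediatrics", "Gastroenterology & GI Surgery",
  "Orthopedics", "Neurology & Neurosurgery", "Urology", "Ophthalmology",
  "Primary Care")

#' Default specialty frequency table
#'
#' Target relative frequencies for the synthetic provider population:
#' primary-care specialties dominate, and every specialty of the six
#' condition groups in [default_condition_map()] is present.
#'
#' @return named numeric vector summing to 1.
#' @export
default_specialty_frequencies <- function() {
  f <- c(
    "Internal Medicine" = 0.17, "Family Medicine" = 0.14,
    "Emergency Medicine" = 0.07, "Orthopedic Surgery" = 0.05,
    "Dermatology" = 0.04, "Neurology" = 0.04, "Gastroenterology" = 0.04,
    "Urology" = 0.03, "Ophthalmology" = 0.04, "Anesthesiology" = 0.05,
    "Obstetrics and Gynecology" = 0.05, "Gynecology Oncology" = 0.005,
    "Counselor" = 0.02, "Psychoanalyst" = 0.003,
    "Clinical Neuropsychologist" = 0.004, "Psychologist" = 0.03,
    "Psychoanalysis" = 0.003, "Marriage and Family Therapist" = 0.01,
    "Pediatric Oncology" = 0.004, "Oncology" = 0.015,
    "Hematology & Oncology" = 0.012, "Radiation Oncology" = 0.008,
    "Cardiologist" = 0.03, "Cardiac Rehabilitation" = 0.004,
    "Cardiology Technician" = 0.003, "Cardiovascular Diseases" = 0.015,
    "Pediatrics" = 0.06, "Neonatal Pediatrics" = 0.006,
    "Pediatrics Critical Care" = 0.005, "Diabetes Educator" = 0.01,
    "Endocrinology" = 0.02, "Diabetes and Metabolism" = 0.012)
  f / sum(f)
}

#' Default raw specialty-to-ranking-category entries
#'
#' The stand-in for the manually curated mapping between the directory's
#' specialty taxonomy and the broad hospital ranking categories; may be
#' one-to-many, and deliberately leaves a few specialties unmapped so the
#' null-hospital-score path is exercised.
#'
#' @return named list: specialty -> character vector of category names.
#' @export
default_specialty_category_entries <- function() {
  list(
    "Internal Medicine" = c("Primary Care", "Gastroenterology & GI Surgery",
                            "Diabetes & Endocrinology"),
    "Family Medicine" = "Primary Care",
    "Emergency Medicine" = "Primary Care",
    "Orthopedic Surgery" = "Orthopedics",
    "Neurology" = "Neurology & Neurosurgery",
    "Gastroenterology" = "Gastroenterology & GI Surgery",
    "Urology" = "Urology",
    "Ophthalmology" = "Ophthalmology",
    "Obstetrics and Gynecology" = "Gynecology",
    "Gynecology Oncology" = c("Gynecology", "Cancer"),
    "Counselor" = "Psychiatry", "Psychoanalyst" = "Psychiatry",
    "Clinical Neuropsychologist" = "Psychiatry", "Psychologist" = "Psychiatry",
    "Psychoanalysis" = "Psychiatry",
    "Marriage and Family Therapist" = "Psychiatry",
    "Pediatric Oncology" = c("Cancer", "Pediatrics"),
    "Oncology" = "Cancer", "Hematology & Oncology" = "Cancer",
    "Radiation Oncology" = "Cancer",
    "Cardiologist" = "Cardiology & Heart Surgery",
    "Cardiac Rehabilitation" = "Cardiology & Heart Surgery",
    "Cardiology Technician" = "Cardiology & Heart Surgery",
    "Cardiovascular Diseases" = "Cardiology & Heart Surgery",
    "Pediatrics" = "Pediatrics", "Neonatal Pediatrics" = "Pediatrics",
    "Pediatrics Critical Care" = "Pediatrics",
    "Diabetes Educator" = "Diabetes & Endocrinology",
    "Endocrinology" = "Diabetes & Endocrinology",
    "Diabetes and Metabolism" = "Diabetes & Endocrinology")
}

#' Name-perturbation parameters
#'
#' @param max_edits maximal number of single-character edits applied to each
#'   name-like field of a cloned profile (the actual count is uniform on
#'   0..max_edits). Edits never touch a field's first character, emulating
#'   directory typos, which overwhelmingly preserve initials.
#' @param dropout probability that a droppable field (middle name, address,
#'   medical school, graduation year) is absent from the clone.
#' @param distractor_rate fraction (of the directory size) of extra site
#'   profiles with no counterpart in the directory.
#' @param insurance_edits maximal edits applied to accepted-insurance name
#'   strings (the trailing state code is never perturbed).
#' @return list of class `noise_config`.
#' @export
noise_config <- function(max_edits = 2, dropout = 0.1, distractor_rate = 0.1,
                         insurance_edits = 1) {
  if (max_edits < 0) config_error("max_edits", "must be >= 0")
  if (dropout < 0 || dropout > 1) config_error("dropout", "must be in [0, 1]")
  if (distractor_rate < 0) config_error("distractor_rate", "must be >= 0")
  if (insurance_edits < 0) config_error("insurance_edits", "must be >= 0")
  structure(list(max_edits = max_edits, dropout = dropout,
                 distractor_rate = distractor_rate,
                 insurance_edits = insurance_edits),
            class = "noise_config")
}

#' Planted-association specification
#'
#' Target Pearson correlations between plan-level aggregates of member
#' provider attributes and the plan consumer-satisfaction score, and between
#' condition-restricted mean specialist ratings and the condition treatment
#' scores. Defaults are the analysis' headline effect sizes.
#'
#' In `"sample"` mode (default) the plan score is constructed so the sample
#' correlation with each generated aggregate equals the target exactly (the
#' `MASS::mvrnorm(empirical = TRUE)` idea); `"population"` mode draws
#' independent Gaussian noise so the target holds in expectation only.
#'
#' @param attributes named targets in (-1, 1) over plan-level aggregate
#'   columns.
#' @param conditions named targets in (-1, 1) over condition groups (names
#'   must match [default_condition_map()]).
#' @param mode `"sample"` or `"population"`.
#' @return list of class `planted_effects`.
#' @export
planted_effects <- function(attributes = c(mean_rating = 0.376,
                                           mean_referrals = 0.031,
                                           cc_ratio = 0.183,
                                           mean_hospital_rank = -0.108,
                                           mean_relative_cost = 0.266),
                            conditions = c("Women's health" = 0.135,
                                           "Mental and behavioral health" = 0.112,
                                           "Cancer screening" = 0.112,
                                           "Heart disease" = -0.002,
                                           "Children and adolescent health" = -0.083,
                                           "Diabetes" = -0.259),
                            mode = c("sample", "population")) {
  mode <- match.arg(mode)
  for (v in list(attributes, conditions))
    if (length(v) && (any(abs(v) >= 1)))
      config_error("planted_effects", "target correlations must be in (-1, 1)")
  structure(list(attributes = attributes, conditions = conditions, mode = mode),
            class = "planted_effects")
}

#' Configuration of the synthetic world
#'
#' Holds the generator's study conditions: population sizes, the empirical
#' marginals used as defaults (4% Castle Connolly award rate, 42% zero
#' referrals, 50/1956 ranked hospitals, 213/1264 plans with incomplete
#' scores), name-perturbation intensity, planted associations and state-level
#' heterogeneity.
#'
#' @param n_providers,n_plans,n_hospitals positive counts.
#' @param states character vector of two-letter state codes.
#' @param specialties named numeric of target specialty frequencies.
#' @param frac_ranked_hospitals proportion of hospitals with an overall rank.
#' @param frac_castle_connolly proportion of award-holding providers.
#' @param frac_zero_referrals zero mass of the referral-count distribution.
#' @param frac_reviewed proportion of providers with at least one review.
#' @param frac_incomplete_plans proportion of plans with incomplete scores.
#' @param name_noise a [noise_config()].
#' @param planted a [planted_effects()].
#' @param state_heterogeneity standard deviation (score points) of
#'   state-level intercepts added to provider ratings and plan
#'   scores; 0 disables stratification structure and plants the targets
#'   pooled, > 0 plants them within state so pooling attenuates.
#' @param state_intercept_cor correlation in \[-1, 1\] between the rating-side
#'   and plan-score-side state intercepts; negative values produce discordant
#'   intercepts that depress the pooled correlation below every state's.
#' @param seed integer seed; the entire world is a deterministic function of
#'   the configuration.
#' @return list of class `world_config`.
#' @export
world_config <- function(n_providers = 4000, n_plans = 400, n_hospitals = 150,
                         states = c("NY", "TX", "IL", "PA", "CA", "OH", "FL",
                                    "AR", "MA", "WA"),
                         specialties = default_specialty_frequencies(),
                         frac_ranked_hospitals = 50 / 1956,
                         frac_castle_connolly = 0.04,
                         frac_zero_referrals = 0.42,
                         frac_reviewed = 0.3,
                         frac_incomplete_plans = 213 / 1264,
                         name_noise = noise_config(),
                         planted = planted_effects(),
                         state_heterogeneity = 6,
                         state_intercept_cor = 0,
                         seed = 1L) {
  for (f in c("n_providers", "n_plans", "n_hospitals")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v < 1) config_error(f, "must be a positive count")
  }
  for (f in c("frac_ranked_hospitals", "frac_castle_connolly",
              "frac_zero_referrals", "frac_reviewed", "frac_incomplete_plans")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) config_error(f, "must be a proportion in [0, 1]")
  }
  if (length(states) < 1L || anyDuplicated(states))
    config_error("states", "must be distinct state codes")
  if (is.null(names(specialties)) || any(specialties < 0) || sum(specialties) <= 0)
    config_error("specialties", "must be named nonnegative frequencies")
  if (!inherits(name_noise, "noise_config"))
    config_error("name_noise", "must be a noise_config()")
  if (!inherits(planted, "planted_effects"))
    config_error("planted", "must be a planted_effects()")
  if (state_heterogeneity < 0) config_error("state_heterogeneity", "must be >= 0")
  if (abs(state_intercept_cor) > 1) config_error("state_intercept_cor", "must be in [-1, 1]")
  if (!is.numeric(seed) || length(seed) != 1L) config_error("seed", "must be an integer")
  structure(list(
    n_providers = as.integer(n_providers), n_plans = as.integer(n_plans),
    n_hospitals = as.integer(n_hospitals), states = states,
    specialties = specialties / sum(specialties),
    frac_ranked_hospitals = frac_ranked_hospitals,
    frac_castle_connolly = frac_castle_connolly,
    frac_zero_referrals = frac_zero_referrals,
    frac_reviewed = frac_reviewed,
    frac_incomplete_plans = frac_incomplete_plans,
    name_noise = name_noise, planted = planted,
    state_heterogeneity = state_heterogeneity,
    state_intercept_cor = state_intercept_cor, seed = as.integer(seed)),
    class = "world_config")
}

# Disjoint synthetic 3x3-degree bounding boxes on a grid, one per state, so
# radius neighborhoods never leak across states. Purely synthetic geography.
state_boxes <- function(states) {
  i <- seq_along(states) - 1L
  data.frame(state = states,
             lon0 = -125 + 4 * (i %% 8L), lat0 = 28 + 5 * (i %/% 8L),
             stringsAsFactors = FALSE)
}

state_weights <- function(states) {
  w <- seq(1.5, 0.5, length.out = length(states))
  w / sum(w)
}

# Apply up to `max_edits` random single-character edits to each string,
# never touching the first character.
perturb_strings <- function(x, max_edits) {
  if (max_edits == 0) return(x)
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    k <- sample.int(max_edits + 1L, 1L) - 1L
    for (e in seq_len(k)) {
      n <- nchar(s)
      if (n < 2L) break
      op <- sample(c("sub", "ins", "del"), 1L)
      if (op == "sub") {
        p <- sample(2:n, 1L)
        substr(s, p, p) <- sample(letters, 1L)
      } else if (op == "ins") {
        p <- sample(1:n, 1L)
        s <- paste0(substr(s, 1L, p), sample(letters, 1L), substr(s, p + 1L, n))
      } else {
        p <- sample(2:n, 1L)
        s <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, n))
      }
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

# Fresh provider rows (names, geography, training, affiliations).
make_providers <- function(n, id_prefix, states, specialties, hospitals) {
  boxes <- state_boxes(states)
  st <- sample(states, n, replace = TRUE, prob = state_weights(states))
  bi <- match(st, boxes$state)
  spec <- sample(names(specialties), n, replace = TRUE, prob = specialties)
  second <- sample(names(specialties), n, replace = TRUE, prob = specialties)
  has_second <- stats::runif(n) < 0.2 & second != spec
  hosp_by_state <- split(hospitals$hospital_id, hospitals$state)
  aff <- vapply(seq_len(n), function(i) {
    pool <- hosp_by_state[[st[i]]] %||% hospitals$hospital_id
    join_set(sample(pool, min(length(pool), sample.int(3L, 1L))))
  }, character(1))
  data.frame(
    provider_id = sprintf("%s%07d", id_prefix, seq_len(n)),
    first_name = sample(FIRST_NAMES, n, replace = TRUE),
    middle_name = sample(letters, n, replace = TRUE),
    last_name = sample(LAST_NAMES, n, replace = TRUE),
    address = paste(sample(100:9999, n, replace = TRUE),
                    sample(STREET_NAMES, n, replace = TRUE), "st"),
    state = st,
    lat = boxes$lat0[bi] + stats::runif(n) * 3,
    lon = boxes$lon0[bi] + stats::runif(n) * 3,
    specialty = spec,
    specialties = ifelse(has_second, paste(spec, second, sep = ";"), spec),
    medical_school = sample(MEDICAL_SCHOOLS, n, replace = TRUE),
    graduation_year = sample(1965:2010, n, replace = TRUE),
    affiliated_hospitals = aff,
    stringsAsFactors = FALSE)
}

#' Read a world configuration from a YAML or JSON file
#'
#' The file holds top-level [world_config()] arguments; `name_noise` and
#' `planted` may be given as nested maps of [noise_config()] /
#' [planted_effects()] arguments. Unknown fields are an error.
#'
#' @param path path to a `.yaml`/`.yml` (needs the yaml package) or `.json`
#'   file.
#' @return a validated [world_config()].
#' @export
world_config_from_file <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(world_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    config_error(bad[1], "is not a world_config field")
  if (!is.null(raw$name_noise))
    raw$name_noise <- do.call(noise_config, raw$name_noise)
  if (!is.null(raw$planted)) {
    for (f in c("attributes", "conditions"))
      if (!is.null(raw$planted[[f]])) raw$planted[[f]] <- unlist(raw$planted[[f]])
    raw$planted <- do.call(planted_effects, raw$planted)
  }
  if (!is.null(raw$specialties)) raw$specialties <- unlist(raw$specialties)
  do.call(world_config, raw)
}

#' Perturb a provider directory into review-site-style profiles
#'
#' Clones every directory record with up to `noise$max_edits` character edits
#' per name-like field (first, middle, last name, address, medical school;
#' initials preserved), drops droppable fields with probability
#' `noise$dropout`, appends `noise$distractor_rate * n` distractor profiles
#' with no directory counterpart, and returns the ground-truth clone pairs.
#'
#' @param providers directory data.frame (as from [generate_world()]'s
#'   `cms_providers`).
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @return list with `perturbed` (site-style directory, ids `SP...`, shuffled)
#'   and `truth` (data.frame `id_a` = directory id, `id_b` = site id).
#' @export
perturb_directory <- function(providers, noise = noise_config(), seed = 1L) {
  stopifnot(inherits(noise, "noise_config"))
  with_seed(seed, {
    n <- nrow(providers)
    clones <- providers
    for (f in c("first_name", "middle_name", "last_name", "address",
                "medical_school"))
      clones[[f]] <- perturb_strings(clones[[f]], noise$max_edits)
    for (f in c("middle_name", "address", "medical_school", "graduation_year"))
      clones[[f]][stats::runif(n) < noise$dropout] <- NA
    truth <- data.frame(id_a = providers$provider_id,
                        id_b = sprintf("SP%07d", seq_len(n)),
                        stringsAsFactors = FALSE)
    clones$provider_id <- truth$id_b

    n_d <- round(noise$distractor_rate * n)
    if (n_d > 0) {
      # distractors: real-looking strangers in the same states/specialties
      base <- providers[sample.int(n, n_d, replace = TRUE), , drop = FALSE]
      base$first_name <- sample(FIRST_NAMES, n_d, replace = TRUE)
      base$last_name <- sample(LAST_NAMES, n_d, replace = TRUE)
      base$middle_name <- sample(letters, n_d, replace = TRUE)
      base$address <- paste(sample(100:9999, n_d, replace = TRUE),
                            sample(STREET_NAMES, n_d, replace = TRUE), "st")
      base$medical_school <- sample(MEDICAL_SCHOOLS, n_d, replace = TRUE)
      base$graduation_year <- sample(1965:2010, n_d, replace = TRUE)
      base$provider_id <- sprintf("SPX%06d", seq_len(n_d))
      clones <- rbind(clones, base)
    }
    perm <- sample.int(nrow(clones))
    clones <- clones[perm, , drop = FALSE]
    rownames(clones) <- NULL
    list(perturbed = clones, truth = truth)
  })
}

# Build the plan table skeleton (no scores yet): state, category, type,
# carrier-based unique names "<Carrier> <Category> <TYPE>, <ST>".
make_plans <- function(n_plans, states) {
  st <- sample(states, n_plans, replace = TRUE, prob = state_weights(states))
  category <- sample(c("private", "Medicare", "Medicaid"), n_plans,
                     replace = TRUE, prob = c(0.5, 0.3, 0.2))
  plan_type <- sample(c("HMO", "PPO"), n_plans, replace = TRUE)
  catword <- c(private = "Health", Medicare = "Medicare", Medicaid = "Medicaid")
  carrier <- character(n_plans)
  cell <- paste(st, category, plan_type)
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    pool <- CARRIERS
    if (length(idx) > length(pool))
      pool <- c(pool, paste(CARRIERS, "II"), paste(CARRIERS, "III"))
    carrier[idx] <- sample(pool, length(idx))
  }
  data.frame(
    plan_id = sprintf("PL%05d", seq_len(n_plans)),
    plan_name = paste0(carrier, " ", catword[category], " ", plan_type,
                       ", ", st),
    state = st, category = category, plan_type = plan_type,
    stringsAsFactors = FALSE)
}

clip01 <- function(x, lo = 0, hi = 100) pmin(hi, pmax(lo, x))

# Construct y (unit scale) with prescribed sample correlations `rho` to the
# columns of X over rows `rows` (complete cases). In "sample" mode the
# achieved sample correlation is exact; in "population" mode it holds in
# expectation. Rows outside `rows` get standard-normal noise. Strata too
# small to support the joint construction (fewer than 4k complete rows, or
# an empirical aggregate correlation matrix making the targets jointly
# infeasible) fall back to planting the first attribute alone, then to pure
# noise, with a warning.
plant_scores <- function(X, rho, mode = "sample") {
  n_all <- nrow(X)
  y <- stats::rnorm(n_all)
  rows <- which(stats::complete.cases(X))
  orig_k <- ncol(X)
  keep <- which(vapply(seq_len(orig_k), function(j) {
    s <- stats::sd(X[rows, j]); !is.na(s) && s > 0
  }, logical(1)))
  achieved <- rep(NA_real_, orig_k)

  construct <- function(cols) {
    k <- length(cols)
    if (k == 0L || length(rows) < max(k + 3L, 4L * k)) return(NULL)
    Z <- scale(X[rows, cols, drop = FALSE])
    S <- stats::cor(Z)
    w <- tryCatch(solve(S, rho[cols]), error = function(e) NULL)
    if (is.null(w)) return(NULL)
    s2 <- 1 - sum(rho[cols] * w)
    if (s2 < 0) return(NULL)
    eps <- stats::rnorm(length(rows))
    if (mode == "sample") {
      # residualize the noise against [1, Z] and rescale to unit sample sd
      e <- stats::lm.fit(cbind(1, Z), eps)$residuals
      e <- e / stats::sd(e)
    } else {
      e <- eps
    }
    list(y = as.numeric(Z %*% w) + sqrt(s2) * e, cols = cols, Z = Z)
  }

  res <- construct(keep)
  if (is.null(res) && length(keep) > 1L) {
    res <- construct(keep[1L])
    if (!is.null(res))
      warning("plant_scores: stratum too small for the joint construction; planted the first attribute only")
  }
  if (is.null(res)) {
    warning("plant_scores: too few complete rows; scores are pure noise")
    return(list(y = y, rows = rows, achieved = achieved))
  }
  y[rows] <- res$y
  achieved[res$cols] <- vapply(seq_along(res$cols), function(j)
    stats::cor(y[rows], res$Z[, j]), numeric(1))
  list(y = y, rows = rows, achieved = achieved)
}

#' Generate the synthetic world
#'
#' Produces all five source families with ground-truth cross-source identity
#' links and planted associations: a geolocated provider directory with
#' specialties, training and hospital affiliations; a perturbed review-site
#' directory with ratings, review counts, award flags and accepted-insurance
#' strings; a hospital table with partial rankings and per-category scores;
#' charge and referral records; and a plan table whose consumer-satisfaction
#' score is built from the plans' true member-provider aggregates according
#' to `config$planted`. Deterministic given `config` (including its seed).
#'
#' @param config a [world_config()].
#' @return object of class `synthetic_world`; see the package vignette for
#'   the table inventory.
#' @export
generate_world <- function(config = world_config()) {
  if (!inherits(config, "world_config"))
    config_error("config", "must be a world_config()")
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(config) {
  states <- config$states
  n <- config$n_providers

  # hospitals: latent quality drives both scores and who is ranked
  nh <- config$n_hospitals
  hospitals <- data.frame(
    hospital_id = sprintf("H%04d", seq_len(nh)),
    name = paste(sample(c("saint", "mercy", "memorial", "university",
                          "general", "regional", "county", "baptist"),
                        nh, replace = TRUE),
                 sample(LAST_NAMES, nh, replace = TRUE), "medical center"),
    state = sample(states, nh, replace = TRUE, prob = state_weights(states)),
    stringsAsFactors = FALSE)
  quality <- stats::rnorm(nh, 70, 10)
  m <- round(config$frac_ranked_hospitals * nh)
  hospitals$rank <- NA_integer_
  if (m > 0) hospitals$rank[order(-quality)[seq_len(m)]] <- seq_len(m)
  n_cat <- pmin(length(RANKING_CATEGORIES), 3L + stats::rpois(nh, 2))
  hospital_scores <- do.call(rbind, lapply(seq_len(nh), function(i) {
    cats <- sample(RANKING_CATEGORIES, n_cat[i])
    data.frame(hospital_id = hospitals$hospital_id[i], category = cats,
               score = clip01(quality[i] + stats::rnorm(n_cat[i], 0, 5)),
               stringsAsFactors = FALSE)
  }))

  cms <- make_providers(n, "NPI", states, config$specialties, hospitals)

  # referrals: zero-inflated negative binomial (heavy-tailed nonzero part)
  zero <- stats::runif(n) < config$frac_zero_referrals
  referrals <- data.frame(
    provider_id = cms$provider_id,
    n_referrals = ifelse(zero, 0L,
                         1L + stats::rnbinom(n, size = 0.4, mu = 120)),
    stringsAsFactors = FALSE)

  # awards and review ratings (state intercepts drive stratification)
  cc <- stats::runif(n) < config$frac_castle_connolly
  u_state <- stats::rnorm(length(states), 0, config$state_heterogeneity)
  names(u_state) <- states
  rating <- clip01(100 - stats::rgamma(n, shape = 2.2, scale = 8) +
                     u_state[cms$state])
  reviewed <- stats::runif(n) < config$frac_reviewed
  n_reviews <- ifelse(reviewed, 1L + stats::rpois(n, 2), 0L)

  # charges: log-normal per code with specialty and state effects
  codes <- sprintf("HCPCS%05d", seq_len(20L))
  base <- stats::runif(20L, log(80), log(1200))
  spec_eff <- stats::rnorm(length(config$specialties), 0, 0.2)
  names(spec_eff) <- names(config$specialties)
  st_eff <- stats::rnorm(length(states), 0, 0.15)
  names(st_eff) <- states
  n_codes <- sample.int(4L, n, replace = TRUE)
  idx <- rep(seq_len(n), n_codes)
  code_i <- unlist(lapply(n_codes, function(k) sample.int(20L, k)))
  charges <- data.frame(
    provider_id = cms$provider_id[idx],
    hcpcs_code = codes[code_i],
    avg_charged = exp(base[code_i] + spec_eff[cms$specialty[idx]] +
                        st_eff[cms$state[idx]] + stats::rnorm(length(idx), 0, 0.35)),
    n_procedures = 1L + stats::rpois(length(idx), 15),
    stringsAsFactors = FALSE)

  # site directory: perturbed clones + distractors
  site <- perturb_directory(cms, config$name_noise,
                            seed = (config$seed %% 2147480000L) + 17L)
  site_providers <- site$perturbed
  truth_links <- site$truth
  n_site <- nrow(site_providers)
  is_clone <- site_providers$provider_id %in% truth_links$id_b
  clone_of <- truth_links$id_a[match(site_providers$provider_id, truth_links$id_b)]
  cms_row <- match(clone_of, cms$provider_id)

  site_providers$castle_connolly <- ifelse(
    is_clone, cc[cms_row], stats::runif(n_site) < config$frac_castle_connolly)
  site_rating <- ifelse(is_clone, rating[cms_row],
                        clip01(100 - stats::rgamma(n_site, 2.2, scale = 8)))
  site_reviewed <- ifelse(is_clone, reviewed[cms_row],
                          stats::runif(n_site) < config$frac_reviewed)
  site_n_reviews <- ifelse(is_clone, n_reviews[cms_row],
                           1L + stats::rpois(n_site, 2))
  reviews <- data.frame(site_id = site_providers$provider_id,
                        rating = ifelse(site_reviewed, site_rating, NA_real_),
                        n_reviews = ifelse(site_reviewed, site_n_reviews, 0L),
                        stringsAsFactors = FALSE)

  # plans and true membership (in-state, popularity-weighted, 1..8 insurers)
  plans <- make_plans(config$n_plans, states)
  n_ins <- sample(1:8, n, replace = TRUE,
                  prob = c(0.62, 0.2, 0.08, 0.045, 0.025, 0.015, 0.01, 0.005))
  plans_by_state <- split(seq_len(nrow(plans)), plans$state)
  pop_w <- 1 / rank(stats::runif(nrow(plans)))  # Zipf-like popularity
  mem_rows <- lapply(seq_len(n), function(i) {
    pool <- plans_by_state[[cms$state[i]]]
    if (is.null(pool) || length(pool) == 0L) return(NULL)
    k <- min(n_ins[i], length(pool))
    pool[sample.int(length(pool), k, prob = pop_w[pool])]
  })
  truth_membership <- data.frame(
    provider_id = rep(cms$provider_id, lengths(mem_rows)),
    plan_id = plans$plan_id[unlist(mem_rows)],
    stringsAsFactors = FALSE)

  # accepted-insurance strings live on the site profile of each member
  site_of <- setNames(truth_links$id_b, truth_links$id_a)
  parts <- split_state_suffix(plans$plan_name)
  mrow <- match(truth_membership$plan_id, plans$plan_id)
  site_insurances <- data.frame(
    site_id = site_of[truth_membership$provider_id],
    insurance_name = paste0(
      perturb_strings(parts$name[mrow], config$name_noise$insurance_edits),
      ", ", parts$state[mrow]),
    stringsAsFactors = FALSE)
  distractor_ids <- site_providers$provider_id[!is_clone]
  if (length(distractor_ids)) {
    k_d <- sample.int(3L, length(distractor_ids), replace = TRUE)
    di <- rep(seq_along(distractor_ids), k_d)
    pl <- sample.int(nrow(plans), length(di), replace = TRUE)
    site_insurances <- rbind(site_insurances, data.frame(
      site_id = distractor_ids[di],
      insurance_name = paste0(
        perturb_strings(parts$name[pl], config$name_noise$insurance_edits),
        ", ", parts$state[pl]),
      stringsAsFactors = FALSE))
  }
  rownames(site_insurances) <- NULL

  # ground-truth attribute aggregates drive the planted plan scores
  smap <- build_specialty_map(
    table(cms$specialty), default_specialty_category_entries(),
    min_occurrences = 100)
  truth_attrs <- suppressWarnings(derive_attributes(
    truth_links, cms, reviews, site_providers, referrals, charges,
    hospitals, hospital_scores, smap, k = 1000, radius_miles = 30))
  agg_x <- plan_attribute_means(truth_membership, truth_attrs)
  attr_names <- names(config$planted$attributes)
  X_all <- as.matrix(agg_x[, attr_names, drop = FALSE])
  X <- X_all[match(plans$plan_id, agg_x$plan_id), , drop = FALSE]

  # plan-score intercepts: correlated (or discordant, if negative) with the
  # rating-side intercepts u_state
  rho_uv <- config$state_intercept_cor %||% 0
  u_std <- if (stats::sd(u_state) > 0) as.numeric(scale(u_state)) else u_state * 0
  v_state <- config$state_heterogeneity *
    (rho_uv * u_std + sqrt(1 - rho_uv^2) * stats::rnorm(length(states)))
  names(v_state) <- states
  y <- numeric(nrow(plans))
  achieved <- matrix(NA_real_, 0, length(attr_names))
  strata <- if (config$state_heterogeneity > 0) plans$state else rep("overall", nrow(plans))
  ach_list <- list()
  for (s in unique(strata)) {
    rows <- which(strata == s)
    pl <- plant_scores(X[rows, , drop = FALSE], config$planted$attributes,
                       mode = config$planted$mode)
    y[rows] <- pl$y
    ach_list[[s]] <- pl$achieved
  }
  satisfaction <- clip01(75 + v_state[plans$state] *
                           (config$state_heterogeneity > 0) + 7 * y)
  plans$OverallScore <- clip01(0.6 * satisfaction + 0.4 * 75 + stats::rnorm(nrow(plans), 0, 4))
  plans$OverallConsumerSatisfactionScore <- satisfaction
  plans$GettingCareScore <- clip01(satisfaction + stats::rnorm(nrow(plans), 0, 4))
  plans$SatisfactionWithPhysiciansScore <- clip01(satisfaction + stats::rnorm(nrow(plans), 0, 4))
  plans$SatisfactionWithHealthPlanServicesScore <- clip01(satisfaction + stats::rnorm(nrow(plans), 0, 4))
  plans$OverallPreventionScore <- clip01(stats::rnorm(nrow(plans), 75, 8))
  plans$CancerScreeningScore <- clip01(stats::rnorm(nrow(plans), 75, 8))
  plans$OtherPreventiveServicesScore <- clip01(stats::rnorm(nrow(plans), 75, 8))
  plans$OverallTreatmentScore <- clip01(stats::rnorm(nrow(plans), 74, 8))
  plans$AsthmaTreatmentScore <- clip01(stats::rnorm(nrow(plans), 74, 8))
  plans$OtherTreatmentMeasuresScore <- clip01(stats::rnorm(nrow(plans), 74, 8))

  # condition treatment scores planted on condition-restricted mean ratings
  cmap <- default_condition_map()
  cond_targets <- config$planted$conditions
  cond_achieved <- setNames(rep(NA_real_, length(cond_targets)),
                            names(cond_targets))
  for (cn in names(cmap)) {
    col <- cmap[[cn]]$score_column
    if (!cn %in% names(cond_targets)) {  # unplanted condition: noise scores
      plans[[col]] <- clip01(stats::rnorm(nrow(plans), 74, 8))
      next
    }
    ids <- truth_attrs$provider_id[truth_attrs$specialty %in%
                                     cmap[[cn]]$specialties &
                                     !is.na(truth_attrs$user_rating)]
    mem <- truth_membership[truth_membership$provider_id %in% ids, , drop = FALSE]
    if (nrow(mem) == 0L) {
      plans[[col]] <- clip01(stats::rnorm(nrow(plans), 74, 8))
      next
    }
    rt <- truth_attrs$user_rating[match(mem$provider_id, truth_attrs$provider_id)]
    mns <- rowsum(rt, mem$plan_id) / as.integer(table(mem$plan_id))
    xc <- as.numeric(mns)[match(plans$plan_id, rownames(mns))]
    pc <- plant_scores(matrix(xc, ncol = 1), cond_targets[cn],
                       mode = config$planted$mode)
    plans[[col]] <- clip01(74 + 7 * pc$y)
    cond_achieved[cn] <- pc$achieved
  }

  # incomplete-score plans (masked after planting)
  n_inc <- round(config$frac_incomplete_plans * nrow(plans))
  if (n_inc > 0) {
    inc <- sample.int(nrow(plans), n_inc)
    plans$OverallScore[inc] <- NA
    plans$OverallConsumerSatisfactionScore[inc] <- NA
  }

  populations <- data.frame(
    state = states,
    population = round(5e6 * length(states) * state_weights(states)),
    stringsAsFactors = FALSE)

  structure(list(
    cms_providers = cms, site_providers = site_providers,
    site_insurances = site_insurances, reviews = reviews,
    referrals = referrals, charges = charges, hospitals = hospitals,
    hospital_scores = hospital_scores, plans = plans,
    populations = populations, truth_links = truth_links,
    truth_membership = truth_membership, truth_attributes = truth_attrs,
    specialty_map = smap,
    truth_params = list(attribute_targets = config$planted$attributes,
                        attribute_achieved = ach_list,
                        condition_targets = cond_targets,
                        condition_achieved = cond_achieved,
                        mode = config$planted$mode),
    config = config), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic provider/plan world (seed", x$config$seed, ")\n")
  cat(sprintf("  directory providers: %d\n  site profiles:       %d (%d distractors)\n",
              nrow(x$cms_providers), nrow(x$site_providers),
              nrow(x$site_providers) - nrow(x$truth_links)))
  cat(sprintf("  hospitals: %d (%d ranked)   plans: %d   charges: %d rows\n",
              nrow(x$hospitals), sum(!is.na(x$hospitals$rank)),
              nrow(x$plans), nrow(x$charges)))
  invisible(x)
}

#' Write the synthetic world as CSV tables
#'
#' Writes the five source families plus the ground-truth sidecars
#' (`truth_links.csv`, `truth_membership.csv`, `truth_params.json`) into a
#' directory.
#'
#' @param world a [generate_world()] object.
#' @param dir output directory (created if absent).
#' @param overwrite overwrite an existing directory?
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("write_world: ", dir, " exists; use overwrite = TRUE", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("cms_providers", "site_providers", "site_insurances", "reviews",
              "referrals", "charges", "hospitals", "hospital_scores",
              "plans", "populations", "truth_links", "truth_membership")
  for (tb in tables)
    utils::write.csv(world[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(world$truth_params,
                       file.path(dir, "truth_params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a world written by [write_world()]
#'
#' @param dir directory containing the CSV tables.
#' @return list resembling a `synthetic_world` (without config).
#' @export
read_world <- function(dir) {
  tables <- c("cms_providers", "site_providers", "site_insurances", "reviews",
              "referrals", "charges", "hospitals", "hospital_scores",
              "plans", "populations", "truth_links", "truth_membership")
  out <- lapply(tables, function(tb) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (file.exists(f)) utils::read.csv(f, stringsAsFactors = FALSE) else NULL
  })
  names(out) <- tables
  structure(out, class = "synthetic_world")
}
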