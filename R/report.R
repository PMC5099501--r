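# End-to-end orchestration: generate (or accept) the source tables, link the
# directories, derive attributes, aggregate per plan, run the correlation
# battery, and emit the analysis artifacts plus a run manifest.

#' Linkage quality report
#'
#' Accepted-pair count and score distribution; precision, recall and F1
#' against ground-truth pairs when available.
#'
#' @param links a `link_set` from [link_directories()].
#' @param truth optional data.frame of true pairs (`id_a`, `id_b`).
#' @return list of class `linkage_report`.
#' @export
linkage_report <- function(links, truth = NULL) {
  acc <- links$accepted
  out <- list(n_scored = nrow(links$scored_pairs), n_accepted = nrow(acc),
              threshold = links$threshold,
              score_summary = if (nrow(acc)) summary(acc$score) else NULL)
  if (!is.null(truth) && nrow(truth) > 0) {
    key <- function(d) paste(d$id_a, d$id_b, sep = "\r")
    tp <- sum(key(acc) %in% key(truth))
    out$precision <- if (nrow(acc)) tp / nrow(acc) else NA_real_
    out$recall <- tp / nrow(truth)
    out$f1 <- if (!is.na(out$precision) && out$precision + out$recall > 0)
      2 * out$precision * out$recall / (out$precision + out$recall) else 0
  }
  structure(out, class = "linkage_report")
}

#' @export
print.linkage_report <- function(x, ...) {
  cat(sprintf("Linkage: %d scored pairs, %d accepted (threshold %.3f)\n",
              x$n_scored, x$n_accepted, x$threshold))
  if (!is.null(x$precision))
    cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n",
                x$precision, x$recall, x$f1))
  invisible(x)
}

# md5 of the serialized configuration, via a temp file (tools::md5sum is
# file-based).
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[order(names(config))], f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (unless a world is supplied) -> link the site profiles to
#' the directory -> map accepted-insurance strings to plan names -> derive
#' provider attributes -> aggregate per plan -> correlation battery
#' (pooled attribute correlations, state-wise stratification, per-plan-type
#' statistics, condition-specific treatment-score correlations) -> report.
#'
#' With `linkage = "truth"` the ground-truth clone pairs are used instead of
#' fuzzy matching (an evaluation mode that isolates the downstream stages).
#' With `threshold = NULL` and ground truth available, the acceptance
#' threshold is calibrated by F1 sweep; otherwise the default 0.85 is used.
#'
#' @param config a [world_config()]; ignored when `world` is given.
#' @param world an existing [generate_world()] object (or [read_world()]
#'   result) to analyze instead of simulating.
#' @param linkage `"fuzzy"` (default) or `"truth"`.
#' @param weights,blocking passed to [link_directories()].
#' @param threshold acceptance threshold, or NULL to calibrate.
#' @param min_similarity minimal similarity for insurance-name mapping.
#' @param min_members minimal plan membership for correlation inclusion.
#' @param min_plans minimal per-state plan count for state-wise correlations.
#' @param k,radius_miles relative-cost neighborhood parameters.
#' @param referral_norm referral normalization (see [derive_attributes()]).
#' @param bh append Benjamini-Hochberg adjusted p-values to correlation
#'   tables?
#' @param out_dir optional output directory for the CSV/JSON artifacts.
#' @param overwrite overwrite a nonempty `out_dir`?
#' @return object of class `pipeline_result`.
#' @export
run_pipeline <- function(config = world_config(), world = NULL,
                         linkage = c("fuzzy", "truth"),
                         weights = default_weights(),
                         blocking = "last_initial_state",
                         threshold = NULL, min_similarity = 0.6,
                         min_members = 5, min_plans = 3,
                         k = 1000, radius_miles = 30,
                         referral_norm = "none", bh = FALSE,
                         out_dir = NULL, overwrite = FALSE) {
  linkage <- match.arg(linkage)
  if (is.null(world)) world <- generate_world(config)

  has_truth <- !is.null(world$truth_links) && nrow(world$truth_links) > 0
  if (linkage == "truth") {
    if (!has_truth) stop("run_pipeline: linkage = 'truth' needs truth_links",
                         call. = FALSE)
    links <- NULL
    accepted <- world$truth_links
    lr <- NULL
  } else {
    links <- link_directories(world$cms_providers, world$site_providers,
                              weights = weights, threshold = 0,
                              blocking = blocking)
    if (is.null(threshold)) {
      threshold <- if (has_truth)
        calibrate_threshold(links$scored_pairs, world$truth_links)$threshold
      else 0.85
    }
    links$threshold <- threshold
    links$accepted <- links$accepted[links$accepted$score >= threshold, ,
                                     drop = FALSE]
    accepted <- links$accepted
    lr <- linkage_report(links, if (has_truth) world$truth_links else NULL)
  }

  smap <- world$specialty_map %||% build_specialty_map(
    table(world$cms_providers$specialty),
    default_specialty_category_entries(), min_occurrences = 100)

  attrs <- suppressWarnings(derive_attributes(
    accepted, world$cms_providers, world$reviews, world$site_providers,
    world$referrals, world$charges, world$hospitals, world$hospital_scores,
    smap, k = k, radius_miles = radius_miles, referral_norm = referral_norm))

  # membership: accepted-insurance strings of linked site profiles, mapped
  # to plan names, attributed to the linked directory provider
  ins <- world$site_insurances
  ins <- ins[ins$site_id %in% accepted$id_b, , drop = FALSE]
  imap <- match_insurance_names(unique(ins$insurance_name),
                                world$plans$plan_name,
                                min_similarity = min_similarity)
  provider_insurances <- data.frame(
    provider_id = accepted$id_a[match(ins$site_id, accepted$id_b)],
    insurance_name = ins$insurance_name, stringsAsFactors = FALSE)
  membership <- plan_membership(world$plans, provider_insurances, imap)

  agg <- suppressMessages(plan_aggregates(world$plans, membership, attrs,
                                          min_members = min_members))

  correlations <- attribute_correlations(agg, bh = bh)
  statewise <- statewise_correlations(agg, min_plans = min_plans, bh = bh)
  ptt <- suppressWarnings(plan_type_table(agg))
  cmap <- default_condition_map()
  cond <- suppressWarnings(condition_correlations(attrs, membership,
                                                  world$plans, cmap))
  states <- state_summaries(world$plans, world$cms_providers,
                            world$populations)

  manifest <- list(
    package_version = as.character(utils::packageVersion("planlink")),
    config_hash = if (!is.null(world$config)) config_hash(world$config) else NA,
    seed = if (!is.null(world$config)) world$config$seed else NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    linkage_mode = linkage,
    counts = list(
      providers = nrow(world$cms_providers),
      site_profiles = nrow(world$site_providers),
      pairs_scored = if (is.null(links)) 0L else nrow(links$scored_pairs),
      links_accepted = nrow(accepted),
      providers_attributed = nrow(attrs),
      memberships = nrow(membership),
      plans_aggregated = nrow(agg),
      correlations_emitted = nrow(correlations) + nrow(statewise) + nrow(cond)))

  out <- structure(list(
    world = world, links = links, linkage_report = lr, attributes = attrs,
    membership = membership, aggregates = agg, correlations = correlations,
    statewise = statewise, plan_type_stats = ptt,
    condition_correlations = cond, state_summaries = states,
    insurance_map = imap, manifest = manifest), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir, overwrite)
  out
}

write_pipeline_result <- function(result, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("run_pipeline: ", out_dir, " exists; use overwrite = TRUE",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_world(result$world, file.path(out_dir, "input"), overwrite = overwrite)
  tabdir <- file.path(out_dir, "tables")
  dir.create(tabdir, showWarnings = FALSE)
  tabs <- list(provider_attributes = result$attributes,
               plan_aggregates = result$aggregates,
               correlations = result$correlations,
               statewise_correlations = result$statewise,
               plan_type_stats = result$plan_type_stats,
               condition_correlations = result$condition_correlations,
               state_summaries = result$state_summaries,
               membership = result$membership)
  for (nm in names(tabs))
    utils::write.csv(tabs[[nm]], file.path(tabdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(result$linkage_report)) {
    lr <- result$linkage_report
    utils::write.csv(
      data.frame(metric = c("n_scored", "n_accepted", "threshold",
                            "precision", "recall", "f1"),
                 value = c(lr$n_scored, lr$n_accepted, lr$threshold,
                           lr$precision %||% NA, lr$recall %||% NA,
                           lr$f1 %||% NA)),
      file.path(tabdir, "linkage_report.csv"), row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Plan-provider correlation pipeline\n")
  m <- x$manifest$counts
  cat(sprintf("  %d providers, %d site profiles, %d links, %d plans aggregated\n",
              m$providers, m$site_profiles, m$links_accepted,
              m$plans_aggregated))
  if (!is.null(x$linkage_report) && !is.null(x$linkage_report$precision))
    cat(sprintf("  linkage precision %.3f, recall %.3f\n",
                x$linkage_report$precision, x$linkage_report$recall))
  cat("  pooled attribute correlations:\n")
  for (i in seq_len(nrow(x$correlations)))
    cat(sprintf("    %-20s r = %+.3f (p = %.3g, n = %d)\n",
                x$correlations$x_attribute[i], x$correlations$r[i],
                x$correlations$p_value[i], x$correlations$n[i]))
  invisible(x)
}
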