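#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rpois rnbinom qnorm sd cor p.adjust
#'   complete.cases aggregate setNames weighted.mean quantile median
#' @importFrom utils adist head
NULL

# Canonicalize a free-text name for fuzzy comparison: case-fold, strip
# punctuation (optionally preserving commas, which delimit trailing state
# codes in insurance names), collapse whitespace.
#' Canonicalize a string for fuzzy matching
#'
#' Lower-cases, strips punctuation (optionally keeping commas, which separate
#' an insurance name from its trailing two-letter state code), and collapses
#' runs of whitespace.
#'
#' @param x character vector.
#' @param keep_comma keep commas (needed for insurance-name state suffixes)?
#' @return character vector of the same length.
#' @export
#' @examples
#' canonicalize_string("  United   Healthcare Services, CA ")
canonicalize_string <- function(x, keep_comma = FALSE) {
  x <- tolower(as.character(x))
  pattern <- if (keep_comma) "[^a-z0-9, ]" else "[^a-z0-9 ]"
  x <- gsub(pattern, " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Split "<name>, <ST>" into name part and state code. Names without a
# recognizable trailing state code get NA state.
split_state_suffix <- function(x) {
  m <- regmatches(x, regexec("^(.*?),\\s*([A-Za-z]{2})\\s*$", x))
  name <- vapply(seq_along(x), function(i) {
    if (length(m[[i]]) == 3) m[[i]][2] else x[i]
  }, character(1))
  state <- vapply(m, function(g) if (length(g) == 3) toupper(g[3]) else NA_character_,
                  character(1))
  data.frame(name = name, state = state, stringsAsFactors = FALSE)
}

# Jaccard overlap of two small sets; empty-vs-anything is treated as a
# missing field (NA), not disagreement.
jaccard <- function(a, b) {
  a <- unique(a[!is.na(a) & nzchar(a)])
  b <- unique(b[!is.na(b) & nzchar(b)])
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}

# ";"-separated set fields used in the flat CSV representation.
split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

join_set <- function(x) paste(sort(unique(x)), collapse = ";")

# Half-up rounding to an integer (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

# Stop with a configuration error naming the offending field.
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate an expression under a seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
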