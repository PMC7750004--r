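#' Normalize a cloze completion string
#'
#' Trims whitespace, lowercases, and keeps only the first
#' whitespace-delimited token. Respondents were asked to complete a
#' truncated sentence with "the word or words that first came to mind";
#' the first token is the candidate particle.
#'
#' @param x character vector of raw completions.
#' @return character vector of normalized completions.
#' @export
#' @examples
#' normalize_completion(c("  Vor ", "an und fuer sich"))
normalize_completion <- function(x) {
  x <- tolower(trimws(as.character(x)))
  sub("\\s.*$", "", x)
}

#' Construct a set of cloze responses for one item and condition
#'
#' A `cloze_response_set` holds the completion counts collected for one
#' item in one cell of the 2x2 (set size x distance) design, together
#' with a flag marking which completion types are verb particles.
#'
#' @param item_id item identifier.
#' @param set_size `"small"` or `"large"`.
#' @param distance `"short"` or `"long"`.
#' @param completions named integer vector: completion string -> count.
#' @param is_particle named logical vector over the same names.
#' @param n_respondents number of respondents who saw this item/condition.
#'   Defaults to the total completion count.
#' @return an object of class `cloze_response_set`.
#' @export
cloze_response_set <- function(item_id, set_size, distance, completions,
                               is_particle, n_respondents = sum(completions)) {
  if (length(completions) == 0L) {
    stop_validation("empty response set for item ", item_id, ": no cloze data")
  }
  assert_that(all(completions >= 1), "all completion counts must be >= 1")
  assert_that(!is.null(names(completions)) && all(nzchar(names(completions))),
              "completions must be a named count vector")
  set_size <- match.arg(set_size, c("small", "large"))
  distance <- match.arg(distance, c("short", "long"))
  assert_that(all(names(completions) %in% names(is_particle)),
              "is_particle must cover every completion type")
  is_particle <- is_particle[names(completions)]
  assert_that(sum(completions) <= n_respondents,
              "completion counts exceed the number of respondents")
  structure(
    list(item_id = item_id, set_size = set_size, distance = distance,
         completions = completions, is_particle = is_particle,
         n_respondents = n_respondents),
    class = "cloze_response_set"
  )
}

# Shannon entropy in bits of a probability vector; zero-probability
# terms contribute nothing.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Cloze probabilities, target cloze, and entropy for one item/condition
#'
#' Normalizes completion counts to cloze probabilities and computes the
#' Shannon entropy H = -sum_i P_i log2 P_i (in bits) over the chosen
#' completion universe. With `particle_only = TRUE` (the default) the
#' universe is restricted to completions flagged as particles, mirroring
#' norming practice where predictability of the particle itself is at
#' stake; non-particle completions can be retained for sensitivity
#' analyses.
#'
#' @param responses a [cloze_response_set()].
#' @param target the designated target particle. Its cloze probability is
#'   0 when it was never produced.
#' @param particle_only restrict the probability universe to particles?
#' @return an object of class `cloze_statistics`: a list with
#'   `probabilities`, `target_cloze`, `entropy_H` (bits),
#'   `n_particle_types`, plus the item/condition identifiers.
#' @export
#' @examples
#' rs <- cloze_response_set("i1", "small", "short",
#'                          c(vor = 9, an = 1), c(vor = TRUE, an = TRUE))
#' compute_cloze_statistics(rs, target = "vor")$entropy_H  # 0.469
compute_cloze_statistics <- function(responses, target, particle_only = TRUE) {
  stopifnot(inherits(responses, "cloze_response_set"))
  counts <- responses$completions
  if (particle_only) {
    counts <- counts[responses$is_particle[names(counts)]]
  }
  if (length(counts) == 0L) {
    probs <- numeric(0)
    h <- NA_real_
  } else {
    probs <- counts / sum(counts)
    h <- entropy_bits(probs)
  }
  n_particle <- sum(responses$is_particle[names(responses$completions)])
  structure(
    list(item_id = responses$item_id,
         set_size = responses$set_size,
         distance = responses$distance,
         probabilities = probs,
         target_particle = target,
         target_cloze = if (target %in% names(probs)) unname(probs[[target]]) else 0,
         entropy_H = h,
         n_particle_types = n_particle),
    class = "cloze_statistics"
  )
}

#' @export
print.cloze_statistics <- function(x, ...) {
  cat(sprintf("Cloze statistics for item %s (%s set, %s distance)\n",
              x$item_id, x$set_size, x$distance))
  cat(sprintf("  target '%s': cloze %.3f | entropy %.3f bits | %d particle types\n",
              x$target_particle, x$target_cloze, x$entropy_H, x$n_particle_types))
  invisible(x)
}

#' Flatten a collection of cloze statistics into a data frame
#'
#' @param stats list of `cloze_statistics` objects.
#' @return data frame with one row per item x condition.
#' @export
cloze_stats_table <- function(stats) {
  do.call(rbind, lapply(stats, function(s) {
    data.frame(item_id = s$item_id, set_size = s$set_size,
               distance = s$distance, target_particle = s$target_particle,
               target_cloze = s$target_cloze, entropy_H = s$entropy_H,
               n_particle_types = s$n_particle_types,
               stringsAsFactors = FALSE)
  }))
}

# Method-of-moments Beta fit. Returns shape1/shape2; errors on zero
# variance (handled by the caller).
fit_beta_moments <- function(x) {
  m <- mean(x)
  v <- stats::var(x)
  if (v <= 0) return(NULL)
  nu <- m * (1 - m) / v - 1
  if (nu <= 0) return(NULL)
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

#' Condition-level summaries of cloze probability and entropy
#'
#' For one level of one design factor, summarizes per-item target-cloze
#' values by a method-of-moments Beta fit (mean and 2.5%/97.5% Beta
#' quantiles, the "CI of the cloze probability distribution") and
#' per-item entropies by their mean with a nonparametric bootstrap 95%
#' CI (2,000 resamples under a fixed seed).
#'
#' @param stats list of `cloze_statistics` objects, or a data frame from
#'   [cloze_stats_table()].
#' @param factor `"set_size"` or `"distance"`.
#' @param level the factor level to summarize (e.g. `"small"`).
#' @param n_boot bootstrap resamples for the entropy CI.
#' @param seed RNG seed for the bootstrap.
#' @return data frame with rows `cloze` and `entropy` and columns
#'   `mean`, `ci_low`, `ci_high`.
#' @export
summarize_condition <- function(stats, factor = c("set_size", "distance"),
                                level, n_boot = 2000, seed = 1L) {
  factor <- match.arg(factor)
  if (!is.data.frame(stats)) stats <- cloze_stats_table(stats)
  rows <- stats[stats[[factor]] == level, ]
  assert_that(nrow(rows) >= 2, "need at least 2 items at level '", level, "'")
  cloze <- rows$target_cloze
  ent <- rows$entropy_H
  assert_that(all(cloze >= 0 & cloze <= 1), "cloze values must lie in [0, 1]")

  beta <- fit_beta_moments(cloze)
  if (is.null(beta)) {
    warning("degenerate cloze distribution at level '", level,
            "': zero variance, CI collapsed to the mean")
    cloze_sum <- c(mean(cloze), mean(cloze), mean(cloze))
  } else {
    cloze_sum <- c(beta[["shape1"]] / sum(beta),
                   stats::qbeta(c(0.025, 0.975), beta[["shape1"]], beta[["shape2"]]))
  }

  if (stats::var(ent) <= 0) {
    warning("degenerate entropy distribution at level '", level,
            "': zero variance, CI collapsed to the mean")
    ent_sum <- c(mean(ent), mean(ent), mean(ent))
  } else {
    boots <- with_seed(seed, replicate(n_boot, mean(sample(ent, replace = TRUE))))
    ent_sum <- c(mean(ent), stats::quantile(boots, c(0.025, 0.975), names = FALSE))
  }

  out <- data.frame(statistic = c("cloze", "entropy"),
                    level = level,
                    mean = c(cloze_sum[1], ent_sum[1]),
                    ci_low = c(cloze_sum[2], ent_sum[2]),
                    ci_high = c(cloze_sum[3], ent_sum[3]),
                    stringsAsFactors = FALSE)
  attr(out, "beta_shapes") <- beta
  out
}

#' Median split of a numeric vector into low/high categories
#'
#' Values strictly below the median go to `low`, strictly above to
#' `high`; ties at the median are assigned `low` so the split is
#' deterministic.
#'
#' @param values numeric vector (e.g. per-item entropies).
#' @return factor with levels `low`, `high`, same length as `values`.
#' @export
median_split <- function(values) {
  assert_that(length(values) >= 2, "median split needs at least 2 values")
  med <- stats::median(values)
  labs <- ifelse(values > med, "high", "low")
  if (all(labs == "low")) {
    warning("all values tied at the median; every value labelled 'low'")
  }
  factor(labs, levels = c("low", "high"))
}

#' Select items that achieve the set-size manipulation
#'
#' An item is retained when (a) every one of its four conditions
#' elicited at least one particle completion, and (b) within each
#' distance level the large-set condition elicited strictly more
#' particle types than the small-set condition. Items missing a
#' condition are skipped with a logged reason.
#'
#' @param stats list of `cloze_statistics` (all four conditions per
#'   item) or a data frame from [cloze_stats_table()].
#' @return data frame with columns `item_id`, `retained`, `reason`.
#' @export
select_items <- function(stats) {
  if (!is.data.frame(stats)) stats <- cloze_stats_table(stats)
  out <- lapply(split(stats, stats$item_id), function(d) {
    cell <- function(ss, dist) d[d$set_size == ss & d$distance == dist, ]
    cells <- list(cell("small", "short"), cell("small", "long"),
                  cell("large", "short"), cell("large", "long"))
    if (any(vapply(cells, nrow, 0L) != 1L)) {
      return(data.frame(item_id = d$item_id[1], retained = FALSE,
                        reason = "missing condition", stringsAsFactors = FALSE))
    }
    types <- vapply(cells, function(x) x$n_particle_types, 0)
    if (any(types < 1)) {
      return(data.frame(item_id = d$item_id[1], retained = FALSE,
                        reason = "no particle", stringsAsFactors = FALSE))
    }
    # large > small within each distance level
    if (!(types[3] > types[1] && types[4] > types[2])) {
      return(data.frame(item_id = d$item_id[1], retained = FALSE,
                        reason = "set-size contrast not elicited",
                        stringsAsFactors = FALSE))
    }
    data.frame(item_id = d$item_id[1], retained = TRUE, reason = "ok",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a delimited cloze-response table
#'
#' Expects a UTF-8 CSV with columns `item`, `set_size`, `distance`,
#' `respondent`, `completion`, `is_particle` (one row per respondent).
#' Completions are cleaned with [normalize_completion()] before
#' counting.
#'
#' @param path CSV file path.
#' @return list of [cloze_response_set()] objects, one per
#'   item x condition.
#' @export
read_cloze_responses <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("item", "set_size", "distance", "respondent", "completion", "is_particle")
  assert_that(all(need %in% names(d)),
              "cloze table must have columns: ", paste(need, collapse = ", "))
  d$completion <- normalize_completion(d$completion)
  d$is_particle <- as.logical(d$is_particle)
  key <- interaction(d$item, d$set_size, d$distance, drop = TRUE)
  lapply(split(d, key), function(g) {
    counts <- table(g$completion)
    flags <- tapply(g$is_particle, g$completion, any)
    cloze_response_set(
      item_id = g$item[1], set_size = g$set_size[1], distance = g$distance[1],
      completions = stats::setNames(as.integer(counts), names(counts)),
      is_particle = flags[names(counts)],
      n_respondents = length(unique(g$respondent))
    )
  })
}
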