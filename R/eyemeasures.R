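#' Construct a fixation sequence for one trial
#'
#' Fixations are stored in chronological order as (region index,
#' duration) pairs, with region indices 1-based over
#' whitespace-delimited words. Zero or negative durations and region
#' indices below 1 are rejected.
#'
#' @param trial_id trial identifier.
#' @param regions integer vector of region indices, in fixation order.
#' @param durations_ms positive fixation durations in ms.
#' @param blink_or_trackloss did the trial contain a blink or track
#'   loss? Such trials are removed by [exclude_invalid_trials()].
#' @return object of class `fixation_sequence`.
#' @export
fixation_sequence <- function(trial_id, regions, durations_ms,
                              blink_or_trackloss = FALSE) {
  assert_that(length(regions) == length(durations_ms),
              "regions and durations must have equal length")
  assert_that(all(durations_ms > 0), "fixation durations must be positive")
  assert_that(all(regions >= 1), "region indices must be >= 1")
  structure(list(trial_id = trial_id,
                 regions = as.integer(regions),
                 durations_ms = as.numeric(durations_ms),
                 blink_or_trackloss = isTRUE(blink_or_trackloss)),
            class = "fixation_sequence")
}

#' Reading measures for a target region
#'
#' Computes the four standard reading-time measures for a (possibly
#' multi-word) target region from an ordered fixation sequence:
#'
#' * **FFD** (first fixation duration): duration of the first first-pass
#'   fixation on the region.
#' * **FPRT** (first-pass reading time, gaze duration): summed fixations
#'   from first entering the region until first leaving it in either
#'   direction.
#' * **TFT** (total fixation time): sum of all fixations on the region.
#' * **RPD** (regression path duration, go-past time): summed fixations
#'   from first entering the region until the first fixation strictly to
#'   its right, including regressive fixations to earlier regions.
#'
#' The region is fixated "in first pass" only if its first fixation
#' occurs before any fixation to the right of the region; otherwise the
#' region counts as skipped in first pass and FFD/FPRT/RPD are missing
#' while TFT still accumulates later fixations. If no fixation ever
#' lands to the right of the region, RPD runs to the end of the trial
#' and is flagged `rpd_unterminated`. Because particles are short and
#' often not fixated on their own, analyses typically use the merged
#' span (particle - 1, particle); pass that span as `region`.
#'
#' @param seq a [fixation_sequence()].
#' @param region integer vector of region indices forming a contiguous
#'   span (e.g. `c(4, 5)`).
#' @return one-row data frame with `trial_id`, `ffd_ms`, `fprt_ms`,
#'   `tft_ms`, `rpd_ms`, `skipped_first_pass`, `rpd_unterminated`.
#' @export
#' @examples
#' s <- fixation_sequence("t1", c(1, 2, 3, 2, 3, 4),
#'                        c(200, 250, 150, 100, 300, 180))
#' compute_region_measures(s, region = 3)
compute_region_measures <- function(seq, region) {
  stopifnot(inherits(seq, "fixation_sequence"))
  region <- sort(unique(as.integer(region)))
  assert_that(length(region) >= 1, "region span must be non-empty")
  assert_that(all(diff(region) == 1L) || length(region) == 1L,
              "region span must be contiguous")

  reg <- seq$regions
  dur <- seq$durations_ms
  in_region <- reg %in% region
  right_of <- reg > max(region)

  res <- data.frame(trial_id = seq$trial_id,
                    ffd_ms = NA_real_, fprt_ms = NA_real_,
                    tft_ms = NA_real_, rpd_ms = NA_real_,
                    skipped_first_pass = TRUE, rpd_unterminated = FALSE,
                    stringsAsFactors = FALSE)

  if (!any(in_region)) return(res)

  first_in <- which(in_region)[1]
  res$tft_ms <- sum(dur[in_region])

  # first fixated only after material to its right: first-pass skip
  if (any(right_of[seq_len(first_in - 1)])) return(res)

  res$skipped_first_pass <- FALSE
  res$ffd_ms <- dur[first_in]

  # first pass: maximal run of fixations staying inside the region
  leave <- which(!in_region & seq_along(reg) > first_in)
  first_pass_end <- if (length(leave)) leave[1] - 1L else length(reg)
  res$fprt_ms <- sum(dur[first_in:first_pass_end])

  # go-past: until the first fixation strictly right of the region
  exit_right <- which(right_of & seq_along(reg) > first_in)
  if (length(exit_right)) {
    res$rpd_ms <- sum(dur[first_in:(exit_right[1] - 1L)])
  } else {
    res$rpd_ms <- sum(dur[first_in:length(reg)])
    res$rpd_unterminated <- TRUE
  }
  res
}

#' Reading measures for a collection of trials
#'
#' @param trials list of [fixation_sequence()] objects.
#' @param region target region span, as in [compute_region_measures()].
#' @return tidy data frame, one row per trial.
#' @export
region_measures_table <- function(trials, region) {
  out <- do.call(rbind, lapply(trials, compute_region_measures, region = region))
  rownames(out) <- NULL
  out
}

#' Exclude trials with blinks or track loss
#'
#' @param trials list of [fixation_sequence()] objects.
#' @return list with `retained` (the clean trials) and `log` (a data
#'   frame of exclusion counts by reason).
#' @export
exclude_invalid_trials <- function(trials) {
  flagged <- vapply(trials, function(t) t$blink_or_trackloss, TRUE)
  list(
    retained = trials[!flagged],
    log = data.frame(reason = "blink/track loss",
                     n_excluded = sum(flagged),
                     n_retained = sum(!flagged),
                     stringsAsFactors = FALSE)
  )
}

#' Read a fixation table from CSV
#'
#' Expects columns `trial`, `order`, `region`, `duration_ms`,
#' `blink_flag`; rows are sorted by `order` within trial.
#'
#' @param path CSV file path.
#' @return list of [fixation_sequence()] objects.
#' @export
read_fixations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("trial", "order", "region", "duration_ms", "blink_flag")
  assert_that(all(need %in% names(d)),
              "fixation table must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, d$trial), function(g) {
    g <- g[order(g$order), ]
    fixation_sequence(g$trial[1], g$region, g$duration_ms,
                      blink_or_trackloss = any(as.logical(g$blink_flag)))
  })
}
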