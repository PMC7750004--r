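# Shared fixtures and independent reference implementations.

# Literal transcription of the verbal reading-measure definitions,
# written as explicit scans so it stays independent of the package's
# vectorized implementation.
ref_region_measures <- function(regions, durations, span) {
  span <- sort(span)
  right <- max(span)
  n <- length(regions)
  out <- list(ffd = NA_real_, fprt = NA_real_, tft = NA_real_,
              rpd = NA_real_, skipped = TRUE, unterminated = FALSE)

  # total fixation time: every fixation on the region, whole trial
  tft <- 0
  any_in <- FALSE
  for (k in seq_len(n)) {
    if (regions[k] %in% span) { tft <- tft + durations[k]; any_in <- TRUE }
  }
  if (!any_in) return(out)
  out$tft <- tft

  # first entry; a prior fixation right of the region means first-pass skip
  entry <- 0
  for (k in seq_len(n)) {
    if (regions[k] %in% span) { entry <- k; break }
    if (regions[k] > right) return(out)
  }
  out$skipped <- FALSE
  out$ffd <- durations[entry]

  # first pass: until the first fixation outside the span
  fprt <- 0
  k <- entry
  while (k <= n && regions[k] %in% span) {
    fprt <- fprt + durations[k]
    k <- k + 1
  }
  out$fprt <- fprt

  # go-past: until the first fixation strictly right of the span
  rpd <- 0
  k <- entry
  while (k <= n && regions[k] <= right) {
    rpd <- rpd + durations[k]
    k <- k + 1
  }
  out$rpd <- rpd
  out$unterminated <- k > n
  out
}

# small deterministic cloze response set
make_cloze_rs <- function(counts, item = "i1", ss = "small", dist = "short",
                          particles = rep(TRUE, length(counts))) {
  cloze_response_set(item, ss, dist, counts,
                     stats::setNames(particles, names(counts)))
}

# a full 4-condition item for select_items tests
make_item_stats <- function(item, types) {
  # types: named numeric c(small_short, small_long, large_short, large_long)
  data.frame(
    item_id = item,
    set_size = c("small", "small", "large", "large"),
    distance = c("short", "long", "short", "long"),
    target_particle = "p1",
    target_cloze = 0.5,
    entropy_H = 1,
    n_particle_types = as.numeric(types),
    stringsAsFactors = FALSE
  )
}
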