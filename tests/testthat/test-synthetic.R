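test_that("Latin-square balance holds across random configurations", {
  set.seed(11)
  for (rep in 1:5) {
    n_items <- 4 * sample(1:8, 1)
    n_part <- sample(4:40, 1)
    des <- experiment_design(n_part, n_items, n_fillers = sample(0:30, 1),
                             seed = rep)
    ls <- build_latin_square(des)
    # each participant sees each item exactly once
    expect_equal(nrow(ls), n_part * n_items)
    expect_true(all(table(ls$participant, ls$item) == 1))
    # per-participant condition counts
    cond <- paste(ls$set_size, ls$distance)
    expect_true(all(table(ls$participant, cond) == n_items / 4))
    # across the four lists every item appears in all four conditions
    by_item <- table(ls$item, cond, ls$list)
    for (it in seq_len(min(n_items, 4))) {
      per_list <- unique(ls[ls$item == it, c("list", "set_size", "distance")])
      expect_equal(nrow(per_list), 4L)
      expect_equal(length(unique(paste(per_list$set_size, per_list$distance))), 4L)
    }
    # presentation slots are unique within participant and within range
    for (pp in unique(ls$participant)[1:2]) {
      slots <- ls$presentation_order[ls$participant == pp]
      expect_false(any(duplicated(slots)))
      expect_true(all(slots >= 1 & slots <= n_items + des$n_fillers))
    }
  }
  expect_error(experiment_design(10, 10), "divisible")
})

test_that("item 7 rotates through all four conditions across lists", {
  ls <- build_latin_square(experiment_design(4, 24, seed = 2))
  item7 <- ls[ls$item == 7, ]
  expect_equal(sort(paste(item7$set_size, item7$distance)),
               sort(c("small short", "small long", "large short", "large long")))
})

test_that("cloze generation tracks the concentration parameter", {
  # near-zero concentration: one dominant particle, entropy near zero
  low <- generate_cloze_responses(n_items = 6, n_respondents = 40,
                                  concentration = 0.02, p_nonparticle = 0,
                                  target_nonmodal_rate = 0, ensure_pass = FALSE,
                                  seed = 5)
  h_low <- vapply(low$responses, function(rs) {
    compute_cloze_statistics(rs, low$targets[[rs$item_id]])$entropy_H
  }, 0)
  expect_lt(mean(h_low), 0.5)

  # symmetric concentration, many respondents: entropy approaches log2 k
  high <- generate_cloze_responses(n_items = 4, n_respondents = 800,
                                   small_inventory = 4, concentration = 1e4,
                                   p_nonparticle = 0, target_nonmodal_rate = 0,
                                   ensure_pass = FALSE, seed = 6)
  small_sets <- Filter(function(rs) rs$set_size == "small", high$responses)
  h_high <- vapply(small_sets, function(rs) {
    compute_cloze_statistics(rs, high$targets[[rs$item_id]])$entropy_H
  }, 0)
  expect_lt(max(abs(h_high - 2)), 0.1)
})

test_that("planted failures are recovered exactly by item selection", {
  gen <- generate_cloze_responses(n_items = 48, fail_items = 1:24, seed = 9)
  stats <- lapply(gen$responses, function(rs) {
    compute_cloze_statistics(rs, gen$targets[[rs$item_id]])
  })
  res <- select_items(cloze_stats_table(stats))
  expect_equal(sum(res$retained), 24L)
  expect_setequal(res$item_id[res$retained], sprintf("item%02d", 25:48))
})

test_that("inventory sizes outside the category bounds are rejected", {
  expect_error(generate_cloze_responses(small_inventory = 6), "fewer than six")
  expect_error(generate_cloze_responses(large_inventory = 10), "more than ten")
})

test_that("self-paced reading times follow the reciprocal model", {
  des <- experiment_design(8, 8, n_fillers = 0, seed = 1)
  # noise-free limit: every reading time is 1000/intercept
  p0 <- generative_params("reciprocal_speed", intercept = 2.5, sigma = 1e-9,
                          sd_participant = rep(0, 4), sd_item = rep(0, 4))
  spr0 <- generate_spr_trials(des, p0, p_sub100 = 0, seed = 2)
  expect_equal(spr0$rt_ms, rep(400, nrow(spr0)), tolerance = 1e-5)

  # closed-form cell means under a pure set-size effect
  p1 <- generative_params("reciprocal_speed", intercept = 2.5,
                          beta = c(set_size = 0.07), sigma = 1e-9,
                          sd_participant = rep(0, 4), sd_item = rep(0, 4))
  spr1 <- generate_spr_trials(des, p1, p_sub100 = 0, seed = 3)
  expect_equal(mean(spr1$rt_ms[spr1$set_size == "small"]), 1000 / 2.465,
               tolerance = 1e-6)
  expect_equal(mean(spr1$rt_ms[spr1$set_size == "large"]), 1000 / 2.535,
               tolerance = 1e-6)
})

test_that("study-scale simulation is centred on the generating intercept", {
  des <- experiment_design(60, 24, seed = 4)
  spr <- generate_spr_trials(des, generative_params("reciprocal_speed"),
                             p_sub100 = 0, seed = 8)
  speed <- 1000 / spr$rt_ms
  se <- sd(speed) / sqrt(length(speed))
  # crossed random effects leave the grand mean unbiased; allow for the
  # between-cluster variance not captured by the naive standard error
  expect_lt(abs(mean(speed) - 2.5), max(3 * se, 0.2))
  # comprehension accuracy near the configured rate
  expect_lt(abs(mean(spr$question_correct) - 0.93),
            3 * sqrt(0.93 * 0.07 / nrow(spr)) + 0.01)
})

test_that("sub-100 ms contamination is injected at the configured rate", {
  des <- experiment_design(20, 12, n_fillers = 0, seed = 1)
  spr <- generate_spr_trials(des, generative_params("reciprocal_speed"),
                             p_sub100 = 0.05, seed = 5)
  expect_equal(sum(spr$rt_ms < 100), round(0.05 * nrow(spr)))
})

test_that("eye-tracking measures collapse when no extra events occur", {
  des <- experiment_design(6, 8, n_fillers = 0, seed = 1)
  et <- generate_et_trials(des, generative_params("log_ms"),
                           p_refix = 0, p_reread = 0, p_regress = 0,
                           p_skip = 0, blink_rate = 0, seed = 2)
  expect_equal(et$fprt_ms, et$ffd_ms)
  expect_equal(et$tft_ms, et$ffd_ms)
  expect_equal(et$rpd_ms, et$ffd_ms)
})

test_that("first fixation durations are lognormal around the intercept", {
  des <- experiment_design(60, 24, seed = 3)
  et <- generate_et_trials(des, generative_params("log_ms"), p_skip = 0,
                           blink_rate = 0, seed = 7)
  expect_lt(abs(median(et$ffd_ms) - exp(5.7)), 12)
  # containment by construction
  ok <- !et$skipped_first_pass
  expect_true(all(et$ffd_ms[ok] <= et$fprt_ms[ok]))
  expect_true(all(et$fprt_ms[ok] <= et$tft_ms[ok]))
  expect_true(all(et$fprt_ms[ok] <= et$rpd_ms[ok]))
})

test_that("emitted fixation sequences reproduce the emitted measures exactly", {
  des <- experiment_design(12, 8, n_fillers = 0, seed = 2)
  et <- generate_et_trials(des, generative_params("log_ms"),
                           emit_fixations = TRUE, seed = 9)
  seqs <- attr(et, "fixations")
  expect_length(seqs, nrow(et))
  m <- region_measures_table(seqs, c(5, 6))
  expect_equal(m$ffd_ms, et$ffd_ms)
  expect_equal(m$fprt_ms, et$fprt_ms)
  expect_equal(m$tft_ms, et$tft_ms)
  expect_equal(m$rpd_ms, et$rpd_ms)
  expect_equal(m$skipped_first_pass, et$skipped_first_pass)
  # blink flags are carried over
  expect_equal(vapply(seqs, function(s) s$blink_or_trackloss, TRUE),
               et$blink_or_trackloss, ignore_attr = TRUE)
})

test_that("entropy distributions overlap across set-size categories", {
  des <- experiment_design(4, 24, seed = 5)
  spr <- generate_spr_trials(des, generative_params("reciprocal_speed"),
                             seed = 11)
  by_item <- unique(spr[, c("item", "set_size", "entropy")])
  small <- by_item$entropy[by_item$set_size == "small"]
  large <- by_item$entropy[by_item$set_size == "large"]
  expect_gt(mean(large), mean(small))
  # overlapping supports: both categories contain high and low entropy
  expect_gt(max(small), min(large))
  expect_true(all(c(small, large) >= 0))
})

test_that("generator parameters are validated", {
  expect_error(generative_params(sigma = -1), "positive")
  expect_error(generative_params(accuracy = 1.2), "accuracy")
  bad_corr <- matrix(c(1, 2, 2, 1), 2)
  expect_error(generative_params(corr_participant = diag(4) * 0 - 1),
               "positive-definite")
  des <- experiment_design(4, 8, seed = 1)
  expect_error(generate_spr_trials(des, generative_params("log_ms")),
               "reciprocal_speed")
  expect_error(generate_et_trials(des, generative_params("reciprocal_speed")),
               "log_ms")
  expect_error(generate_et_trials(des, generative_params("log_ms"),
                                  p_refix = 1.5), "probabilities")
})
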