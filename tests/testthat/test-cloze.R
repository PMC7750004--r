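test_that("cloze probabilities and entropy match hand computation", {
  rs <- make_cloze_rs(c(vor = 9, an = 1))
  st <- compute_cloze_statistics(rs, target = "vor")
  expect_equal(st$target_cloze, 0.9)
  expect_equal(round(st$entropy_H, 2), 0.47)
  expect_equal(sum(st$probabilities), 1, tolerance = 1e-9)

  one <- compute_cloze_statistics(make_cloze_rs(c(vor = 10)), "vor")
  expect_equal(one$entropy_H, 0)
  expect_equal(one$target_cloze, 1)

  unif <- compute_cloze_statistics(
    make_cloze_rs(c(a = 5, b = 5, c = 5, d = 5)), "a")
  expect_equal(unif$entropy_H, 2)
})

test_that("the probability universe respects the particle flag", {
  rs <- make_cloze_rs(c(vor = 6, an = 2, und = 2),
                      particles = c(TRUE, TRUE, FALSE))
  st <- compute_cloze_statistics(rs, "vor", particle_only = TRUE)
  expect_equal(st$target_cloze, 6 / 8)
  st_all <- compute_cloze_statistics(rs, "vor", particle_only = FALSE)
  expect_equal(st_all$target_cloze, 0.6)
  # an unknown target has zero cloze
  expect_equal(compute_cloze_statistics(rs, "zu")$target_cloze, 0)
})

test_that("invalid response sets are rejected", {
  expect_error(cloze_response_set("i", "small", "short",
                                  integer(0), logical(0)),
               "no cloze data")
  expect_error(make_cloze_rs(c(vor = 0, an = 3)), ">= 1")
  expect_error(cloze_response_set("i", "small", "short", c(vor = 9),
                                  c(vor = TRUE), n_respondents = 5),
               "exceed")
})

test_that("entropy is label-invariant and merging types never increases it", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    counts <- stats::setNames(sample(1:9, k, replace = TRUE),
                              paste0("c", seq_len(k)))
    h <- compute_cloze_statistics(make_cloze_rs(counts), "c1")$entropy_H
    # permuted labels
    perm <- sample(k)
    counts_p <- stats::setNames(counts[perm], names(counts))
    h_p <- compute_cloze_statistics(make_cloze_rs(counts_p), "c1")$entropy_H
    expect_equal(h, h_p)
    # merge two random types (coarsening)
    ij <- sample(k, 2)
    merged <- counts
    merged[ij[1]] <- merged[ij[1]] + merged[ij[2]]
    merged <- merged[-ij[2]]
    h_m <- compute_cloze_statistics(make_cloze_rs(merged), "c1")$entropy_H
    expect_lte(h_m, h + 1e-12)
    # modal cloze is at least 1/k
    st <- compute_cloze_statistics(make_cloze_rs(counts), "c1")
    expect_gte(max(st$probabilities), 1 / st$n_particle_types)
  }
})

test_that("condition summaries use a method-of-moments Beta fit", {
  # two values with sample mean 0.5 and sample variance 0.05
  a <- sqrt(0.025)
  stats_df <- data.frame(
    item_id = c("i1", "i2"), set_size = "small", distance = "short",
    target_particle = "p", target_cloze = c(0.5 - a, 0.5 + a),
    entropy_H = c(1, 1.4), n_particle_types = 3)
  s <- summarize_condition(stats_df, "set_size", "small", seed = 1)
  shapes <- attr(s, "beta_shapes")
  expect_equal(unname(shapes), c(2, 2), tolerance = 1e-9)
  expect_equal(s$mean[s$statistic == "cloze"], 0.5)
  ci <- s[s$statistic == "cloze", ]
  expect_equal(unname(ci$ci_low), qbeta(0.025, 2, 2))
  expect_equal(unname(ci$ci_high), qbeta(0.975, 2, 2))

  # degenerate: identical values collapse both CIs, one warning each
  stats_df$target_cloze <- c(0.5, 0.5)
  stats_df$entropy_H <- c(1, 1)
  w <- capture_warnings(sd <- summarize_condition(stats_df, "set_size", "small"))
  expect_length(w, 2)
  expect_match(w, "degenerate", all = TRUE)
  expect_equal(sd$ci_low, sd$mean)
  expect_equal(sd$ci_high, sd$mean)
})

test_that("Beta fit recovers the generating distribution", {
  set.seed(42)
  vals <- rbeta(200, 2, 2)
  stats_df <- data.frame(
    item_id = paste0("i", 1:200), set_size = "large", distance = "short",
    target_particle = "p", target_cloze = vals,
    entropy_H = runif(200, 0.5, 2), n_particle_types = 3)
  s <- summarize_condition(stats_df, "set_size", "large", seed = 2)
  expect_lt(abs(s$mean[s$statistic == "cloze"] - 0.5), 0.05)
  # method-of-moments round trip at large n
  shapes <- attr(s, "beta_shapes")
  expect_lt(abs(shapes[["shape1"]] - 2), 0.5)
  expect_lt(abs(shapes[["shape2"]] - 2), 0.5)
})

test_that("median split is deterministic with ties to low", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_warning(all_low <- median_split(c(1, 1, 1)), "tied")
  expect_true(all(all_low == "low"))
  set.seed(3)
  v24 <- sample(seq(0.1, 2.4, by = 0.1))
  expect_equal(as.integer(table(median_split(v24))), c(12L, 12L))
  expect_error(median_split(1), "at least 2")
})

test_that("item selection applies both norming rules with reasons", {
  stats <- rbind(
    make_item_stats("keep", c(2, 2, 4, 4)),
    make_item_stats("noparticle", c(0, 2, 4, 4)),
    make_item_stats("nocontrast", c(3, 2, 3, 4)))
  res <- select_items(stats)
  expect_true(res$retained[res$item_id == "keep"])
  expect_false(res$retained[res$item_id == "noparticle"])
  expect_match(res$reason[res$item_id == "noparticle"], "no particle")
  expect_false(res$retained[res$item_id == "nocontrast"])
  # missing condition is skipped with a logged reason
  partial <- make_item_stats("partial", c(2, 2, 4, 4))[-1, ]
  res2 <- select_items(rbind(stats, partial))
  expect_match(res2$reason[res2$item_id == "partial"], "missing")
})

test_that("cloze tables round-trip through CSV with normalization", {
  d <- data.frame(
    item = "i1", set_size = "small", distance = "short",
    respondent = 1:4,
    completion = c(" Vor", "vor ", "AN", "an und"),
    is_particle = c(TRUE, TRUE, TRUE, FALSE))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE, fileEncoding = "UTF-8")
  rs <- read_cloze_responses(f)
  expect_length(rs, 1)
  expect_equal(sort(names(rs[[1]]$completions)), c("an", "vor"))
  expect_equal(unname(rs[[1]]$completions[["vor"]]), 2L)
  # "an und" normalizes to "an" and keeps respondent 3's particle flag
  expect_equal(unname(rs[[1]]$completions[["an"]]), 2L)
  expect_equal(rs[[1]]$n_respondents, 4L)
  unlink(f)
})
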