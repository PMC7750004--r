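#' Experiment design description
#'
#' Describes a 2x2 (set size x distance) reading experiment with a
#' Latin-square assignment of items to conditions across four lists.
#' Defaults mirror a typical well-powered reading study of this kind:
#' 60 participants, 24 items (6 trials per condition per participant),
#' 72 fillers.
#'
#' @param n_participants number of participants.
#' @param n_items number of experimental items; must be divisible by 4.
#' @param n_fillers number of filler trials per participant.
#' @param seed seed used for filler interleaving and downstream
#'   generation.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(n_participants = 60, n_items = 24,
                              n_fillers = 72, seed = 1L) {
  assert_that(n_items %% 4 == 0, "n_items must be divisible by the 4 conditions")
  assert_that(n_participants >= 1, "need at least one participant")
  structure(list(n_participants = n_participants, n_items = n_items,
                 n_conditions = 4L, n_lists = 4L, n_fillers = n_fillers,
                 conditions = data.frame(
                   condition = 1:4,
                   set_size = c("small", "small", "large", "large"),
                   distance = c("short", "long", "short", "long"),
                   stringsAsFactors = FALSE),
                 seed = seed),
            class = "experiment_design")
}

#' Latin-square assignment of items to conditions
#'
#' Builds the four presentation lists by rotating conditions over
#' items, assigns participants to lists round-robin, and interleaves
#' filler positions at random under the design seed. Every participant
#' sees each item exactly once, each item appears in all four
#' conditions across lists, and each participant sees `n_items / 4`
#' trials per condition.
#'
#' @param design an [experiment_design()].
#' @return data frame with one row per participant x item: columns
#'   `participant`, `item`, `list`, `set_size`, `distance`,
#'   `presentation_order` (position among targets + fillers).
#' @export
build_latin_square <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  with_seed(design$seed, {
    rows <- lapply(seq_len(design$n_participants), function(p) {
      lst <- ((p - 1L) %% design$n_lists) + 1L
      item <- seq_len(design$n_items)
      cond <- ((item - 1L + lst - 1L) %% 4L) + 1L
      slots <- sort(sample.int(design$n_items + design$n_fillers,
                               design$n_items))
      data.frame(participant = p, item = item, list = lst,
                 condition = cond, presentation_order = slots)
    })
    out <- do.call(rbind, rows)
  })
  out <- merge(out, cbind(design$conditions), by = "condition", sort = FALSE)
  out <- out[order(out$participant, out$item),
             c("participant", "item", "list", "set_size", "distance",
               "presentation_order")]
  rownames(out) <- NULL
  out
}

# symmetric Dirichlet draw
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Generate synthetic cloze-test responses
#'
#' Simulates a cloze norming study: per item and condition, respondents
#' produce completions drawn from a multinomial over the verb's particle
#' inventory with Dirichlet-distributed probabilities. The symmetric
#' Dirichlet `concentration` tunes entropy (small values give one
#' dominant particle, hence low entropy; large values approach a
#' uniform distribution with entropy `log2(k)`). Small-set inventories
#' must contain fewer than six particles and large-set inventories more
#' than ten. Optionally a fraction of completions are non-particles, a
#' fraction of items get a designated target that is not the modal
#' particle, and a planted subset of items is forced to fail item
#' selection (one condition elicits no particle).
#'
#' @param n_items number of items (each with all four conditions).
#' @param n_respondents respondents per item x condition.
#' @param small_inventory,large_inventory particle-inventory sizes for
#'   the small and large set conditions; the small inventory is a
#'   subset of the large one.
#' @param concentration symmetric Dirichlet concentration.
#' @param p_nonparticle probability that a completion is a
#'   non-particle.
#' @param target_nonmodal_rate fraction of items whose designated
#'   target is not the modal particle.
#' @param fail_items item indices forced to fail [select_items()].
#' @param ensure_pass resample (up to 200 tries) so that items not in
#'   `fail_items` satisfy the selection rules.
#' @param seed RNG seed.
#' @return list with `responses` (list of [cloze_response_set()]),
#'   `targets` (named character vector item -> target particle).
#' @export
generate_cloze_responses <- function(n_items = 48, n_respondents = 31,
                                     small_inventory = 4, large_inventory = 14,
                                     concentration = 1,
                                     p_nonparticle = 0.05,
                                     target_nonmodal_rate = 0.08,
                                     fail_items = NULL,
                                     ensure_pass = TRUE,
                                     seed = 1L) {
  assert_that(small_inventory < 6,
              "small-set inventory must contain fewer than six particles")
  assert_that(large_inventory > 10,
              "large-set inventory must contain more than ten particles")
  assert_that(p_nonparticle >= 0 && p_nonparticle < 1,
              "p_nonparticle must be in [0, 1)")
  particles <- paste0("p", seq_len(large_inventory))
  with_seed(seed, {
    responses <- list()
    targets <- character(n_items)
    for (it in seq_len(n_items)) {
      item_id <- sprintf("item%02d", it)
      force_fail <- it %in% fail_items
      # the condition whose particles are suppressed for planted failures
      fail_cell <- if (force_fail) sample.int(4, 1) else 0L
      ok <- FALSE
      for (try in seq_len(if (ensure_pass) 200L else 1L)) {
        sets <- list()
        cell_idx <- 0L
        for (ss in c("small", "large")) {
          k <- if (ss == "small") small_inventory else large_inventory
          inv <- particles[seq_len(k)]
          for (dist in c("short", "long")) {
            cell_idx <- cell_idx + 1L
            probs <- rdirichlet1(rep(concentration, k))
            draws <- inv[sample.int(k, n_respondents, replace = TRUE, prob = probs)]
            is_np <- stats::runif(n_respondents) < p_nonparticle
            if (cell_idx == fail_cell) is_np[] <- TRUE
            words <- ifelse(is_np, paste0("word", sample.int(20, n_respondents,
                                                             replace = TRUE)),
                            draws)
            counts <- table(words)
            flags <- !grepl("^word", names(counts))
            names(flags) <- names(counts)
            sets[[paste(ss, dist)]] <- cloze_response_set(
              item_id, ss, dist,
              stats::setNames(as.integer(counts), names(counts)),
              flags, n_respondents = n_respondents)
          }
        }
        n_types <- vapply(sets, function(s) sum(s$is_particle), 0)
        has_particle <- n_types >= 1
        contrast <- n_types[["large short"]] > n_types[["small short"]] &&
          n_types[["large long"]] > n_types[["small long"]]
        ok <- all(has_particle) && contrast
        if (force_fail || ok || !ensure_pass) break
      }
      # designated target: modal particle of the small/short cell unless
      # the item is one where target matching across conditions forced a
      # non-modal choice
      small_short <- sets[["small short"]]
      pc <- small_short$completions[small_short$is_particle]
      if (length(pc) == 0L) pc <- stats::setNames(1L, particles[1])
      ord <- names(sort(pc, decreasing = TRUE))
      nonmodal <- stats::runif(1) < target_nonmodal_rate && length(ord) > 1
      targets[it] <- if (nonmodal) ord[2] else ord[1]
      names(targets)[it] <- item_id
      responses <- c(responses, sets)
    }
    list(responses = responses, targets = targets)
  })
}

#' Parameters of the reading-time generators
#'
#' Fixed effects are expressed on the model scale (`reciprocal_speed`:
#' words/second, as in self-paced reading analyses with a 1000/rt
#' transform; `log_ms`: log milliseconds, as in eye-tracking analyses).
#' Random effects for participants and items cover the intercept and
#' all three slopes with a full covariance matrix. Per-item entropy is
#' drawn from two overlapping truncated-normal components so that both
#' set-size categories contain high- and low-entropy items while the
#' large-set mean is higher.
#'
#' @param scale `"reciprocal_speed"` or `"log_ms"`.
#' @param intercept fixed intercept on the model scale (default 2.5
#'   words/s or 5.7 log ms).
#' @param beta named numeric: effects `set_size`, `distance`,
#'   `interaction`, and `entropy` (per bit, applied on top of the
#'   categorical structure; default all 0).
#' @param sd_participant,sd_item random-effect SDs (length 4:
#'   intercept and the three slopes).
#' @param corr_participant,corr_item 4x4 random-effect correlation
#'   matrices.
#' @param sigma residual SD on the model scale.
#' @param accuracy comprehension-question accuracy in [0, 1].
#' @param entropy_mean named numeric `c(small = , large = )`: mean
#'   entropy (bits) per set-size category.
#' @param entropy_sd SD of the per-item entropy distribution.
#' @return object of class `generative_params`.
#' @export
generative_params <- function(scale = c("reciprocal_speed", "log_ms"),
                              intercept = NULL,
                              beta = c(set_size = 0, distance = 0,
                                       interaction = 0, entropy = 0),
                              sd_participant = NULL, sd_item = NULL,
                              corr_participant = diag(4), corr_item = diag(4),
                              sigma = NULL,
                              accuracy = 0.93,
                              entropy_mean = c(small = 1.10, large = 1.20),
                              entropy_sd = 0.40) {
  scale <- match.arg(scale)
  defaults <- if (scale == "reciprocal_speed") {
    list(intercept = 2.5, sigma = 0.5,
         sd_participant = c(0.30, 0.10, 0.10, 0.10),
         sd_item = c(0.12, 0.05, 0.05, 0.05))
  } else {
    list(intercept = 5.7, sigma = 0.35,
         sd_participant = c(0.20, 0.05, 0.05, 0.05),
         sd_item = c(0.08, 0.03, 0.03, 0.03))
  }
  intercept <- intercept %||% defaults$intercept
  sigma <- sigma %||% defaults$sigma
  sd_participant <- sd_participant %||% defaults$sd_participant
  sd_item <- sd_item %||% defaults$sd_item
  b <- c(set_size = 0, distance = 0, interaction = 0, entropy = 0)
  b[names(beta)] <- beta
  assert_that(sigma > 0, "residual SD must be positive")
  assert_that(all(sd_participant >= 0) && all(sd_item >= 0),
              "random-effect SDs must be non-negative")
  assert_that(accuracy >= 0 && accuracy <= 1, "accuracy must be in [0, 1]")
  for (R in list(corr_participant, corr_item)) {
    assert_that(all(eigen(R, only.values = TRUE)$values > 0),
                "correlation matrices must be positive-definite")
  }
  structure(list(scale = scale, intercept = intercept, beta = b,
                 sd_participant = sd_participant, sd_item = sd_item,
                 corr_participant = corr_participant, corr_item = corr_item,
                 sigma = sigma, accuracy = accuracy,
                 entropy_mean = entropy_mean, entropy_sd = entropy_sd),
            class = "generative_params")
}

# per item x set_size entropy values: truncated-normal components that
# overlap across categories
draw_item_entropy <- function(n_items, params) {
  draw <- function(m) {
    x <- stats::rnorm(n_items, m, params$entropy_sd)
    while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), m, params$entropy_sd)
    x
  }
  data.frame(item = rep(seq_len(n_items), 2),
             set_size = rep(c("small", "large"), each = n_items),
             entropy = c(draw(params$entropy_mean[["small"]]),
                         draw(params$entropy_mean[["large"]])),
             stringsAsFactors = FALSE)
}

# shared linear predictor on the model scale for one assignment table
linear_predictor <- function(assign, params) {
  c_ss <- ifelse(assign$set_size == "large", 0.5, -0.5)
  c_dist <- ifelse(assign$distance == "long", 0.5, -0.5)
  ent_c <- assign$entropy - mean(assign$entropy)
  X <- cbind(1, c_ss, c_dist, c_ss * c_dist)
  np <- max(assign$participant)
  ni <- max(assign$item)
  Sig_p <- diag(params$sd_participant) %*% params$corr_participant %*%
    diag(params$sd_participant)
  Sig_i <- diag(params$sd_item) %*% params$corr_item %*% diag(params$sd_item)
  u_p <- MASS::mvrnorm(np, rep(0, 4), Sig_p)
  u_i <- MASS::mvrnorm(ni, rep(0, 4), Sig_i)
  beta <- c(params$intercept, params$beta[["set_size"]],
            params$beta[["distance"]], params$beta[["interaction"]])
  drop(X %*% beta) +
    rowSums(X * u_p[assign$participant, , drop = FALSE]) +
    rowSums(X * u_i[assign$item, , drop = FALSE]) +
    params$beta[["entropy"]] * ent_c
}

attach_entropy <- function(assign, params) {
  ent <- draw_item_entropy(max(assign$item), params)
  merge(assign, ent, by = c("item", "set_size"), sort = FALSE)
}

question_columns <- function(n, accuracy) {
  data.frame(question_correct = stats::runif(n) < accuracy,
             question_rt_ms = stats::rlnorm(n, log(2000), 0.25))
}

#' Generate synthetic self-paced reading trials
#'
#' Draws reading speed at the particle on the words/second scale from
#' the hierarchical linear model implied by `params` (fixed effects +
#' crossed participant/item random effects + Gaussian residual), then
#' maps it to a reading time `rt_ms = 1000 / speed`. Draws with speed
#' <= 0.1 words/s are resampled as a guard against non-positive or
#' absurd reading times. A configured proportion of trials is replaced
#' by uniform 30-99 ms values so that the sub-100-ms exclusion rule has
#' something to exclude. Comprehension accuracy is Bernoulli.
#'
#' @param design an [experiment_design()].
#' @param params a [generative_params()] with
#'   `scale = "reciprocal_speed"`.
#' @param p_sub100 proportion of trials contaminated with sub-100 ms
#'   reading times.
#' @param seed RNG seed (defaults to the design seed).
#' @return data frame of trials: `participant`, `item`, `set_size`,
#'   `distance`, `entropy`, `rt_ms`, `question_correct`,
#'   `question_rt_ms`.
#' @export
generate_spr_trials <- function(design, params = generative_params(),
                                p_sub100 = 0.01, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "generative_params"))
  assert_that(params$scale == "reciprocal_speed",
              "self-paced generator needs params on the reciprocal_speed scale")
  seed <- seed %||% design$seed
  with_seed(seed, {
    assign <- build_latin_square(design)
    assign <- attach_entropy(assign, params)
    mu <- linear_predictor(assign, params)
    speed <- mu + stats::rnorm(nrow(assign), 0, params$sigma)
    bad <- speed <= 0.1
    while (any(bad)) {
      speed[bad] <- mu[bad] + stats::rnorm(sum(bad), 0, params$sigma)
      bad <- speed <= 0.1
    }
    rt <- 1000 / speed
    n_sub <- round(p_sub100 * length(rt))
    if (n_sub > 0) {
      idx <- sample.int(length(rt), n_sub)
      rt[idx] <- stats::runif(n_sub, 30, 99)
    }
    out <- cbind(assign[, c("participant", "item", "set_size", "distance",
                            "entropy")],
                 rt_ms = rt,
                 question_columns(nrow(assign), params$accuracy))
    attr(out, "seed") <- seed
    out
  })
}

#' Generate synthetic eye-tracking trials
#'
#' First fixation duration is lognormal: its log is drawn from the
#' hierarchical model implied by `params`. The remaining measures are
#' built compositionally so the containment relations hold by
#' construction: FPRT adds a refixation with probability `p_refix`,
#' TFT adds re-reading time with probability `p_reread`, and RPD adds
#' regression time with probability `p_regress`. A fraction `p_skip`
#' of trials skip the target region in first pass (FFD/FPRT/RPD
#' missing, TFT from a late fixation only), and `blink_rate` of trials
#' are flagged for exclusion. With `emit_fixations = TRUE` the
#' generator also returns fixation sequences that reproduce these
#' measures exactly when fed to [compute_region_measures()] over the
#' merged span `c(target_region - 1, target_region)`.
#'
#' @param design an [experiment_design()].
#' @param params a [generative_params()] with `scale = "log_ms"`.
#' @param p_refix,p_reread,p_regress,p_skip event probabilities.
#' @param blink_rate fraction of trials flagged blink/track loss.
#' @param target_region index of the particle region (the analysis
#'   span merges it with the preceding word).
#' @param n_regions number of word regions in the sentence.
#' @param emit_fixations also build full fixation sequences?
#' @param seed RNG seed (defaults to the design seed).
#' @return data frame of trials with the four measures (NA where the
#'   region was skipped in first pass), `blink_or_trackloss`, question
#'   data, plus attributes `fixations` (list of [fixation_sequence()],
#'   when requested) and `seed`.
#' @export
generate_et_trials <- function(design, params = generative_params("log_ms"),
                               p_refix = 0.3, p_reread = 0.25,
                               p_regress = 0.2, p_skip = 0.1,
                               blink_rate = 0.05,
                               target_region = 6L, n_regions = 8L,
                               emit_fixations = FALSE, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "generative_params"))
  assert_that(params$scale == "log_ms",
              "eye-tracking generator needs params on the log_ms scale")
  for (p in c(p_refix, p_reread, p_regress, p_skip, blink_rate)) {
    assert_that(p >= 0 && p <= 1, "event probabilities must be in [0, 1]")
  }
  assert_that(target_region >= 2 && target_region < n_regions,
              "target_region must leave room for the preceding word and an exit region")
  seed <- seed %||% design$seed
  with_seed(seed, {
    assign <- build_latin_square(design)
    assign <- attach_entropy(assign, params)
    n <- nrow(assign)
    log_ffd <- linear_predictor(assign, params) +
      stats::rnorm(n, 0, params$sigma)
    ffd <- exp(log_ffd)
    refix <- stats::runif(n) < p_refix
    reread <- stats::runif(n) < p_reread
    regress <- stats::runif(n) < p_regress
    skip <- stats::runif(n) < p_skip
    extra_fp <- ifelse(refix, stats::rlnorm(n, log(150), 0.4), 0)
    extra_rr <- ifelse(reread, stats::rlnorm(n, log(250), 0.4), 0)
    extra_rg <- ifelse(regress, stats::rlnorm(n, log(200), 0.4), 0)
    fprt <- ffd + extra_fp
    tft <- fprt + extra_rr
    rpd <- fprt + extra_rg

    out <- cbind(assign[, c("participant", "item", "set_size", "distance",
                            "entropy")],
                 ffd_ms = ffd, fprt_ms = fprt, tft_ms = tft, rpd_ms = rpd,
                 skipped_first_pass = skip,
                 blink_or_trackloss = stats::runif(n) < blink_rate,
                 question_columns(n, params$accuracy))
    # a skipped region contributes only late reading time
    late_only <- exp(stats::rnorm(sum(skip), params$intercept, params$sigma))
    out$ffd_ms[skip] <- NA
    out$fprt_ms[skip] <- NA
    out$rpd_ms[skip] <- NA
    out$tft_ms[skip] <- late_only

    if (emit_fixations) {
      attr(out, "fixations") <- build_fixation_sequences(
        out, ffd, extra_fp, extra_rg, target_region, n_regions)
    }
    attr(out, "seed") <- seed
    out
  })
}

# Construct fixation sequences whose derived measures equal the
# generated ones exactly. The merged target span is
# {target_region - 1, target_region}.
build_fixation_sequences <- function(trials, ffd, extra_fp, extra_rg,
                                     target_region, n_regions) {
  pre <- seq_len(target_region - 2L)
  exit1 <- target_region + 1L
  lapply(seq_len(nrow(trials)), function(i) {
    trial_id <- sprintf("p%02d_i%02d", trials$participant[i], trials$item[i])
    walk_reg <- pre
    walk_dur <- stats::runif(length(pre), 150, 280)
    if (trials$skipped_first_pass[i]) {
      # first pass jumps over the target span, a single late revisit
      # carries the total fixation time
      regs <- c(walk_reg, exit1, target_region, n_regions)
      durs <- c(walk_dur, stats::runif(1, 150, 280), trials$tft_ms[i],
                stats::runif(1, 150, 280))
    } else {
      regs <- c(walk_reg, target_region - 1L)
      durs <- c(walk_dur, ffd[i])
      if (extra_fp[i] > 0) {
        regs <- c(regs, target_region)
        durs <- c(durs, extra_fp[i])
      }
      if (extra_rg[i] > 0) {
        regs <- c(regs, max(1L, target_region - 2L))
        durs <- c(durs, extra_rg[i])
      }
      regs <- c(regs, exit1)
      durs <- c(durs, stats::runif(1, 150, 280))
      rr <- trials$tft_ms[i] - trials$fprt_ms[i]
      if (rr > 0) {
        regs <- c(regs, target_region, n_regions)
        durs <- c(durs, rr, stats::runif(1, 150, 280))
      }
    }
    fixation_sequence(trial_id, regs, durs,
                      blink_or_trackloss = trials$blink_or_trackloss[i])
  })
}
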