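# End-to-end orchestration: simulate -> cloze statistics -> decay
# predictions -> reading measures -> hierarchical fits -> Bayes
# factors -> report tables.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with the study-scale defaults:
#' a 60-participant, 24-item 2x2 Latin-square reading experiment with
#' 72 fillers; a 48-item cloze norming study with 31 respondents per
#' condition and 63 fillers; the decay simulator defaults; and the
#' model/prior settings of both analysis scales. Every stochastic stage
#' derives its own seed from the master seed.
#'
#' @param seed master seed.
#' @return nested configuration list (class `pipeline_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    design = list(n_participants = 60L, n_items = 24L, n_fillers = 72L),
    cloze = list(n_items = 48L, n_respondents = 31L, n_fillers = 63L,
                 small_inventory = 4L, large_inventory = 14L,
                 concentration = 1, p_nonparticle = 0.05,
                 target_nonmodal_rate = 0.08),
    decay = list(pool = 1, decay_rate = 0.5, latency_factor = 200,
                 t0 = 0.4, k_word = 0.4, words_short = 5L, words_long = 7L,
                 n_small = 4L, n_large = 14L),
    spr = list(intercept = 2.5, set_size = 0, distance = 0, interaction = 0,
               entropy = 0, sigma = 0.5, accuracy = 0.93, p_sub100 = 0.01),
    et = list(intercept = 5.7, set_size = 0, distance = 0, interaction = 0,
              entropy = 0, sigma = 0.35, accuracy = 0.93, blink_rate = 0.05,
              p_refix = 0.3, p_reread = 0.25, p_regress = 0.2, p_skip = 0.1),
    exclusion = list(rt_min = 100),
    fit = list(enabled = TRUE, predictors = "categorical",
               et_measures = c("ffd", "fprt", "tft", "rpd"),
               chains = 4L, warmup = 1000L, iter = 1000L),
    bayes_factors = list(enabled = FALSE,
                         widths = list(informative = 0.1, planned = 0.5,
                                       diffuse = 1.0))
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips: writing and re-reading yields an
#' identical configuration.
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return `read_config` returns the configuration; `write_config`
#'   returns the path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), raw)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# bootstrap CI over by-participant condition means
condition_summary <- function(trials, value_col, group_cols, n_boot = 2000,
                              seed = 1L) {
  vals <- trials[[value_col]]
  keep <- !is.na(vals)
  trials <- trials[keep, ]
  vals <- vals[keep]
  key <- interaction(trials[group_cols], drop = TRUE, sep = "|")
  with_seed(seed, {
    out <- lapply(levels(key), function(lev) {
      sub <- trials[key == lev, ]
      pm <- tapply(vals[key == lev], sub$participant, mean)
      boots <- replicate(n_boot, mean(sample(pm, replace = TRUE)))
      parts <- strsplit(lev, "|", fixed = TRUE)[[1]]
      row <- stats::setNames(as.list(parts), group_cols)
      row$mean <- mean(pm)
      row$ci_low <- stats::quantile(boots, 0.025, names = FALSE)
      row$ci_high <- stats::quantile(boots, 0.975, names = FALSE)
      as.data.frame(row, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

fit_summary_row <- function(fit, label) {
  s <- fit$summary[grepl("^b_|^sigma$", fit$summary$parameter), ]
  s$model <- label
  s[, c("model", "parameter", "mean", "ci_low", "ci_high", "rhat", "ess")]
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage in order on data generated under the
#' configuration: cloze norming simulation and statistics (with item
#' selection and Beta/bootstrap condition summaries), decay-simulator
#' predictions, self-paced reading simulation with the sub-100-ms
#' exclusion and condition summaries, eye-tracking simulation with
#' blink exclusion and the four reading measures, hierarchical model
#' fits, and (optionally) the Bayes-factor table. Identical
#' configuration and seed reproduce identical tables.
#'
#' @param config a configuration list from [default_config()] or
#'   [read_config()] (or a path to a YAML file).
#' @param output_dir optional directory; when given, all tables are
#'   written there as CSV via [write_report()].
#' @return object of class `report_tables`: a named list of data
#'   frames (`cloze_summary`, `item_selection`, `decay_predictions`,
#'   `spr_condition_summary`, `spr_entropy_split`, `accuracy_summary`,
#'   `et_condition_summary`, `posteriors`, `bf_table`,
#'   `exclusion_log`), plus the configuration.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  stage_seed <- function(stage) derive_seed(cfg$seed, stage)
  tables <- list()
  exclusions <- list()

  # ---- cloze stage --------------------------------------------------------
  cl <- cfg$cloze
  gen <- generate_cloze_responses(
    n_items = cl$n_items, n_respondents = cl$n_respondents,
    small_inventory = cl$small_inventory, large_inventory = cl$large_inventory,
    concentration = cl$concentration, p_nonparticle = cl$p_nonparticle,
    target_nonmodal_rate = cl$target_nonmodal_rate,
    seed = stage_seed("cloze"))
  stats_list <- lapply(gen$responses, function(rs) {
    compute_cloze_statistics(rs, target = gen$targets[[rs$item_id]])
  })
  stats_df <- cloze_stats_table(stats_list)
  tables$cloze_summary <- do.call(rbind, list(
    summarize_condition(stats_df, "set_size", "small", seed = stage_seed("cs1")),
    summarize_condition(stats_df, "set_size", "large", seed = stage_seed("cs2")),
    summarize_condition(stats_df, "distance", "short", seed = stage_seed("cs3")),
    summarize_condition(stats_df, "distance", "long", seed = stage_seed("cs4"))))
  tables$item_selection <- select_items(stats_df)

  # ---- decay predictions --------------------------------------------------
  dc <- cfg$decay
  pred <- predict_design(
    decay_config(pool = dc$pool, decay_rate = dc$decay_rate,
                 latency_factor = dc$latency_factor, t0 = dc$t0,
                 k_word = dc$k_word, words_short = dc$words_short,
                 words_long = dc$words_long),
    n_small = dc$n_small, n_large = dc$n_large)
  tables$decay_predictions <- pred$cells[, c("set_size", "distance",
                                             "latency_ms")]

  # ---- self-paced reading stage -------------------------------------------
  design <- experiment_design(cfg$design$n_participants, cfg$design$n_items,
                              cfg$design$n_fillers, seed = stage_seed("design"))
  spr_params <- generative_params(
    "reciprocal_speed", intercept = cfg$spr$intercept,
    beta = c(set_size = cfg$spr$set_size, distance = cfg$spr$distance,
             interaction = cfg$spr$interaction, entropy = cfg$spr$entropy),
    sigma = cfg$spr$sigma, accuracy = cfg$spr$accuracy)
  spr <- generate_spr_trials(design, spr_params, p_sub100 = cfg$spr$p_sub100,
                             seed = stage_seed("spr"))
  fast <- spr$rt_ms < cfg$exclusion$rt_min
  exclusions$spr <- data.frame(stage = "self-paced reading",
                               reason = sprintf("rt < %g ms",
                                                cfg$exclusion$rt_min),
                               n_in = nrow(spr), n_excluded = sum(fast),
                               n_retained = sum(!fast))
  spr_kept <- spr[!fast, ]
  tables$spr_condition_summary <- condition_summary(
    spr_kept, "rt_ms", c("set_size", "distance"), seed = stage_seed("sprsum"))
  spr_kept$entropy_cat <- as.character(median_split(spr_kept$entropy))
  tables$spr_entropy_split <- condition_summary(
    spr_kept, "rt_ms", c("entropy_cat", "distance"),
    seed = stage_seed("sprsplit"))
  tables$accuracy_summary <- condition_summary(
    transform(spr, acc = 100 * question_correct), "acc",
    c("set_size", "distance"), seed = stage_seed("acc"))

  # ---- eye-tracking stage -------------------------------------------------
  et_params <- generative_params(
    "log_ms", intercept = cfg$et$intercept,
    beta = c(set_size = cfg$et$set_size, distance = cfg$et$distance,
             interaction = cfg$et$interaction, entropy = cfg$et$entropy),
    sigma = cfg$et$sigma, accuracy = cfg$et$accuracy)
  et <- generate_et_trials(design, et_params, p_refix = cfg$et$p_refix,
                           p_reread = cfg$et$p_reread,
                           p_regress = cfg$et$p_regress,
                           p_skip = cfg$et$p_skip,
                           blink_rate = cfg$et$blink_rate,
                           seed = stage_seed("et"))
  blink <- et$blink_or_trackloss
  exclusions$et <- data.frame(stage = "eye tracking",
                              reason = "blink/track loss",
                              n_in = nrow(et), n_excluded = sum(blink),
                              n_retained = sum(!blink))
  et_kept <- et[!blink, ]
  measure_cols <- c(ffd = "ffd_ms", fprt = "fprt_ms", tft = "tft_ms",
                    rpd = "rpd_ms")
  tables$et_condition_summary <- do.call(rbind, lapply(names(measure_cols),
    function(mn) {
      s <- condition_summary(et_kept, measure_cols[[mn]],
                             c("set_size", "distance"),
                             seed = stage_seed(paste0("et", mn)))
      cbind(measure = mn, s)
    }))

  # ---- model fits ---------------------------------------------------------
  posteriors <- NULL
  if (isTRUE(cfg$fit$enabled)) {
    fit_spr <- fit_reading_model(
      spr_kept, predictors = cfg$fit$predictors,
      prior = prior_spec("reciprocal_speed"),
      rt_min = cfg$exclusion$rt_min,
      chains = cfg$fit$chains, warmup = cfg$fit$warmup, iter = cfg$fit$iter,
      seed = stage_seed("fit-spr"))
    posteriors <- fit_summary_row(fit_spr, "self-paced reading (words/s)")
    for (mn in cfg$fit$et_measures) {
      fit_m <- fit_reading_model(
        et_kept, predictors = cfg$fit$predictors,
        prior = prior_spec("log_ms"), response = measure_cols[[mn]],
        chains = cfg$fit$chains, warmup = cfg$fit$warmup,
        iter = cfg$fit$iter, seed = stage_seed(paste0("fit-", mn)))
      posteriors <- rbind(posteriors,
                          fit_summary_row(fit_m, paste0(mn, " (log ms)")))
      exclusions[[paste0("fit_", mn)]] <- data.frame(
        stage = paste0("fit ", mn),
        reason = paste(fit_m$exclusions$reason, collapse = "; "),
        n_in = nrow(et_kept),
        n_excluded = sum(fit_m$exclusions$n),
        n_retained = nrow(et_kept) - sum(fit_m$exclusions$n))
    }
  }
  tables["posteriors"] <- list(posteriors)

  # ---- Bayes factors ------------------------------------------------------
  bf_table <- NULL
  if (isTRUE(cfg$bayes_factors$enabled)) {
    bf_table <- bf_predictor_table(
      spr_kept, predictors = cfg$fit$predictors,
      prior = prior_spec("reciprocal_speed"),
      widths = unlist(cfg$bayes_factors$widths),
      chains = cfg$fit$chains, warmup = cfg$fit$warmup, iter = cfg$fit$iter,
      seed = stage_seed("bf"))
  }
  tables["bf_table"] <- list(bf_table)

  tables$exclusion_log <- do.call(rbind, exclusions)
  rownames(tables$exclusion_log) <- NULL
  # exclusion accounting must balance in every stage
  stopifnot(all(tables$exclusion_log$n_in ==
                  tables$exclusion_log$n_excluded +
                  tables$exclusion_log$n_retained))

  out <- structure(list(tables = tables, config = cfg), class = "report_tables")
  if (!is.null(output_dir)) write_report(out, output_dir)
  out
}

#' @export
print.report_tables <- function(x, ...) {
  cat("Pipeline report (master seed ", x$config$seed, ")\n", sep = "")
  for (nm in names(x$tables)) {
    t <- x$tables[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(t)) "not computed"
                else paste0(nrow(t), " rows")))
  }
  invisible(x)
}

#' Write report tables to disk
#'
#' Writes every table as UTF-8 CSV into `dir`, a YAML echo of the
#' configuration, and a short human-readable summary embedding
#' exclusion counts and the master seed. Tables that were not computed
#' are written with an explicit "not computed" marker.
#'
#' @param report a `report_tables` object from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "report_tables"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  files <- character(0)
  for (nm in names(report$tables)) {
    t <- report$tables[[nm]]
    if (is.null(t) || nrow(t) == 0) {
      t <- data.frame(note = "not computed")
    }
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(t, f, row.names = FALSE, fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  cfg_file <- file.path(dir, "config.yaml")
  write_config(report$config, cfg_file)
  summary_file <- file.path(dir, "summary.txt")
  con <- file(summary_file, "w", encoding = "UTF-8")
  writeLines(c(
    sprintf("Pipeline run, master seed %d", report$config$seed),
    "",
    "Exclusions:",
    utils::capture.output(print(report$tables$exclusion_log,
                                row.names = FALSE)),
    "",
    sprintf("Tables written: %s",
            paste(basename(files), collapse = ", "))), con)
  close(con)
  invisible(c(files, cfg_file, summary_file))
}
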