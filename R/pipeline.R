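#' Demo-scale cohort configuration
#'
#' A [cohort_config()] sized for interactive use and end-to-end validation:
#' the full 20 participants, but 3 PRE / 2 ADAPT / 2 POST jumps per
#' participant (the comparison timepoints only need the first and last jump
#' of each block, and injected condition effects are constant within a
#' block, so extra within-block jumps add runtime without adding
#' information).
#'
#' @param ... overrides passed to [cohort_config()].
#' @export
demo_config <- function(...) {
  defaults <- list(jumps_per_condition = c(PRE = 3, ADAPT = 2, POST = 2))
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# map (condition, jump index) to a comparison timepoint; NA = not a
# comparison jump (still analyzed and logged)
timepoint_of <- function(condition, jump, jumps_per_condition) {
  dplyr::case_when(
    condition == "PRE" ~ "PRE",
    condition == "ADAPT" & jump == 1 ~ "EarlyAdaptation",
    condition == "ADAPT" & jump == jumps_per_condition[["ADAPT"]] ~ "LateAdaptation",
    condition == "POST" & jump == 1 ~ "POST",
    condition == "POST" & jump == jumps_per_condition[["POST"]] ~ "Washout",
    TRUE ~ NA_character_
  )
}

#' Run the full jump-analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> kinetics -> EMG -> scalar statistics (and
#' optionally the wavelet functional test) into one reproducible run.
#' Per participant: three maximum jumps set the EMG normalization peaks;
#' every configured trial is segmented from the filtered vertical force,
#' impulses / jump height / target error computed, and each muscle's
#' preactivation onset, magnitude and iEMG extracted with the exclusion
#' gates. Per-jump metrics are aggregated per participant and timepoint
#' (PRE = mean over the PRE block; Early/Late Adaptation = first/last ADAPT
#' jump; POST/Washout = first/last POST jump) and compared against PRE with
#' the gated paired battery. The aftereffect summary is POST minus PRE per
#' participant, then averaged.
#'
#' @param config a [cohort_config()]; defaults to [demo_config()].
#' @param do_functional also run [wavelet_paired_test()] on the
#'   time-normalized aerial-phase EMG waveforms (dominant MG), PRE vs POST.
#' @param out_dir optional directory: writes `metrics.tsv`,
#'   `comparisons.tsv`, `aftereffects.tsv`, `exclusions.tsv` and
#'   `manifest.json`.
#' @return object of class `hypojump_run`: tibbles `metrics` (per jump),
#'   `by_timepoint` (per participant x timepoint), `comparisons`,
#'   `aftereffects`, `exclusions`, optional `functional`, plus `config`.
#' @export
run_jump_analysis <- function(config = demo_config(), do_functional = FALSE,
                              out_dir = NULL) {
  validate_config(config)
  conds <- c("PRE", "ADAPT", "POST")
  n_tr <- sum(config$jumps_per_condition[conds])
  withr::with_seed(config$seed, {
    p_seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)
    t_seeds <- matrix(
      sample.int(.Machine$integer.max - 1L, config$n_participants * (n_tr + 3)),
      nrow = config$n_participants
    )
  })

  kin_rows <- list(); emg_rows <- list(); excl_rows <- list()
  wave_pre <- list(); wave_post <- list()
  for (i in seq_len(config$n_participants)) {
    p <- participant_params(config, sprintf("P%02d", i), p_seeds[i])
    max_trials <- lapply(1:3, function(j) generate_trial(p, "MAX", t_seeds[i, j], config))
    peaks <- normalization_peaks(max_trials)
    ks <- 3L
    for (cond in conds) {
      for (j in seq_len(config$jumps_per_condition[[cond]])) {
        ks <- ks + 1L
        tr <- generate_trial(p, cond, t_seeds[i, ks], config)
        key <- sprintf("%s_%s_%02d", p$id, cond, j)
        kin <- analyze_trial_kinetics(tr)
        kin$jump <- j
        kin_rows[[key]] <- kin
        em <- analyze_trial_emg(tr, peaks, kin$liftoff_t, kin$touchdown_t)
        em$jump <- j
        emg_rows[[key]] <- em
        excl_rows[[key]] <- em %>%
          select("participant", "condition", "muscle", "leg",
                 "included", "exclusion_rule") %>%
          mutate(jump = j, key = key)
        if (do_functional && cond %in% c("PRE", "POST")) {
          rect <- emg_preprocess(tr$emg$MG_dom, tr$fs$emg) / peaks[["MG_dom"]]
          t_emg <- tr$emg$time
          idx <- which(t_emg >= kin$liftoff_t & t_emg <= kin$touchdown_t)
          wv <- time_normalize(rect[idx], phase_points("aerial"))
          if (cond == "PRE") {
            wave_pre[[p$id]] <- rbind(wave_pre[[p$id]], wv)
          } else {
            wave_post[[p$id]] <- rbind(wave_post[[p$id]], wv)
          }
        }
      }
    }
  }

  kinetics <- bind_rows(kin_rows)
  emg <- bind_rows(emg_rows)
  exclusions <- bind_rows(excl_rows)

  jp <- config$jumps_per_condition
  kinetics$timepoint <- timepoint_of(kinetics$condition, kinetics$jump, jp)
  emg$timepoint <- timepoint_of(emg$condition, emg$jump, jp)

  kin_long <- kinetics %>%
    filter(!is.na(.data$timepoint)) %>%
    tidyr::pivot_longer(
      c("jump_height", "target_error", "abs_target_error",
        "lift_impulse", "land_impulse"),
      names_to = "metric", values_to = "value"
    ) %>%
    select("participant", "timepoint", "metric", "value")

  emg_m <- emg %>%
    filter(!is.na(.data$timepoint), .data$included) %>%
    mutate(muscle_leg = paste(.data$muscle, .data$leg, sep = "_"))
  emg_long <- bind_rows(
    emg_m %>% mutate(metric = paste0("onset_", .data$muscle_leg),
                     value = .data$onset_ms) %>%
      select("participant", "timepoint", "metric", "value"),
    emg_m %>% mutate(metric = paste0("magnitude_", .data$muscle_leg),
                     value = .data$magnitude) %>%
      select("participant", "timepoint", "metric", "value")
  )

  tsp_long <- emg %>%
    filter(!is.na(.data$timepoint)) %>%
    mutate(iemg_ok = ifelse(.data$included, .data$iemg, NA_real_)) %>%
    group_by(.data$participant, .data$timepoint, .data$leg, .data$condition,
             .data$jump) %>%
    summarise(value = if (anyNA(.data$iemg_ok)) NA_real_
              else mean(.data$iemg_ok), .groups = "drop") %>%
    mutate(metric = paste0("tsp_", .data$leg)) %>%
    select("participant", "timepoint", "metric", "value")

  metrics_long <- bind_rows(kin_long, emg_long, tsp_long)

  by_timepoint <- metrics_long %>%
    group_by(.data$participant, .data$timepoint, .data$metric) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
    mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value))

  comparisons <- compare_conditions(by_timepoint)

  aftereffects <- by_timepoint %>%
    filter(.data$timepoint %in% c("PRE", "POST")) %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value") %>%
    mutate(diff = .data$POST - .data$PRE) %>%
    group_by(.data$metric) %>%
    summarise(
      n = sum(is.finite(.data$diff)),
      aftereffect = mean(.data$diff, na.rm = TRUE),
      sd = sd(.data$diff, na.rm = TRUE), .groups = "drop"
    ) %>%
    left_join(
      comparisons %>% filter(.data$timepoint == "POST") %>%
        select("metric", "p", "significant"),
      by = "metric"
    )

  functional <- NULL
  if (do_functional) {
    ids <- intersect(names(wave_pre), names(wave_post))
    if (length(ids) >= 3) {
      pre_m <- do.call(rbind, lapply(ids, function(id)
        colMeans(wave_pre[[id]], na.rm = TRUE)))
      post_m <- do.call(rbind, lapply(ids, function(id)
        colMeans(wave_post[[id]], na.rm = TRUE)))
      functional <- wavelet_paired_test(pre_m, post_m)
    }
  }

  run <- structure(list(
    metrics = kinetics, emg = emg, metrics_long = metrics_long,
    by_timepoint = by_timepoint, comparisons = comparisons,
    aftereffects = aftereffects, exclusions = exclusions,
    functional = functional, config = config
  ), class = "hypojump_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(kinetics, file.path(out_dir, "metrics.tsv"))
    readr::write_tsv(emg, file.path(out_dir, "emg.tsv"))
    readr::write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"))
    readr::write_tsv(run$aftereffects, file.path(out_dir, "aftereffects.tsv"))
    readr::write_tsv(exclusions, file.path(out_dir, "exclusions.tsv"))
    jsonlite::write_json(
      list(seed = config$seed,
           n_participants = config$n_participants,
           jumps_per_condition = as.list(config$jumps_per_condition),
           exclusion_counts = as.list(table(exclusions$exclusion_rule))),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  run
}

#' @export
print.hypojump_run <- function(x, ...) {
  cat("<hypojump_run> ", x$config$n_participants, " participants, ",
      nrow(x$metrics), " analyzed jumps\n", sep = "")
  ex <- table(x$exclusions$exclusion_rule)
  cat("  EMG exclusions:", paste(names(ex), ex, sep = "=", collapse = ", "), "\n")
  cat("  POST vs PRE aftereffects (significant at alpha = .05):\n")
  sig <- x$aftereffects %>% filter(isTRUE(.data$significant) | .data$significant %in% TRUE)
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %-24s %+.4g (p = %.3g)\n", sig$metric[i],
                  sig$aftereffect[i], sig$p[i]))
    }
  } else cat("    none\n")
  invisible(x)
}

#' Aftereffect summary plot
#'
#' Bar chart of the POST minus PRE aftereffect per metric (participant
#' means, +-1 SD), asterisks marking metrics whose POST vs PRE comparison is
#' significant.
#'
#' @param object a `hypojump_run`.
#' @param metrics optional character vector restricting the plot.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hypojump_run <- function(object, metrics = NULL, ...) {
  df <- object$aftereffects
  if (!is.null(metrics)) df <- filter(df, .data$metric %in% metrics)
  df <- mutate(df, label = ifelse(.data$significant %in% TRUE, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$aftereffect)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$aftereffect - .data$sd,
                   ymax = .data$aftereffect + .data$sd),
      width = 0.25
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.5,
                       size = 6) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "POST - PRE (participant mean)",
                  title = "Aftereffects of simulated hypogravity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname run_jump_analysis
#' @param x a `hypojump_run`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.hypojump_run <- function(x, ...) x$comparisons

#' @rdname run_jump_analysis
#' @exportS3Method generics::glance
glance.hypojump_run <- function(x, ...) {
  tibble(
    n_participants = x$config$n_participants,
    n_jumps = nrow(x$metrics),
    n_emg_observations = nrow(x$emg),
    n_excluded = sum(!x$exclusions$included),
    n_significant_post = sum(
      x$comparisons$timepoint == "POST" & x$comparisons$significant %in% TRUE
    ),
    seed = x$config$seed
  )
}
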