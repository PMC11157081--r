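#' Write / read one trial as a headered TSV
#'
#' One delimited-text file per trial. Commented header lines (`#key\tvalue`)
#' carry the scalar metadata (participant, condition, body weight, effective
#' g, per-family sampling rates); the table body holds one column per channel,
#' each channel family on its own clock (`time_grf`/`grf_z`,
#' `time_emg`/muscles, `time_marker`/`z`, and optional MTJ/torque columns).
#' Families with fewer samples are NA-padded to the longest column.
#'
#' @param trial a `jump_trial` from [generate_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_tsv <- function(trial, path) {
  stopifnot(inherits(trial, "jump_trial"))
  meta <- c(
    participant = trial$participant, condition = trial$condition,
    body_mass_kg = trial$body_mass, body_weight_N = trial$body_weight,
    effective_g = trial$effective_g,
    standing_height_m = trial$standing_height,
    target_height_m = trial$target_height,
    fs_grf = trial$fs$grf, fs_emg = trial$fs$emg,
    fs_marker = trial$fs$marker, fs_mtj = trial$fs$mtj,
    seed = trial$seed
  )
  blocks <- list(
    setNames(trial$grf, c("time_grf", "grf_z")),
    setNames(trial$emg, c("time_emg", paste0("emg_", names(trial$emg)[-1]))),
    setNames(trial$marker, c("time_marker", "marker_z"))
  )
  if (!is.null(trial$mtj)) {
    blocks <- c(blocks, list(
      setNames(trial$mtj, c("time_mtj", names(trial$mtj)[-1])),
      setNames(trial$torque, c("time_torque", "ankle_torque"))
    ))
  }
  nmax <- max(vapply(blocks, nrow, 1L))
  pad <- function(df) {
    extra <- nmax - nrow(df)
    if (extra > 0) df <- bind_rows(df, df[rep(NA_integer_, extra), ])
    df
  }
  wide <- do.call(cbind, lapply(blocks, pad))
  writeLines(sprintf("#%s\t%s", names(meta), unname(meta)), path)
  readr::write_tsv(as_tibble(wide), path, na = "", append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_trial_tsv
#' @param path file written by [write_trial_tsv()].
#' @export
read_trial_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- strsplit(sub("^#", "", lines[hdr]), "\t")
  meta <- setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  body <- readr::read_tsv(I(lines[-hdr]), show_col_types = FALSE,
                          progress = FALSE)
  num <- function(k) as.numeric(meta[[k]])
  strip <- function(df) df[!is.na(df[[1]]), , drop = FALSE]
  grf <- strip(tibble(time = body$time_grf, grf_z = body$grf_z))
  emg_cols <- grep("^emg_", names(body), value = TRUE)
  emg <- strip(as_tibble(c(list(time = body$time_emg),
                           setNames(as.list(body[emg_cols]),
                                    sub("^emg_", "", emg_cols)))))
  marker <- strip(tibble(time = body$time_marker, z = body$marker_z))
  mtj <- NULL; torque <- NULL
  if ("time_mtj" %in% names(body)) {
    mtj_cols <- setdiff(names(body), c(
      "time_grf", "grf_z", emg_cols, "time_emg", "time_marker", "marker_z",
      "time_mtj", "time_torque", "ankle_torque"
    ))
    mtj <- strip(as_tibble(c(list(time = body$time_mtj),
                             as.list(body[mtj_cols]))))
    torque <- strip(tibble(time = body$time_torque,
                           ankle_torque = body$ankle_torque))
  }
  structure(list(
    participant = meta[["participant"]], condition = meta[["condition"]],
    body_mass = num("body_mass_kg"), body_weight = num("body_weight_N"),
    effective_g = num("effective_g"),
    standing_height = num("standing_height_m"),
    target_height = num("target_height_m"),
    fs = list(grf = num("fs_grf"), emg = num("fs_emg"),
              marker = num("fs_marker"), mtj = num("fs_mtj")),
    grf = grf, emg = emg, marker = marker, mtj = mtj, torque = torque,
    truth = NULL, seed = as.integer(num("seed"))
  ), class = "jump_trial")
}

# write every trial of a cohort plus a JSON manifest with ground truth
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$trials)) {
    write_trial_tsv(cohort$trials[[key]], file.path(out_dir, paste0(key, ".tsv")))
  }
  write_cohort_manifest(cohort, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Write the cohort manifest
#'
#' JSON manifest listing every generated trial with its seed and ground-truth
#' scalars, so an analysis run can be audited trial by trial.
#'
#' @param cohort a `jump_cohort`.
#' @param path output JSON path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  jsonlite::write_json(list(
    config = cohort$config[setdiff(names(cohort$config), "class")],
    trials = cohort$manifest
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
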