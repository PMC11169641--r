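# Batch orchestration: manifest-driven feature extraction across the four
# paradigms, and the cohort statistics battery. These functions (plus the
# generators in synth.R) are the package's interface; the thin command-line
# wrapper in inst/cli/ calls straight into them.

#' Pipeline configuration
#'
#' All analysis parameters in one place, echoed into output provenance.
#' Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults.
#' @return A named list of parameters (class `pdspeech_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    f0_min = 75,            # Hz, F0 search floor
    f0_max = 400,           # Hz, F0 search ceiling
    smooth_ms = 20,         # envelope smoothing
    min_prominence = 0.25,  # DDK peak prominence (fraction of max)
    min_period_ms = 100,    # DDK minimum inter-peak period
    f2_prominence_hz = 200, # /i/-/u/ cycle prominence
    min_pause_ms = 30,      # minimum pause duration
    pause_floor_db = -25,   # pause energy floor re speech level
    n_syllables = 105,      # passage length in syllables
    sparsity = 0.2,         # network edge density
    cv_folds = 5,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pdspeech_config")
}

# analyze one recording; returns a named list of the features its paradigm
# contributes (F1/F2 of vowels are intermediates for the vowel space area)
.analyze_recording <- function(rec, cfg) {
  switch(rec$task,
    vowel_a = {
      ph <- phonation_features(rec, cfg$f0_min, cfg$f0_max)
      ph[c("F0", "F0std", "vF0", "Ampstd", "vAmp", "MPT", "HNR",
           "F1", "F2")] |> stats::setNames(
             c("F0", "F0std", "vF0", "Ampstd", "vAmp", "MPT", "HNR",
               ".F1_a", ".F2_a"))
    },
    vowel_i = ,
    vowel_u = {
      ph <- phonation_features(rec, cfg$f0_min, cfg$f0_max)
      suf <- if (rec$task == "vowel_i") "i" else "u"
      stats::setNames(ph[c("F1", "F2")],
                      paste0(c(".F1_", ".F2_"), suf))
    },
    ddk_pa = {
      trimmed <- trim_silence(rec)
      env <- amplitude_envelope(trimmed, cfg$smooth_ms)
      ev <- detect_syllables(env, cfg$min_prominence, cfg$min_period_ms)
      fx <- ddk_features(ev, rec_duration(trimmed))
      fx$VOT <- tryCatch(measure_vot(trimmed, ev),
                         error = function(e) NA_real_)
      fx
    },
    iu_alternation = {
      f2 <- lpc_formants(rec, n_formants = 3)[[2]]
      cyc <- detect_f2_cycles(f2, cfg$f2_prominence_hz)
      articulation_features(cyc, f2)
    },
    passage = {
      p <- detect_pauses(rec, cfg$min_pause_ms, cfg$pause_floor_db)
      prosody_features(rec, p, cfg$n_syllables)
    },
    stop("unknown task: ", rec$task)
  )
}

#' Extract the 29-feature vector for every subject in a manifest
#'
#' The manifest lists one WAV per (subject, task, repetition). Each
#' recording is analyzed by its paradigm; repetitions are averaged per
#' feature (a single repetition is accepted with a warning). The vowel
#' space area is assembled once per subject from the median formants of
#' /a/, /i/ and /u/. Missing tasks yield `NA` cells, never silent zeros;
#' unreadable or failing files are recorded in the `errors` attribute and
#' the run continues.
#'
#' @param manifest Data frame with columns `subject_id`, `task`,
#'   `repetition`, `path`.
#' @param config A [pipeline_config()].
#' @return A tibble, one row per subject, with `subject_id` plus the 29
#'   feature columns. Attributes: `repetitions` (long per-repetition
#'   table), `errors` (per-file failures), `provenance` (config echo).
#' @export
extract_features <- function(manifest, config = pipeline_config()) {
  req <- c("subject_id", "task", "repetition", "path")
  missing_cols <- setdiff(req, names(manifest))
  if (length(missing_cols) > 0) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "),
         " (need subject_id, task, repetition, path)")
  }
  feature_names <- acoustic_feature_names()

  long <- list()
  errors <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      rec <- read_wav(row$path, task = row$task,
                      subject_id = row$subject_id,
                      repetition = row$repetition)
      .analyze_recording(rec, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <- tibble::tibble(
        subject_id = row$subject_id, task = row$task,
        repetition = row$repetition, path = row$path,
        message = conditionMessage(res))
      next
    }
    long[[length(long) + 1]] <- tibble::tibble(
      subject_id = row$subject_id, task = row$task,
      repetition = row$repetition,
      feature = names(res), value = as.numeric(unlist(res)))
  }
  long_tab <- dplyr::bind_rows(long)
  err_tab <- dplyr::bind_rows(errors)

  subjects <- unique(manifest$subject_id)
  out <- tibble::tibble(subject_id = subjects)
  for (f in c(feature_names, ".F1_a", ".F2_a", ".F1_i", ".F2_i",
              ".F1_u", ".F2_u")) {
    out[[f]] <- NA_real_
  }
  if (nrow(long_tab) > 0) {
    n_reps <- length(unique(manifest$repetition))
    agg <- long_tab |>
      dplyr::group_by(.data$subject_id, .data$feature) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                       n = dplyr::n(), .groups = "drop")
    if (n_reps > 1 && any(agg$n < n_reps)) {
      warning("some features computed from a single repetition")
    }
    for (j in seq_len(nrow(agg))) {
      if (agg$feature[j] %in% names(out)) {
        out[[agg$feature[j]]][out$subject_id == agg$subject_id[j]] <-
          agg$value[j]
      }
    }
  }
  have_corners <- stats::complete.cases(
    out[, c(".F1_a", ".F2_a", ".F1_i", ".F2_i", ".F1_u", ".F2_u")])
  out$VowelArea <- NA_real_
  for (i in which(have_corners)) {
    out$VowelArea[i] <- vowel_space_area(
      out$.F1_a[i], out$.F2_a[i], out$.F1_i[i], out$.F2_i[i],
      out$.F1_u[i], out$.F2_u[i])
  }
  out <- out[, c("subject_id", feature_names)]
  attr(out, "repetitions") <- long_tab
  attr(out, "errors") <- err_tab
  attr(out, "provenance") <- c(list(pdspeech_version =
                                      as.character(utils::packageVersion("pdspeech"))),
                               unclass(config))
  out
}

#' Write a feature table as CSV with a provenance header
#'
#' Provenance (package version and every configuration parameter) is
#' written as leading `#`-comment lines so reruns are byte-comparable.
#'
#' @param features Output of [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  prov <- attr(features, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prov)) {
    writeLines(sprintf("# %s: %s", names(prov),
                       vapply(prov, function(x) paste(format(x), collapse = ","),
                              character(1))), con)
  }
  utils::write.csv(as.data.frame(features), con, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [write_feature_csv()]
#' @param path CSV path.
#' @return A tibble.
#' @export
read_feature_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Run the cohort statistics battery
#'
#' Joins the extracted features to the cohort metadata, z-normalizes
#' against same-sex healthy controls, compares groups with Hedges' g,
#' ranks features, cross-validates the Gaussian naive Bayes classifier on
#' the six-feature preset, compares Hoehn-Yahr stages, and computes
#' covariate-adjusted partial correlations of each preset feature with
#' MDS-UPDRS III (FDR-corrected).
#'
#' @param features Feature table from [extract_features()] or a cohort
#'   table that already carries feature columns.
#' @param cohort Metadata table (`subject_id`, `group`, `sex`, covariates,
#'   clinical scores).
#' @param config A [pipeline_config()].
#' @return A list: `comparison`, `zscores`, `ranking`, `classifier`,
#'   `stage_tests`, `updrs_correlations`.
#' @export
run_stats <- function(features, cohort, config = pipeline_config()) {
  if (!all(features$subject_id %in% cohort$subject_id)) {
    missing_ids <- setdiff(features$subject_id, cohort$subject_id)
    stop("id mismatch: feature subjects absent from cohort: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  meta_cols <- setdiff(names(cohort), acoustic_feature_names())
  tab <- dplyr::inner_join(cohort[, meta_cols], features,
                           by = "subject_id")
  if (length(unique(tab$group)) < 2) {
    stop("single-class cohort: need both HC and PD")
  }
  z <- znormalize(tab)
  comparison <- compare_groups(tab)
  ranking <- rank_features(comparison, tab)

  preset <- intersect(selected_feature_preset(), names(z))
  Xz <- as.matrix(z[, preset])
  ok <- stats::complete.cases(Xz)
  classifier <- nb_classify_cv(Xz[ok, , drop = FALSE],
                               factor(tab$group[ok], c("HC", "PD")),
                               k = config$cv_folds, seed = config$seed)

  stage_tests <- if ("HY_stage" %in% names(tab)) {
    stats::setNames(lapply(preset, function(f) {
      tryCatch(stage_comparison(tab, f), error = function(e) NULL)
    }), preset)
  } else NULL

  covs <- intersect(c("age", "sex", "MoCA", "height", "weight"), names(tab))
  updrs <- NULL
  if ("UPDRS_III" %in% names(tab)) {
    pd <- tab[tab$group == "PD", ]
    Zc <- pd[, covs]
    if ("sex" %in% covs) Zc$sex <- as.numeric(factor(Zc$sex))
    updrs <- dplyr::bind_rows(lapply(preset, function(f) {
      pc <- tryCatch(
        partial_correlation(pd[[f]], pd$UPDRS_III, Zc),
        error = function(e) list(r = NA_real_, p = NA_real_, n = NA))
      tibble::tibble(feature = f, r = pc$r, p = pc$p, n = pc$n)
    }))
    good <- !is.na(updrs$p)
    updrs$p_fdr <- NA_real_
    updrs$p_fdr[good] <- fdr_adjust(updrs$p[good])
  }
  list(comparison = comparison, zscores = z, ranking = ranking,
       classifier = classifier, stage_tests = stage_tests,
       updrs_correlations = updrs)
}
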