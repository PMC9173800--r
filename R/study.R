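#' Study configuration
#'
#' A fully serializable description of an end-to-end run: the cohort
#' specification, the stimulus protocol, processing and association
#' options, and the master seed.  A study run is a pure function of its
#' configuration.
#'
#' @param seed Master seed; every random stream in the run derives from it.
#' @param cohort Named list of [cohort_spec()] arguments (the seed is
#'   injected from `seed`).
#' @param protocol `"all"`, `"iscev"`, `"xenon"`, or a named list of
#'   [stimulus_spec()] objects.
#' @param a_window,b_window Measurement windows (ms).
#' @param abs_cap,k Artifact-rejection settings.
#' @param coding Dosage coding for the design matrix.
#' @param method `"REML"` or `"ML"`.
#' @param bh Add a Benjamini-Hochberg column to the association table?
#' @param lesion_demo Run the lesion comparisons (CRAO, cCSNB)?
#' @param out_dir Output directory (`NULL` = keep results in memory only).
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed, cohort = list(), protocol = "all",
                         a_window = c(3, 28), b_window = c(10, 80),
                         abs_cap = 1000, k = 5,
                         coding = "additive", method = "REML", bh = FALSE,
                         lesion_demo = TRUE, out_dir = NULL) {
  if (missing(seed)) stop("`seed` is mandatory")
  structure(list(seed = seed, cohort = cohort, protocol = protocol,
                 a_window = a_window, b_window = b_window,
                 abs_cap = abs_cap, k = k, coding = coding,
                 method = method, bh = bh, lesion_demo = lesion_demo,
                 out_dir = out_dir),
            class = "study_config")
}

resolve_protocol <- function(protocol) {
  if (is.character(protocol)) standard_protocol(protocol) else protocol
}

build_cohort <- function(config) {
  args <- config$cohort
  args$seed <- config$seed
  do.call(cohort_spec, args)
}

# write a numeric data frame so that doubles round-trip exactly
write_table_exact <- function(d, path) {
  for (nm in names(d)) {
    if (is.double(d[[nm]])) d[[nm]] <- sprintf("%.17g", d[[nm]])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9.-]", "_", x)

#' Simulate all recording sessions of a cohort
#'
#' One [simulate_session()] per subject, each with a seed derived from the
#' cohort's master seed and the subject id.
#'
#' @param cohort An `erg_cohort` from [simulate_cohort()].
#' @param protocol Named list of [stimulus_spec()].
#' @return Named list of `erg_session` objects keyed by subject id.
#' @export
simulate_sessions <- function(cohort, protocol) {
  ids <- cohort$subjects$subject_id
  out <- lapply(seq_along(ids), function(i) {
    simulate_session(cohort$subjects[i, ], cohort$gains[[ids[i]]],
                     protocol, cohort$spec,
                     seed = derive_seed(cohort$spec$seed,
                                        paste0("session:", ids[i])))
  })
  names(out) <- ids
  out
}

#' Process all sessions into a stacked feature table
#'
#' @param sessions Named list of `erg_session`s.
#' @param protocol The protocol they were recorded with.
#' @param config A [study_config()] (windows and artifact settings).
#' @return List with `features` (stacked long data frame) and
#'   `rejection_log`.
#' @export
process_sessions <- function(sessions, protocol, config = study_config(1)) {
  res <- lapply(sessions, extract_features, protocol = protocol,
                a_window = config$a_window, b_window = config$b_window,
                abs_cap = config$abs_cap, k = config$k)
  feats <- do.call(rbind, lapply(res, `[[`, "features"))
  rownames(feats) <- NULL
  list(features = feats,
       rejection_log = do.call(rbind, lapply(res, `[[`, "rejection_log")))
}

#' Noiseless per-subject features straight from cellular gains
#'
#' Fast deterministic path used for calibration work and power studies:
#' synthesizes each subject's noiseless single-eye response per stimulus
#' and measures the same feature set as the full processing chain (for
#' noiseless identical eyes, parameter-level eye averaging equals
#' single-eye measurement).
#'
#' @param cohort An `erg_cohort`.
#' @param protocol Named list of [stimulus_spec()].
#' @param a_window,b_window Measurement windows (ms).
#' @return Long feature data frame (`subject_id`, `parameter`, `value`).
#' @export
noiseless_cohort_features <- function(cohort, protocol,
                                      a_window = c(3, 28),
                                      b_window = c(10, 80)) {
  time <- trace_grid()
  rows <- lapply(cohort$subjects$subject_id, function(id) {
    g <- cohort$gains[[id]]
    traces <- lapply(protocol, function(stim) {
      if (stim$mode == "flicker_30hz") {
        synthesize_flicker_response(stim, g, time = time)
      } else {
        tr <- synthesize_flash_response(stim, g, time = time)$trace
        tr$meta$flash_strength <- stim$flash_strength
        tr
      }
    })
    fr <- lapply(names(traces), function(label) {
      measure_trace_features(traces[[label]], label,
                             protocol[[label]]$mode, a_window, b_window)
    })
    for (s in xenon_strengths()) {
      dl <- sprintf("X%g-dark", s); bl <- sprintf("X%g-blue", s)
      if (is.null(traces[[dl]]) || is.null(traces[[bl]])) next
      iso <- isolate_rod_response(traces[[dl]], traces[[bl]])
      amp <- measure_a_wave(iso, estimate_baseline(iso), a_window)$amplitude
      fr[[length(fr) + 1L]] <- data.frame(
        parameter = sprintf("X%g-rod a-wave", s), value = amp)
    }
    data.frame(subject_id = id, do.call(rbind, fr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lesion comparison through the full processing chain
#'
#' Synthesizes noiseless responses for healthy (`"none"`) and lesioned
#' retinae with the same gains, runs both through baseline estimation,
#' a-/b-wave measurement and rod isolation, and reports lesioned/healthy
#' amplitude ratios per stimulus, including the rod-isolated a-wave.
#'
#' @param protocol Named list of [stimulus_spec()] (single-flash stimuli;
#'   flicker stimuli are measured by their flicker amplitude).
#' @param gains A [cellular_gains()] object.
#' @param lesion `"crao"` or `"ccsnb"`.
#' @param a_window,b_window Measurement windows (ms).
#' @return Data frame: parameter, healthy, lesioned, ratio.
#' @export
lesion_comparison <- function(protocol, gains = default_gains(),
                              lesion = c("crao", "ccsnb"),
                              a_window = c(3, 28), b_window = c(10, 80)) {
  lesion <- match.arg(lesion)
  time <- trace_grid()
  one_side <- function(les) {
    traces <- lapply(protocol, function(stim) {
      if (stim$mode == "flicker_30hz") {
        synthesize_flicker_response(stim, gains, lesion = les, time = time)
      } else {
        tr <- synthesize_flash_response(stim, gains, lesion = les,
                                        time = time)$trace
        tr$meta$flash_strength <- stim$flash_strength
        tr
      }
    })
    fr <- lapply(names(traces), function(label) {
      measure_trace_features(traces[[label]], label,
                             protocol[[label]]$mode, a_window, b_window)
    })
    for (s in xenon_strengths()) {
      dl <- sprintf("X%g-dark", s); bl <- sprintf("X%g-blue", s)
      if (is.null(traces[[dl]]) || is.null(traces[[bl]])) next
      iso <- isolate_rod_response(traces[[dl]], traces[[bl]])
      amp <- measure_a_wave(iso, estimate_baseline(iso), a_window)$amplitude
      fr[[length(fr) + 1L]] <- data.frame(
        parameter = sprintf("X%g-rod a-wave", s), value = amp)
    }
    do.call(rbind, fr)
  }
  h <- one_side("none")
  l <- one_side(lesion)
  keep <- !grepl("-time$", h$parameter)
  out <- data.frame(parameter = h$parameter[keep],
                    healthy = h$value[keep],
                    lesioned = l$value[match(h$parameter[keep],
                                             l$parameter)],
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$healthy > 0, out$lesioned / out$healthy, NA_real_)
  rownames(out) <- NULL
  out
}

#' Run the full study pipeline
#'
#' simulate -> process -> associate -> report, deterministically from the
#' configuration.  With an `out_dir`, all report tables are written as CSV
#' and a provenance record (configuration hash, seed, package version) as
#' JSON; running the same configuration twice produces byte-identical
#' tables.  Individual stages can be run against intermediate files for a
#' stage-wise pipeline.
#'
#' @param config A [study_config()].
#' @param stage `"all"` (in memory, default) or one of `"simulate"`,
#'   `"process"`, `"associate"` to run a single stage against
#'   `config$out_dir` (which is then required).
#' @return An object of class `erg_study_report` (invisibly for single
#'   stages): cohort, features, group summary, association results, lesion
#'   tables, provenance.
#' @export
run_study <- function(config,
                      stage = c("all", "simulate", "process", "associate")) {
  stopifnot(inherits(config, "study_config"))
  stage <- match.arg(stage)
  protocol <- resolve_protocol(config$protocol)
  out <- config$out_dir
  if (stage != "all" && is.null(out)) {
    stop("stage-wise runs require `out_dir`")
  }
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (stage %in% c("all", "simulate")) {
    spec <- build_cohort(config)
    cohort <- simulate_cohort(spec)
    sessions <- simulate_sessions(cohort, protocol)
    if (!is.null(out)) {
      write_cohort(cohort$subjects, file.path(out, "cohort.csv"))
      write_kinship(cohort$kinship, file.path(out, "kinship.csv"))
    }
    if (stage == "simulate") {
      sess_dir <- file.path(out, "sessions")
      for (id in names(sessions)) {
        d <- file.path(sess_dir, id)
        dir.create(d, showWarnings = FALSE, recursive = TRUE)
        sw <- sessions[[id]]$sweeps
        for (label in names(sw)) for (eye in names(sw[[label]])) {
          for (j in seq_along(sw[[label]][[eye]])) {
            tr <- sw[[label]][[eye]][[j]]
            write_trace(tr, file.path(d, sprintf("%s_%s_%02d.csv",
                                                 sanitize_label(label),
                                                 eye, j)))
          }
        }
      }
      return(invisible(NULL))
    }
  }

  if (stage == "process") {
    cohort <- list(subjects = read_cohort(file.path(out, "cohort.csv")))
    sessions <- read_sessions(file.path(out, "sessions"))
  }

  if (stage %in% c("all", "process")) {
    proc <- process_sessions(sessions, protocol, config)
    features <- proc$features
    if (!is.null(out)) {
      write_table_exact(features, file.path(out, "features.csv"))
      rl <- file.path(out, "rejection_log.jsonl")
      writeLines(vapply(seq_len(nrow(proc$rejection_log)), function(i)
        as.character(jsonlite::toJSON(as.list(proc$rejection_log[i, ]),
                                      auto_unbox = TRUE, digits = NA)),
        ""), rl)
    }
    if (stage == "process") return(invisible(NULL))
  }

  if (stage == "associate") {
    features <- read_features(file.path(out, "features.csv"))
    subjects <- read_cohort(file.path(out, "cohort.csv"))
    K <- read_kinship(file.path(out, "kinship.csv"))
    cohort <- list(subjects = subjects, kinship = K)
  } else {
    subjects <- cohort$subjects
    K <- cohort$kinship
  }

  assoc <- association_scan(features, subjects, K, bh = config$bh,
                            method = config$method)
  summary_tab <- summarize_by_group(
    features, stats::setNames(subjects$dosage, subjects$subject_id))
  lesions <- NULL
  if (config$lesion_demo) {
    gains0 <- if (!is.null(config$cohort$baseline_gains))
      config$cohort$baseline_gains else default_gains()
    lesions <- list(crao = lesion_comparison(protocol, gains0, "crao"),
                    ccsnb = lesion_comparison(protocol, gains0, "ccsnb"))
  }
  cfg_id <- unclass(config)
  cfg_id$out_dir <- NULL        # identity excludes the output location
  provenance <- list(config_hash = config_hash(cfg_id),
                     seed = config$seed,
                     package = "ergdose",
                     version = as.character(utils::packageVersion("ergdose")))
  report <- structure(list(subjects = subjects, kinship = K,
                           features = features,
                           group_summary = summary_tab,
                           association = assoc,
                           lesions = lesions,
                           provenance = provenance),
                      class = "erg_study_report")
  if (!is.null(out)) {
    write_table_exact(summary_tab, file.path(out, "group_summary.csv"))
    write_table_exact(assoc, file.path(out, "association.csv"))
    if (!is.null(lesions)) {
      write_table_exact(lesions$crao, file.path(out, "lesion_crao.csv"))
      write_table_exact(lesions$ccsnb, file.path(out, "lesion_ccsnb.csv"))
    }
    jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# read a directory of per-subject trace CSVs back into erg_session objects
read_sessions <- function(sess_dir) {
  ids <- list.dirs(sess_dir, recursive = FALSE, full.names = FALSE)
  out <- lapply(ids, function(id) {
    files <- list.files(file.path(sess_dir, id), pattern = "\\.csv$",
                        full.names = TRUE)
    traces <- lapply(files, read_trace)
    sweeps <- list()
    for (tr in traces) {
      lab <- tr$meta$stimulus; eye <- tr$meta$eye
      k <- tr$meta$sweep
      if (is.null(sweeps[[lab]])) sweeps[[lab]] <- list(RE = list(),
                                                        LE = list())
      sweeps[[lab]][[eye]][[k]] <- tr
    }
    structure(list(subject_id = id, sweeps = sweeps,
                   artifact_log = NULL),
              class = "erg_session")
  })
  names(out) <- ids
  out
}

read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.erg_study_report <- function(x, ...) {
  cat(sprintf("<erg_study_report> %d subjects, %d parameters, config %s\n",
              nrow(x$subjects),
              length(unique(x$features$parameter)),
              x$provenance$config_hash))
  sig <- x$association$parameter[which(x$association$significant)]
  cat("  significant at P < 0.05:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
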