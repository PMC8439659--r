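#' Default pipeline configuration
#'
#' All parameters default to the analysis' canonical values: smoothing
#' sigma 0.83 s, derivative width 2.3 s, velocity-derivative sigma 0.5 s,
#' middle-40% test split, family alpha 0.05 with the |rho| >= 0.4 floor,
#' acceleration-penalty weight mu = 10, L1 ratio 0.01, and the 90%
#' threshold defining N90.
#'
#' @param seed integer seed used by every random stage.
#' @param ... overrides for any top-level entry (lists are replaced, not
#'   merged).
#' @return named list of class \code{run_config}.
#' @export
default_run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    synth = list(duration_s = 480, volume_rate_hz = 6, n_neurons = 60,
                 signal_gain_global = 1),
    stages = list(synth = TRUE, preprocess = TRUE, behavior = FALSE,
                  tuning = TRUE, decode = TRUE, popstruct = FALSE),
    preprocess = list(smooth_sigma_s = 0.83, deriv_width_s = 2.3,
                      bleach_min_r2 = 0.1),
    tuning = list(M = 500, family_alpha = 0.05, rho_min = 0.4),
    decode = list(lambda_grid = 10^seq(-3, 6, length.out = 30),
                  n90_frac = 0.9, mu = 10, l1_ratio = 0.01),
    output_dir = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order: synthetic-data generation
#' (or a user-supplied recording + behavior), preprocessing, optional
#' behavior re-extraction from centerlines, tuning analysis, decoding of
#' velocity and curvature (population, BSN, truncated-model/N90), and —
#' when the recording carries moving/immobile epochs — correlation
#' structure analysis. Every random stage consumes the config seed, so a
#' config reruns to identical results.
#'
#' @param config a \code{run_config} (see \code{\link{default_run_config}})
#'   or a path to a YAML file with the same structure.
#' @param recording optional \code{fluorescence_recording} to analyze
#'   instead of generating one.
#' @param behavior optional \code{behavior_trace} paired with
#'   \code{recording}.
#' @return list of class \code{run_report}: resolved \code{config},
#'   per-stage outputs, and a flat \code{summary} of headline numbers
#'   (decoder and BSN RMS-squared per target, N90s, intersection size,
#'   tuning counts, Fano factor). If \code{config$output_dir} is set, the
#'   report summary and QC/tuning/prediction tables are written there.
#' @export
run_pipeline <- function(config = default_run_config(), recording = NULL,
                         behavior = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(!is.null(config$seed))
  st <- config$stages
  report <- list(config = config)

  if (is.null(recording)) {
    if (!isTRUE(st$synth)) stop("stage 'synth' disabled and no recording given")
    scfg <- do.call(synth_config, c(config$synth, list(seed = config$seed)))
    beh <- generate_behavior(scfg)
    gen <- generate_recording(beh, scfg)
    recording <- gen$recording
    behavior <- beh$behavior
    report$truth <- gen$truth
  }
  if (is.null(behavior)) stop("behavior trace required with a user recording")

  if (!isTRUE(st$preprocess)) stop("pipeline requires the preprocess stage")
  act <- do.call(preprocess_recording, c(list(recording), config$preprocess))
  report$activity <- act
  fano <- tryCatch(fano_gcamp(recording$G, recording$valid_mask),
                   error = function(e) NA_real_)

  if (isTRUE(st$tuning)) {
    report$tuning <- tuning_analysis(act, behavior, M = config$tuning$M,
                                     family_alpha = config$tuning$family_alpha,
                                     rho_min = config$tuning$rho_min,
                                     seed = config$seed)
  }

  if (isTRUE(st$decode)) {
    report$decode <- lapply(c(velocity = "velocity", curvature = "curvature"),
                            function(tg) decode_behavior(
                              act, behavior, tg,
                              lambda_grid = config$decode$lambda_grid))
    n90s <- vapply(report$decode, function(d) d$curve$N90, integer(1))
    inter <- tryCatch(length(intersect_n90(report$decode$velocity$curve,
                                           report$decode$curvature$curve)),
                      error = function(e) NA_integer_)
  }

  if (isTRUE(st$popstruct) && !is.null(act$epochs) &&
      all(c("moving", "immobile") %in% act$epochs$name)) {
    ep <- act$epochs
    mw <- unlist(ep[ep$name == "moving", c("start_s", "end_s")])
    iw <- unlist(ep[ep$name == "immobile", c("start_s", "end_s")])
    report$popstruct <- list(
      rho_moving = correlation_matrix(act, mw, epoch_name = "moving"),
      rho_immobile = correlation_matrix(act, iw, epoch_name = "immobile"))
    report$popstruct$dissimilarity <- dissimilarity(
      report$popstruct$rho_moving, report$popstruct$rho_immobile)
  }

  summ <- list(fano_gcamp = fano)
  if (!is.null(report$tuning)) {
    summ$n_significant_tuning <- sum(report$tuning$significant)
    summ$bonferroni_threshold <- report$tuning$threshold_used[1]
  }
  if (!is.null(report$decode)) {
    for (tg in names(report$decode)) {
      d <- report$decode[[tg]]
      summ[[paste0("rms2_test_", tg)]] <- d$decoder$rms_r2_test
      summ[[paste0("rms2_train_", tg)]] <- d$decoder$rms_r2_train
      summ[[paste0("rms2_test_bsn_", tg)]] <- d$bsn$rms_r2_test
      summ[[paste0("n90_", tg)]] <- d$curve$N90
    }
    summ$n90_intersection <- inter
  }
  if (!is.null(report$popstruct))
    summ$dissimilarity_moving_vs_immobile <- report$popstruct$dissimilarity
  report$summary <- summ
  class(report) <- "run_report"

  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-32s %s\n", nm, format(x$summary[[nm]], digits = 4)))
  invisible(x)
}

#' Write the tables and summary of a pipeline run
#'
#' Layout: \code{report.json} (summary + resolved scalar config) at the
#' root, then \code{preprocess/qc.csv}, \code{tuning/tuning.csv} and
#' \code{decode/predictions_<target>.csv}.
#'
#' @param report a \code{run_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(summary = report$summary,
         config = report$config[setdiff(names(report$config), "stages")]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$activity)) {
    dir.create(file.path(dir, "preprocess"), showWarnings = FALSE)
    utils::write.csv(report$activity$qc,
                     file.path(dir, "preprocess", "qc.csv"), row.names = FALSE)
  }
  if (!is.null(report$tuning)) {
    dir.create(file.path(dir, "tuning"), showWarnings = FALSE)
    utils::write.csv(report$tuning, file.path(dir, "tuning", "tuning.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$decode)) {
    dir.create(file.path(dir, "decode"), showWarnings = FALSE)
    for (tg in names(report$decode)) {
      d <- report$decode[[tg]]
      y <- d$decoder$prediction
      utils::write.csv(
        data.frame(time_s = report$activity$time_s,
                   y_hat = y,
                   is_test = seq_along(y) %in% d$split$test),
        file.path(dir, "decode", sprintf("predictions_%s.csv", tg)),
        row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a pipeline config from YAML
#'
#' Entries present in the file override the defaults of
#' \code{\link{default_run_config}}; nested lists are merged one level
#' deep.
#'
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) stop("config must set a seed")
  cfg <- default_run_config(seed = user$seed)
  for (nm in setdiff(names(user), "seed")) {
    if (is.list(user[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}
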