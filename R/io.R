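#' Write a fluorescence recording to plain-text CSV files
#'
#' Layout under \code{dir}: \code{G.csv} and \code{R.csv} (neurons x time,
#' no headers), \code{mask.csv} (0/1), \code{time_s.csv}, \code{epochs.csv}
#' and optional \code{labels.csv}.
#'
#' @param rec a \code{fluorescence_recording}.
#' @param dir target directory.
#' @return invisibly, the directory.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "fluorescence_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(rec$G, file.path(dir, "G.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(rec$R, file.path(dir, "R.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(rec$valid_mask + 0L, file.path(dir, "mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(rec$time_s, file.path(dir, "time_s.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(rec$epochs))
    utils::write.csv(rec$epochs, file.path(dir, "epochs.csv"),
                     row.names = FALSE)
  if (!is.null(rec$neuron_labels))
    utils::write.table(rec$neuron_labels, file.path(dir, "labels.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a fluorescence recording written by \code{\link{write_recording}}
#'
#' @param dir directory holding the CSV layout.
#' @return a \code{fluorescence_recording}.
#' @export
read_recording <- function(dir) {
  G <- as.matrix(utils::read.csv(file.path(dir, "G.csv"), header = FALSE))
  R <- as.matrix(utils::read.csv(file.path(dir, "R.csv"), header = FALSE))
  mask <- as.matrix(utils::read.csv(file.path(dir, "mask.csv"),
                                    header = FALSE)) > 0
  time_s <- utils::read.csv(file.path(dir, "time_s.csv"), header = FALSE)[, 1]
  epochs <- NULL
  if (file.exists(file.path(dir, "epochs.csv")))
    epochs <- utils::read.csv(file.path(dir, "epochs.csv"),
                              stringsAsFactors = FALSE)
  labels <- NULL
  if (file.exists(file.path(dir, "labels.csv")))
    labels <- utils::read.csv(file.path(dir, "labels.csv"),
                              header = FALSE)[, 1]
  dimnames(G) <- dimnames(R) <- dimnames(mask) <- NULL
  fluorescence_recording(time_s, G, R, mask, labels, epochs)
}

#' Write a behavior trace as CSV
#'
#' Columns: time_s, velocity_mm_s, curvature_inv_mm.
#'
#' @param behavior a \code{behavior_trace}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_behavior <- function(behavior, path) {
  stopifnot(inherits(behavior, "behavior_trace"))
  utils::write.csv(data.frame(time_s = behavior$time_s,
                              velocity_mm_s = behavior$velocity,
                              curvature_inv_mm = behavior$curvature),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a behavior trace CSV
#'
#' @param path file written by \code{\link{write_behavior}}.
#' @return a \code{behavior_trace}.
#' @export
read_behavior <- function(path) {
  df <- utils::read.csv(path)
  behavior_trace(df$time_s, df$velocity_mm_s, df$curvature_inv_mm)
}

#' Serialize a fitted decoder to JSON
#'
#' Stores weights, intercept, penalty strength, feature scaling, split
#' indices, variant and scores; \code{\link{read_decoder}} restores an
#' object usable for prediction on matching features.
#'
#' @param decoder a \code{population_decoder}.
#' @param path JSON file path.
#' @return invisibly, the path.
#' @export
write_decoder <- function(decoder, path) {
  stopifnot(inherits(decoder, "population_decoder"))
  keep <- c("W", "W_F", "W_dFdt", "beta", "lambda", "feature_means",
            "feature_sds", "kept", "target", "split", "variant", "mu",
            "l1_ratio", "rms_r2_train", "rms_r2_test", "rms_r2_all")
  jsonlite::write_json(decoder[keep], path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a decoder serialized by \code{\link{write_decoder}}
#'
#' @param path JSON file path.
#' @return a \code{population_decoder} (without stored predictions).
#' @export
read_decoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$split <- lapply(obj$split, as.integer)
  structure(obj, class = "population_decoder")
}
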