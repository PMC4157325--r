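# --- detection streams -------------------------------------------------------

#' Write / read detection streams as CSV
#'
#' The CSV has the header `patch_id, timestamp_s, feeder_id, tag_id, species`.
#' A JSON sidecar (`<path>.meta.json`) records the logging interval, number
#' of feeders, species labels and — when supplied — the generator seed, so a
#' stream round-trips losslessly.
#'
#' @param stream A `detection_stream`.
#' @param path Output CSV path.
#' @param seed Optional generator seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_detections <- function(stream, path, seed = NULL) {
  stopifnot(inherits(stream, "detection_stream"))
  write.csv(as.data.frame(stream), path, row.names = FALSE, quote = FALSE)
  meta <- list(logging_interval = attr(stream, "logging_interval"),
               n_feeders = attr(stream, "n_feeders"),
               species_labels = attr(stream, "species_labels"),
               seed = seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    as_detection_stream(x, logging_interval = meta$logging_interval,
                        n_feeders = meta$n_feeders,
                        species_labels = meta$species_labels)
  } else {
    as_detection_stream(x)
  }
}

# --- movement events ---------------------------------------------------------

#' Write / read movement events as CSV
#'
#' One row per event with the occupancy vectors flattened to per-feeder
#' columns; window, logging interval and feeder count go to a JSON sidecar.
#'
#' @param events A `movement_events` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "movement_events"))
  write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  meta <- list(n_feeders = attr(events, "n_feeders"),
               window = attr(events, "window"),
               logging_interval = attr(events, "logging_interval"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("missing events sidecar ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  new_movement_events(x, n_feeders = meta$n_feeders, window = meta$window,
                      logging_interval = meta$logging_interval)
}

# --- fits and curves ---------------------------------------------------------

#' Serialize a model fit to JSON
#'
#' Writes point estimates, profile CIs (when present), log-likelihoods,
#' event count, variant, likelihood convention and convergence diagnostics.
#'
#' @param fit A `flock_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "flock_fit"))
  p <- fit$params
  est <- if (p$variant == "single") {
    list(s = p$s, k = p$k, a = p$a)
  } else {
    list(s_c = p$s_c, s_h = p$s_h, k = p$k, a = p$a)
  }
  out <- list(
    variant = fit$variant,
    convention = fit$convention,
    context = fit$context,
    species_filter = fit$species_filter,
    estimates = est,
    ci = fit$ci,
    log_likelihood = fit$log_likelihood,
    null_log_likelihood = fit$null_log_likelihood,
    n_events = fit$n_events,
    converged = fit$converged,
    iterations = fit$iterations
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a density curve (with optional envelope and TASP columns) as CSV
#'
#' @param curve A `density_curve`.
#' @param path Output CSV path.
#' @param envelope Optional envelope table from [jackknife_envelope()].
#' @param tasp Optional `tasp_curve` evaluated at the bin mids.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curve, path, envelope = NULL, tasp = NULL) {
  stopifnot(inherits(curve, "density_curve"))
  out <- as.data.frame(curve)
  if (!is.null(envelope)) {
    out$env_leave_lo <- envelope$leave_lo
    out$env_leave_hi <- envelope$leave_hi
    out$env_arrive_lo <- envelope$arrive_lo
    out$env_arrive_hi <- envelope$arrive_hi
  }
  if (!is.null(tasp)) {
    out$tasp_leave <- tasp$p_leave
    out$tasp_arrive <- tasp$p_arrive
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a choice surface as CSV (grid plus contour polylines)
#'
#' @param surface A `flock_surface` from [choice_surface()].
#' @param path Output CSV path for the grid; the P = 0.25 contour polylines
#'   go to `<path base>_contour.csv`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "flock_surface"))
  write.csv(surface$grid, path, row.names = FALSE, quote = FALSE)
  if (length(surface$contour_25)) {
    cont <- do.call(rbind, lapply(seq_along(surface$contour_25), function(i) {
      cbind(segment = i, surface$contour_25[[i]])
    }))
    write.csv(cont, sub("\\.csv$", "_contour.csv", path), row.names = FALSE,
              quote = FALSE)
  }
  invisible(path)
}
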