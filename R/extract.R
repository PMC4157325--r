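#' Merge per-feeder detection streams
#'
#' Combines the records from each feeder of one patch into a single stream,
#' sorted by (timestamp, feeder, tag), with duplicate records within one
#' (bird, feeder, interval) collapsed to one.
#'
#' @param streams A list of `detection_stream` objects (or a single one), all
#'   from the same patch.
#' @return A merged, de-duplicated, sorted `detection_stream`.
#' @export
merge_streams <- function(streams) {
  if (inherits(streams, "detection_stream")) streams <- list(streams)
  stopifnot(length(streams) >= 1L)
  interval <- attr(streams[[1L]], "logging_interval")
  nf <- attr(streams[[1L]], "n_feeders")
  species <- unique(unlist(lapply(streams, attr, "species_labels")))
  x <- do.call(rbind, lapply(streams, as.data.frame))
  if (nrow(x) && length(unique(x$patch_id)) > 1L) {
    stop("mixed patch ids: streams must come from a single patch",
         call. = FALSE)
  }
  x <- unique(x)
  as_detection_stream(x, logging_interval = interval, n_feeders = nf,
                      species_labels = species)
}

#' Extract within-patch movement events
#'
#' Scans each bird's detection sequence in a merged stream and emits one
#' movement event per pair of consecutive detections at *different* feeders
#' whose gap does not exceed `gap_threshold` (birds with longer gaps are
#' treated as having left the patch in between). For each event the occupancy
#' of every feeder is computed over the half-open window
#' `[t - window, t)` before the departure and before the arrival, counting
#' distinct birds per feeder with the focal bird removed, split into
#' conspecifics and heterospecifics relative to the focal species, and
#' converted to relative densities `rho` (per-feeder count divided by the
#' patch total). Windows with a zero patch total get undefined (`NA`)
#' densities and are flagged via `rho_defined`.
#'
#' When a bird is logged at two feeders within the same interval, records are
#' ordered by feeder id, so the lower-numbered feeder provides the departure
#' context and the other the arrival (a documented tie-break); such events
#' have a zero gap.
#'
#' @param stream A merged, sorted `detection_stream`.
#' @param gap_threshold Maximum gap (s) between successive detections for the
#'   bird to count as having remained in the patch (default 240).
#' @param window Occupancy window length in seconds (default 30, i.e. two
#'   15 s logging steps); must be a multiple of the logging interval.
#' @return A `movement_events` data frame: one row per event with focal tag
#'   and species, origin/destination feeders, departure/arrival times,
#'   flattened per-feeder occupancy (`dep_nc_*`, `dep_nh_*`, `dep_rho_*` and
#'   the `arr_*` equivalents), window totals, `rho_leave`, `rho_arrive` and
#'   `rho_defined`.
#' @export
extract_movements <- function(stream, gap_threshold = 240, window = 30) {
  stopifnot(inherits(stream, "detection_stream"))
  interval <- attr(stream, "logging_interval")
  nf <- attr(stream, "n_feeders")
  if (is.unsorted(stream$timestamp_s)) {
    stop("stream must be sorted by timestamp (use merge_streams())",
         call. = FALSE)
  }
  if (window %% interval != 0) {
    stop("`window` must be a multiple of the logging interval", call. = FALSE)
  }
  det <- unique(as.data.frame(stream))
  if (nrow(det) == 0L) return(empty_events(nf, window, interval))

  # per-bird consecutive detection pairs
  ord <- order(det$tag_id, det$timestamp_s, det$feeder_id)
  d <- det[ord, ]
  n <- nrow(d)
  same_bird <- d$tag_id[-1L] == d$tag_id[-n]
  dt <- d$timestamp_s[-1L] - d$timestamp_s[-n]
  moved <- d$feeder_id[-1L] != d$feeder_id[-n]
  is_event <- same_bird & moved & dt >= 0 & dt <= gap_threshold
  idx <- which(is_event)
  if (!length(idx)) return(empty_events(nf, window, interval))

  focal_tag <- d$tag_id[idx]
  focal_species <- d$species[idx]
  from <- d$feeder_id[idx]
  to <- d$feeder_id[idx + 1L]
  t_dep <- d$timestamp_s[idx]
  t_arr <- d$timestamp_s[idx + 1L]

  lookup <- interval_index(det, interval)
  dep <- occupancy_windows(det, lookup, t_dep, window, interval, focal_tag,
                           focal_species, nf)
  arr <- occupancy_windows(det, lookup, t_arr, window, interval, focal_tag,
                           focal_species, nf)

  ev <- data.frame(
    patch_id = d$patch_id[idx],
    focal_tag = focal_tag,
    focal_species = focal_species,
    from_feeder = from,
    to_feeder = to,
    t_depart = t_dep,
    t_arrive = t_arr,
    stringsAsFactors = FALSE
  )
  ev <- cbind(ev, flatten_occ(dep, "dep", nf), flatten_occ(arr, "arr", nf))
  ev$rho_leave <- dep$rho[cbind(seq_along(from), from)]
  ev$rho_arrive <- arr$rho[cbind(seq_along(to), to)]
  ev$rho_defined <- dep$total > 0 & arr$total > 0
  new_movement_events(ev, n_feeders = nf, window = window,
                      logging_interval = interval)
}

# Row indices of the detection table grouped by logging-interval id.
interval_index <- function(det, interval) {
  split(seq_len(nrow(det)), det$timestamp_s %/% interval)
}

# Occupancy (focal removed) of every feeder over [t - window, t) for a
# vector of events. Returns matrices nc, nh, rho (n_events x n_feeders) and
# the patch total per event.
occupancy_windows <- function(det, lookup, t, window, interval, focal_tag,
                              focal_species, nf) {
  n <- length(t)
  nc <- matrix(0L, n, nf)
  nh <- matrix(0L, n, nf)
  w_steps <- window %/% interval
  for (i in seq_len(n)) {
    ids <- as.character((t[i] %/% interval - w_steps):(t[i] %/% interval - 1L))
    rows <- unlist(lookup[ids], use.names = FALSE)
    if (!length(rows)) next
    sub <- det[rows, c("feeder_id", "tag_id", "species")]
    sub <- sub[sub$tag_id != focal_tag[i], , drop = FALSE]
    if (!nrow(sub)) next
    sub <- unique(sub)
    con <- sub$species == focal_species[i]
    nc[i, ] <- tabulate(sub$feeder_id[con], nbins = nf)
    nh[i, ] <- tabulate(sub$feeder_id[!con], nbins = nf)
  }
  tot <- rowSums(nc) + rowSums(nh)
  rho <- (nc + nh) / ifelse(tot > 0, tot, NA_real_)
  list(nc = nc, nh = nh, rho = rho, total = tot)
}

flatten_occ <- function(occ, prefix, nf) {
  out <- data.frame(occ$nc, occ$nh, occ$rho)
  names(out) <- c(sprintf("%s_nc_%d", prefix, seq_len(nf)),
                  sprintf("%s_nh_%d", prefix, seq_len(nf)),
                  sprintf("%s_rho_%d", prefix, seq_len(nf)))
  out[[sprintf("%s_total", prefix)]] <- occ$total
  out
}

new_movement_events <- function(df, n_feeders, window, logging_interval) {
  rownames(df) <- NULL
  structure(df,
            n_feeders = as.integer(n_feeders),
            window = as.integer(window),
            logging_interval = as.integer(logging_interval),
            class = c("movement_events", "data.frame"))
}

empty_events <- function(nf, window, interval) {
  base <- data.frame(
    patch_id = character(0), focal_tag = character(0),
    focal_species = character(0), from_feeder = integer(0),
    to_feeder = integer(0), t_depart = numeric(0), t_arrive = numeric(0),
    stringsAsFactors = FALSE
  )
  occ0 <- list(nc = matrix(0L, 0, nf), nh = matrix(0L, 0, nf),
               rho = matrix(numeric(0), 0, nf), total = numeric(0))
  ev <- cbind(base, flatten_occ(occ0, "dep", nf), flatten_occ(occ0, "arr", nf))
  ev$rho_leave <- numeric(0)
  ev$rho_arrive <- numeric(0)
  ev$rho_defined <- logical(0)
  new_movement_events(ev, nf, window, interval)
}

#' Estimate the patch-residency gap threshold from inter-detection gaps
#'
#' Movement (intravisit) gaps and between-visit gaps form two regimes in the
#' distribution of a bird's inter-detection intervals. This heuristic fits a
#' two-component exponential mixture by EM and returns the gap at which the
#' component responsibilities cross 0.5 — the point where the distribution
#' changes from the peak to the tail — rounded to logging-interval
#' resolution. The fit is deterministic (moment-based initialization, no
#' random starts). When in doubt, the conventional default threshold of
#' 240 s is a safe choice.
#'
#' @param gaps Numeric vector of positive inter-detection gaps in seconds
#'   (at least 50).
#' @param logging_interval Resolution to round the threshold to (default 15).
#' @param max_iter,tol EM iteration controls.
#' @return Threshold in seconds (multiple of `logging_interval`), with
#'   attributes `rates`, `weights` and `crossing` (the unrounded crossing).
#' @export
estimate_gap_threshold <- function(gaps, logging_interval = 15L,
                                   max_iter = 500L, tol = 1e-8) {
  gaps <- gaps[is.finite(gaps)]
  if (length(gaps) < 50L || any(gaps <= 0)) {
    stop("need at least 50 positive gaps; with fewer, use the 240 s default",
         call. = FALSE)
  }
  if (stats::sd(gaps) < .Machine$double.eps * mean(gaps)) {
    stop("degenerate gap distribution (all gaps identical): no mixture to fit; use the 240 s default",
         call. = FALSE)
  }
  # moment-based init: fast component from the lower half, slow from the tail
  med <- stats::median(gaps)
  r1 <- 1 / mean(gaps[gaps <= med])
  hi <- gaps[gaps > stats::quantile(gaps, 0.75)]
  r2 <- 1 / mean(hi)
  if (!is.finite(r2) || r2 >= r1) r2 <- r1 / 10
  w1 <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    l1 <- log(w1) + stats::dexp(gaps, r1, log = TRUE)
    l2 <- log(1 - w1) + stats::dexp(gaps, r2, log = TRUE)
    m <- pmax(l1, l2)
    den <- m + log(exp(l1 - m) + exp(l2 - m))
    g1 <- exp(l1 - den)
    ll <- sum(den)
    w1 <- mean(g1)
    r1 <- sum(g1) / sum(g1 * gaps)
    r2 <- sum(1 - g1) / sum((1 - g1) * gaps)
    if (r1 < r2) {  # keep component 1 the fast one
      tmp <- r1; r1 <- r2; r2 <- tmp
      w1 <- 1 - w1
    }
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  if (!is.finite(r1) || !is.finite(r2) || r1 - r2 < 1e-12 ||
      w1 * r1 <= (1 - w1) * r2) {
    stop("mixture fit degenerate: no peak-to-tail crossing; use the 240 s default",
         call. = FALSE)
  }
  crossing <- log((w1 * r1) / ((1 - w1) * r2)) / (r1 - r2)
  out <- max(logging_interval,
             round(crossing / logging_interval) * logging_interval)
  structure(out, rates = c(fast = r1, slow = r2),
            weights = c(fast = w1, slow = 1 - w1), crossing = crossing)
}

#' Filter movement events
#'
#' Order-preserving subset of a `movement_events` table.
#'
#' @param events A `movement_events` data frame.
#' @param predicate Either a logical vector of length `nrow(events)` or a
#'   function taking the events data frame and returning such a vector
#'   (e.g. `function(e) e$focal_species == "great_tit"`, or a first-day
#'   restriction `function(e) e$t_depart < min(e$t_depart) + 86400`).
#' @return The filtered `movement_events`, attributes preserved.
#' @export
filter_events <- function(events, predicate) {
  stopifnot(inherits(events, "movement_events"))
  keep <- if (is.function(predicate)) predicate(events) else predicate
  stopifnot(is.logical(keep), length(keep) == nrow(events))
  keep[is.na(keep)] <- FALSE
  new_movement_events(as.data.frame(events)[keep, , drop = FALSE],
                      n_feeders = attr(events, "n_feeders"),
                      window = attr(events, "window"),
                      logging_interval = attr(events, "logging_interval"))
}
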