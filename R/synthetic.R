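#' Default species pool for synthetic patches
#'
#' Five woodland passerines with strongly skewed abundances, matching the
#' community composition typical of winter mixed-species tit flocks: blue
#' tit, great tit, marsh tit, coal tit and nuthatch.
#'
#' @return Named integer vector of tagged-pool sizes per species.
#' @export
default_species_pool <- function() {
  c(blue_tit = 825L, great_tit = 813L, marsh_tit = 133L, coal_tit = 101L,
    nuthatch = 32L)
}

#' Default species activity weights
#'
#' Relative shares of feeder activity per species (blue tit 34.3%, great tit
#' 32.5%, marsh tit 16.4%, coal tit 11.2%, nuthatch 6.0%), renormalized to
#' sum to exactly 1.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_species_weights <- function() {
  w <- c(blue_tit = 0.343, great_tit = 0.325, marsh_tit = 0.164,
         coal_tit = 0.112, nuthatch = 0.060)
  w / sum(w)
}

#' Configuration for the synthetic detection-stream generator
#'
#' Describes a single monitored patch: a square of identical feeders with
#' RFID antennae that log one record per tagged bird per feeder per logging
#' interval. Flocks arrive as a homogeneous Poisson process; flock sizes are
#' drawn from a (truncated) negative binomial, reflecting the overdispersed,
#' bursty visits seen at woodland feeding stations. Within a visit each
#' present bird re-evaluates its feeder each interval with probability
#' `per_step_move_probability`, choosing among all feeders (staying included)
#' with the social decision rule in `generator_params`, and leaves the patch
#' with per-interval probability `leave_patch_hazard`.
#'
#' @param species_labels Character vector of species names.
#' @param species_weights Relative abundance per species; must sum to 1
#'   (within 1e-8) with all weights >= 0.
#' @param n_individuals Number of tagged birds in the pool.
#' @param species_pool Optional named integer vector of per-species pool
#'   sizes; must sum to `n_individuals`. When `NULL`, pool species are drawn
#'   from `species_weights`.
#' @param n_feeders Number of feeders in the patch (>= 2; default 4).
#' @param logging_interval Seconds between logged scans (default 15).
#' @param session_length Session length in seconds; must be a multiple of
#'   `logging_interval`. Default 28800 (one 8 h winter foraging day).
#' @param flock_arrival_rate Expected flock visits per hour (default 6).
#' @param flock_size_distribution List with `name` (`"nbinom"` or
#'   `"poisson"`), its parameters (`mu`, `size` for nbinom; `lambda` for
#'   poisson) and a lower truncation `min`. Default negative binomial with
#'   mean 25, dispersion 5, truncated at 2 — overdispersed patch flocks of a
#'   few to several tens of birds.
#' @param per_step_move_probability Probability a present bird re-evaluates
#'   its feeder each interval (default 0.1).
#' @param leave_patch_hazard Per-interval probability a present bird departs
#'   the patch (default 0.025, i.e. mean visit ~10 min).
#' @param feeder_clumping Dirichlet concentration per feeder used when
#'   allocating a freshly drawn flock across feeders; values < 1 produce the
#'   strong clumping characteristic of flocks (default 0.5).
#' @param generator_params [decision_params()] driving within-patch choices
#'   (a single rule for all species, or a named list of rules by species with
#'   an optional `.default`). Default a moderately social single rule
#'   (`s = 4, k = 0.01, a = 10`), of the magnitude typical for parid flocks.
#' @param patch_id Patch identifier recorded in every detection.
#' @param seed Integer seed; identical config + seed reproduces the stream
#'   bit for bit.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(species_labels = names(default_species_pool()),
                             species_weights = default_species_weights(),
                             n_individuals = 1904L,
                             species_pool = default_species_pool(),
                             n_feeders = 4L,
                             logging_interval = 15L,
                             session_length = 28800L,
                             flock_arrival_rate = 6,
                             flock_size_distribution = list(
                               name = "nbinom", mu = 25, size = 5, min = 2),
                             per_step_move_probability = 0.1,
                             leave_patch_hazard = 0.025,
                             feeder_clumping = 0.5,
                             generator_params = decision_params(
                               s = 4, k = 0.01, a = 10),
                             patch_id = "P1",
                             seed = 1L) {
  if (length(species_labels) < 1L) {
    stop("invalid `species_labels`: need at least one species", call. = FALSE)
  }
  if (length(species_weights) != length(species_labels)) {
    stop("invalid `species_weights`: length must match `species_labels`",
         call. = FALSE)
  }
  if (any(species_weights < 0) || abs(sum(species_weights) - 1) > 1e-8) {
    stop("invalid `species_weights`: must be >= 0 and sum to 1", call. = FALSE)
  }
  species_weights <- species_weights / sum(species_weights)
  if (n_individuals < 0) {
    stop("invalid `n_individuals`: must be >= 0", call. = FALSE)
  }
  if (!is.null(species_pool)) {
    if (length(species_pool) != length(species_labels) ||
        sum(species_pool) != n_individuals) {
      stop("invalid `species_pool`: must have one count per species summing to `n_individuals`",
           call. = FALSE)
    }
  }
  if (n_feeders < 2) stop("invalid `n_feeders`: must be >= 2", call. = FALSE)
  if (logging_interval <= 0 || session_length %% logging_interval != 0) {
    stop("invalid `session_length`: must be a positive multiple of `logging_interval`",
         call. = FALSE)
  }
  if (flock_arrival_rate < 0) {
    stop("invalid `flock_arrival_rate`: must be >= 0", call. = FALSE)
  }
  if (per_step_move_probability < 0 || per_step_move_probability > 1) {
    stop("invalid `per_step_move_probability`: must be in [0, 1]", call. = FALSE)
  }
  if (leave_patch_hazard < 0 || leave_patch_hazard > 1) {
    stop("invalid `leave_patch_hazard`: must be in [0, 1]", call. = FALSE)
  }
  if (feeder_clumping <= 0) {
    stop("invalid `feeder_clumping`: must be > 0", call. = FALSE)
  }
  structure(
    list(species_labels = species_labels,
         species_weights = as.numeric(species_weights),
         n_individuals = as.integer(n_individuals),
         species_pool = species_pool,
         n_feeders = as.integer(n_feeders),
         logging_interval = as.integer(logging_interval),
         session_length = as.integer(session_length),
         flock_arrival_rate = flock_arrival_rate,
         flock_size_distribution = flock_size_distribution,
         per_step_move_probability = per_step_move_probability,
         leave_patch_hazard = leave_patch_hazard,
         feeder_clumping = feeder_clumping,
         generator_params = generator_params,
         patch_id = patch_id,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

draw_flock_sizes <- function(dist, n) {
  if (n == 0L) return(integer(0))
  lo <- dist$min %||% 1L
  draw <- switch(dist$name,
    nbinom = function(m) stats::rnbinom(m, mu = dist$mu, size = dist$size),
    poisson = function(m) stats::rpois(m, lambda = dist$lambda),
    stop(sprintf("unknown flock size distribution '%s'", dist$name),
         call. = FALSE)
  )
  out <- draw(n)
  while (any(out < lo)) {
    idx <- out < lo
    out[idx] <- draw(sum(idx))
  }
  out
}

# Resolve per-species decision rules: returns a named list keyed by species
# label, falling back to a shared rule (or `.default`).
resolve_params_by_species <- function(params, species_labels) {
  if (inherits(params, "flock_params")) {
    return(setNames(rep(list(params), length(species_labels)), species_labels))
  }
  stopifnot(is.list(params))
  default <- params[[".default"]]
  out <- lapply(species_labels, function(sp) {
    p <- params[[sp]] %||% default
    if (is.null(p)) {
      stop(sprintf("no decision rule for species '%s' and no `.default`", sp),
           call. = FALSE)
    }
    p
  })
  setNames(out, species_labels)
}

#' Generate a synthetic RFID detection stream
#'
#' Simulates a session at a multi-feeder patch under the configured flock
#' arrival process and within-patch decision rule, and logs one record per
#' present bird per feeder per logging interval (detection is treated as
#' complete). The result has the structure of merged field data: bursty
#' multi-species flock visits, birds freely entering and leaving the patch,
#' and movement decisions driven by the configured social rule.
#'
#' @param config A [synthetic_config()].
#' @return A `detection_stream`: data frame with columns `patch_id`,
#'   `timestamp_s`, `feeder_id`, `tag_id`, `species`, sorted by
#'   (timestamp, feeder, tag), with attributes `logging_interval`,
#'   `n_feeders` and `species_labels`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::local_seed(config$seed)

  n_sp <- length(config$species_labels)
  nf <- config$n_feeders
  n <- config$n_individuals
  if (n == 0L) {
    return(empty_stream(config))
  }
  # assign species to the tagged pool
  if (!is.null(config$species_pool)) {
    sp_idx <- rep(seq_len(n_sp), times = config$species_pool)
  } else {
    sp_idx <- sample(seq_len(n_sp), n, replace = TRUE,
                     prob = config$species_weights)
  }
  tag_ids <- sprintf("B%05d", seq_len(n))

  rules <- resolve_params_by_species(config$generator_params,
                                     config$species_labels)
  interval <- config$logging_interval
  steps <- seq(0L, config$session_length - interval, by = interval)
  p_arr_per_step <- config$flock_arrival_rate * interval / 3600

  feeder_of <- rep(NA_integer_, n)   # NA = not in patch
  recs <- vector("list", length(steps))

  for (si in seq_along(steps)) {
    t <- steps[si]
    present <- which(!is.na(feeder_of))

    # departures
    if (length(present)) {
      leaving <- present[runif(length(present)) < config$leave_patch_hazard]
      feeder_of[leaving] <- NA_integer_
    }

    # flock arrivals: each arriving bird picks a feeder by the decision rule
    n_flocks <- rpois(1L, p_arr_per_step)
    if (n_flocks > 0L) {
      sizes <- draw_flock_sizes(config$flock_size_distribution, n_flocks)
      for (fs in sizes) {
        absent <- which(is.na(feeder_of))
        if (!length(absent)) break
        joiners <- if (length(absent) == 1L) absent else {
          sample(absent, min(fs, length(absent)))
        }
        for (b in joiners) {
          cnts <- occupancy_by_species(feeder_of, sp_idx, nf, n_sp)
          nc <- cnts[sp_idx[b], ]
          nh <- colSums(cnts) - nc
          pr <- score_matrix(rules[[config$species_labels[sp_idx[b]]]],
                             rbind(nc), rbind(nh))[1L, ]
          feeder_of[b] <- sample.int(nf, 1L, prob = pr)
        }
      }
    }

    # within-patch re-evaluation (synchronous, based on start-of-step state)
    present <- which(!is.na(feeder_of))
    if (length(present)) {
      movers <- present[runif(length(present)) <
                          config$per_step_move_probability]
      if (length(movers)) {
        cnts <- occupancy_by_species(feeder_of, sp_idx, nf, n_sp)
        tot <- colSums(cnts)
        new_feeder <- integer(length(movers))
        for (j in seq_along(movers)) {
          b <- movers[j]
          nc <- cnts[sp_idx[b], ]
          nc[feeder_of[b]] <- nc[feeder_of[b]] - 1L  # focal removed
          nh <- tot - cnts[sp_idx[b], ]
          pr <- score_matrix(rules[[config$species_labels[sp_idx[b]]]],
                             rbind(nc), rbind(nh))[1L, ]
          new_feeder[j] <- sample.int(nf, 1L, prob = pr)
        }
        feeder_of[movers] <- new_feeder
      }
    }

    # log one record per present bird
    present <- which(!is.na(feeder_of))
    if (length(present)) {
      recs[[si]] <- data.frame(
        patch_id = config$patch_id,
        timestamp_s = t,
        feeder_id = feeder_of[present],
        tag_id = tag_ids[present],
        species = config$species_labels[sp_idx[present]],
        stringsAsFactors = FALSE
      )
    }
  }

  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out)) return(empty_stream(config))
  as_detection_stream(out, logging_interval = interval, n_feeders = nf,
                      species_labels = config$species_labels)
}

occupancy_by_species <- function(feeder_of, sp_idx, nf, n_sp) {
  present <- which(!is.na(feeder_of))
  m <- matrix(0L, nrow = n_sp, ncol = nf)
  if (length(present)) {
    tb <- table(factor(sp_idx[present], levels = seq_len(n_sp)),
                factor(feeder_of[present], levels = seq_len(nf)))
    m <- matrix(as.integer(tb), nrow = n_sp, ncol = nf)
  }
  m
}

empty_stream <- function(config) {
  as_detection_stream(
    data.frame(patch_id = character(0), timestamp_s = integer(0),
               feeder_id = integer(0), tag_id = character(0),
               species = character(0), stringsAsFactors = FALSE),
    logging_interval = config$logging_interval,
    n_feeders = config$n_feeders,
    species_labels = config$species_labels
  )
}

#' Coerce a data frame to a detection stream
#'
#' @param x Data frame with columns `patch_id`, `timestamp_s`, `feeder_id`,
#'   `tag_id`, `species`.
#' @param logging_interval Logging interval in seconds.
#' @param n_feeders Number of feeders in the patch.
#' @param species_labels Optional species labels (defaults to those present).
#' @return The data frame, sorted by (timestamp, feeder, tag), with class
#'   `detection_stream`.
#' @export
as_detection_stream <- function(x, logging_interval = 15L, n_feeders = 4L,
                                species_labels = NULL) {
  need <- c("patch_id", "timestamp_s", "feeder_id", "tag_id", "species")
  if (!all(need %in% names(x))) {
    stop("detection stream needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) && any(x$timestamp_s %% logging_interval != 0)) {
    stop("timestamps must be multiples of the logging interval", call. = FALSE)
  }
  x <- x[order(x$timestamp_s, x$feeder_id, x$tag_id), need, drop = FALSE]
  rownames(x) <- NULL
  structure(x,
            logging_interval = as.integer(logging_interval),
            n_feeders = as.integer(n_feeders),
            species_labels = species_labels %||% sort(unique(x$species)),
            class = c("detection_stream", "data.frame"))
}

#' Sample a flock snapshot
#'
#' Draws one instantaneous patch configuration (per-feeder, per-species bird
#' counts). From a detection stream, the snapshot is drawn uniformly from the
#' set of occupied logging intervals; from a [synthetic_config()], a fresh
#' flock is drawn from the configured flock-size distribution, species
#' weights and feeder-clumping allocation.
#'
#' @param source A `detection_stream` or a [synthetic_config()].
#' @param seed Optional integer seed.
#' @return A `flock_snapshot`: list with `counts` (n_feeders x n_species
#'   integer matrix), `species` labels and `timestamp` (NA for de novo
#'   draws).
#' @export
sample_flock_snapshot <- function(source, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (inherits(source, "detection_stream")) {
    if (nrow(source) == 0L) stop("no occupied intervals", call. = FALSE)
    species <- attr(source, "species_labels")
    nf <- attr(source, "n_feeders")
    ts <- unique(source$timestamp_s)
    t <- if (length(ts) == 1L) ts else sample(ts, 1L)
    sub <- source[source$timestamp_s == t, , drop = FALSE]
    sub <- unique(sub[, c("feeder_id", "tag_id", "species")])
    counts <- table(factor(sub$feeder_id, levels = seq_len(nf)),
                    factor(sub$species, levels = species))
    counts <- matrix(as.integer(counts), nrow = nf,
                     dimnames = list(NULL, species))
    return(structure(list(counts = counts, species = species, timestamp = t),
                     class = "flock_snapshot"))
  }
  stopifnot(inherits(source, "synthetic_config"))
  species <- source$species_labels
  nf <- source$n_feeders
  size <- draw_flock_sizes(source$flock_size_distribution, 1L)
  sp <- sample(seq_along(species), size, replace = TRUE,
               prob = source$species_weights)
  p <- rgamma(nf, shape = source$feeder_clumping)
  p <- p / sum(p)
  fd <- sample.int(nf, size, replace = TRUE, prob = p)
  counts <- table(factor(fd, levels = seq_len(nf)),
                  factor(sp, levels = seq_along(species)))
  counts <- matrix(as.integer(counts), nrow = nf,
                   dimnames = list(NULL, species))
  structure(list(counts = counts, species = species, timestamp = NA_real_),
            class = "flock_snapshot")
}

#' @export
print.flock_snapshot <- function(x, ...) {
  cat("Flock snapshot (", sum(x$counts), " birds)\n", sep = "")
  m <- x$counts
  rownames(m) <- paste0("F", seq_len(nrow(m)))
  print(m)
  invisible(x)
}

#' Pool of occupied-interval flock configurations
#'
#' Harvests every occupied logging interval of a detection stream as a
#' snapshot, for reuse as the flock source of [simulate_flocks()].
#'
#' @param stream A `detection_stream`.
#' @return List of `flock_snapshot` objects, one per occupied interval.
#' @export
snapshot_pool <- function(stream) {
  stopifnot(inherits(stream, "detection_stream"))
  if (nrow(stream) == 0L) stop("no occupied intervals", call. = FALSE)
  species <- attr(stream, "species_labels")
  nf <- attr(stream, "n_feeders")
  sub <- unique(stream[, c("timestamp_s", "feeder_id", "tag_id", "species")])
  by_t <- split(sub, sub$timestamp_s)
  lapply(by_t, function(d) {
    counts <- table(factor(d$feeder_id, levels = seq_len(nf)),
                    factor(d$species, levels = species))
    counts <- matrix(as.integer(counts), nrow = nf,
                     dimnames = list(NULL, species))
    structure(list(counts = counts, species = species,
                   timestamp = d$timestamp_s[1L]),
              class = "flock_snapshot")
  })
}
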