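# --- vectorized sampling helpers -------------------------------------------

# Row-wise categorical draw: P is an n x F matrix of non-negative weights,
# u uniform(0,1) draws of length n. Returns the chosen column per row.
sample_rows <- function(P, u) {
  n <- nrow(P)
  F <- ncol(P)
  UT <- upper.tri(matrix(0, F, F), diag = TRUE)
  cs <- P %*% UT                      # cs[i, j] = sum(P[i, 1:j])
  tot <- cs[, F]
  1L + rowSums(cs < u * tot)
}

# Row-wise multinomial allocation by sequential conditional binomials:
# n_vec[i] items allocated over F cells with probabilities P[i, ].
alloc_multinom <- function(n_vec, P) {
  n <- length(n_vec)
  F <- ncol(P)
  out <- matrix(0L, n, F)
  rem <- as.integer(n_vec)
  tail_p <- rowSums(P)
  for (f in seq_len(F - 1L)) {
    pcond <- P[, f] / tail_p
    pcond[!is.finite(pcond)] <- 0
    pcond <- pmin(pmax(pcond, 0), 1)
    x <- rbinom(n, rem, pcond)
    out[, f] <- x
    rem <- rem - x
    tail_p <- tail_p - P[, f]
  }
  out[, F] <- rem
  out
}

# Shared builder for movement_events tables from occupancy matrices (the
# departure and arrival contexts coincide when only the focal bird moved).
build_events_df <- function(patch_id, focal_tag, focal_species, from, to,
                            t_dep, t_arr, nc, nh, nf, window, interval) {
  tot <- rowSums(nc) + rowSums(nh)
  rho <- (nc + nh) / ifelse(tot > 0, tot, NA_real_)
  occ <- list(nc = nc, nh = nh, rho = rho, total = tot)
  n <- length(from)
  ev <- data.frame(
    patch_id = patch_id, focal_tag = focal_tag,
    focal_species = focal_species,
    from_feeder = as.integer(from), to_feeder = as.integer(to),
    t_depart = t_dep, t_arrive = t_arr,
    stringsAsFactors = FALSE
  )
  ev <- cbind(ev, flatten_occ(occ, "dep", nf), flatten_occ(occ, "arr", nf))
  ev$rho_leave <- rho[cbind(seq_len(n), from)]
  ev$rho_arrive <- rho[cbind(seq_len(n), to)]
  ev$rho_defined <- tot > 0
  new_movement_events(ev, n_feeders = nf, window = window,
                      logging_interval = interval)
}

# Per-species decision-rule coefficients on the log scale, for vectorized
# evaluation across mixed-species movers.
rule_coefs <- function(params, species_labels) {
  rules <- resolve_params_by_species(params, species_labels)
  t(vapply(rules, function(p) {
    if (p$variant == "single") {
      c(lsc = log(p$s), lsh = log(p$s), la = log(p$a), k = p$k)
    } else {
      c(lsc = log(p$s_c), lsh = log(p$s_h), la = log(p$a), k = p$k)
    }
  }, numeric(4)))
}

#' Simulate standalone movement decisions
#'
#' Generates independent within-patch movement decisions from the decision
#' rule, for parameter-recovery experiments: each decision consists of a
#' focal bird and a freshly drawn flock of flockmates (sizes from the
#' configured flock-size distribution, conspecific/heterospecific split from
#' the species weights, feeders allocated with the configured clumping), and
#' the destination feeder is sampled from the rule's choice probabilities.
#' Under the default `"conditional"` convention the choice is among the
#' non-origin feeders, so every decision is a movement; under
#' `"unconditional"` the focal may also stay, and only actual moves are
#' returned as events.
#'
#' @param params A [decision_params()] object, or a named list of them by
#'   species.
#' @param n_decisions Number of decisions to simulate.
#' @param config A [synthetic_config()] supplying flock sizes, species
#'   weights and feeder clumping.
#' @param focal_species Species making the decisions; `NULL` (default) draws
#'   the focal species per decision from the species weights.
#' @param seed Optional integer seed.
#' @param convention `"conditional"` (default) or `"unconditional"`.
#' @return A `movement_events` data frame (exactly `n_decisions` rows under
#'   the conditional convention).
#' @export
simulate_decisions <- function(params, n_decisions, config,
                               focal_species = NULL, seed = NULL,
                               convention = c("conditional", "unconditional")) {
  convention <- match.arg(convention)
  stopifnot(inherits(config, "synthetic_config"), n_decisions >= 1L)
  if (!is.null(seed)) withr::local_seed(seed)
  nf <- config$n_feeders
  interval <- config$logging_interval
  labels <- config$species_labels
  n <- as.integer(n_decisions)

  sizes <- draw_flock_sizes(config$flock_size_distribution, n)
  sp <- if (is.null(focal_species)) {
    sample(labels, n, replace = TRUE, prob = config$species_weights)
  } else {
    if (!focal_species %in% labels) {
      stop(sprintf("unknown focal species '%s'", focal_species), call. = FALSE)
    }
    rep(focal_species, n)
  }
  w_f <- config$species_weights[match(sp, labels)]
  n_others <- pmax(sizes - 1L, 0L)
  ncon_tot <- rbinom(n, n_others, w_f)
  nhet_tot <- n_others - ncon_tot

  G <- matrix(rgamma(n * nf, shape = config$feeder_clumping), n, nf)
  P <- G / rowSums(G)
  origin <- sample_rows(P, runif(n))
  NC <- alloc_multinom(ncon_tot, P)
  NH <- alloc_multinom(nhet_tot, P)

  coefs <- rule_coefs(params, labels)[sp, , drop = FALSE]
  k <- coefs[, "k"]
  ec <- NC * (1 + k) - k * rowSums(NC)
  eh <- NH * (1 + k) - k * rowSums(NH)
  S <- stats::plogis(ec * coefs[, "lsc"] + eh * coefs[, "lsh"] - coefs[, "la"])

  i <- seq_len(n)
  if (convention == "conditional") {
    S[cbind(i, origin)] <- 0
    dest <- sample_rows(S, runif(n))
    keep <- rep(TRUE, n)
  } else {
    dest <- sample_rows(S, runif(n))
    keep <- dest != origin
  }
  t_dep <- (i - 1) * interval
  ev <- build_events_df(
    patch_id = "simdec", focal_tag = sprintf("sim%06d", i),
    focal_species = sp, from = origin, to = dest,
    t_dep = t_dep, t_arr = t_dep + interval,
    nc = NC, nh = NH, nf = nf, window = 2L * interval, interval = interval
  )
  filter_events(ev, keep)
}

#' Agent-based replay of a decision rule over sampled flocks
#'
#' Replays a (fitted) decision rule in an agent-based simulation: each
#' simulated flock starts from a snapshot drawn from `flock_source`; at each
#' decision step one bird is selected uniformly at random and either remains
#' at its feeder or moves to another, sampling from the stay-included choice
#' distribution computed with its own presence removed from the occupancy.
#' Between-feeder moves are emitted as movement events (with synthetic
#' timestamps at one decision per logging interval) and can be analysed with
#' [empirical_density_curves()] exactly like extracted field or synthetic
#' data. The emitted occupancy context is the complete pre-move flock
#' configuration — the mover counted at its origin feeder — which is what
#' makes an asocial (`s = 1`) replay reproduce the theoretical asocial
#' prediction exactly; the mover's own presence is excluded only from the
#' counts its decision responds to. Default scale: 1000 flocks of 50
#' decisions each.
#'
#' @param params A [decision_params()], or a named list of them by species
#'   (each mover uses its own species' rule; a single object applies one rule
#'   to all).
#' @param flock_source A [synthetic_config()] (flocks drawn de novo), a list
#'   of `flock_snapshot`s (sampled with replacement), or a
#'   `detection_stream` (its occupied intervals are harvested first).
#' @param n_flocks Number of simulated flocks (default 1000).
#' @param n_decisions Decision steps per flock (default 50).
#' @param seed Optional integer seed.
#' @param logging_interval Seconds per decision step in the synthetic
#'   timestamps (default 15).
#' @return A `movement_events` data frame of all between-feeder moves.
#' @export
simulate_flocks <- function(params, flock_source, n_flocks = 1000L,
                            n_decisions = 50L, seed = NULL,
                            logging_interval = 15L) {
  stopifnot(n_flocks >= 1L, n_decisions >= 1L)
  if (!is.null(seed)) withr::local_seed(seed)
  src <- flock_source
  if (inherits(src, "detection_stream")) src <- snapshot_pool(src)

  if (inherits(src, "synthetic_config")) {
    labels <- src$species_labels
    nf <- src$n_feeders
    nsp <- length(labels)
    sizes <- draw_flock_sizes(src$flock_size_distribution, n_flocks)
    SP <- alloc_multinom(sizes, matrix(src$species_weights, n_flocks, nsp,
                                       byrow = TRUE))
    G <- matrix(rgamma(n_flocks * nf, shape = src$feeder_clumping),
                n_flocks, nf)
    P <- G / rowSums(G)
    M <- matrix(0L, n_flocks, nf * nsp)   # column (sp-1)*nf + feeder
    for (s in seq_len(nsp)) {
      M[, (s - 1L) * nf + seq_len(nf)] <- alloc_multinom(SP[, s], P)
    }
  } else if (is.list(src) && length(src) &&
             inherits(src[[1L]], "flock_snapshot")) {
    labels <- src[[1L]]$species
    nf <- nrow(src[[1L]]$counts)
    nsp <- length(labels)
    pick <- sample.int(length(src), n_flocks, replace = TRUE)
    M <- t(vapply(src[pick], function(sn) as.integer(sn$counts),
                  integer(nf * nsp)))
  } else {
    stop("`flock_source` must be a synthetic_config, a detection_stream, or a non-empty list of flock_snapshots",
         call. = FALSE)
  }
  if (all(rowSums(M) == 0L)) stop("empty flock source", call. = FALSE)

  coefs_by_sp <- rule_coefs(params, labels)
  Tmat <- matrix(0L, nf * nsp, nf)      # fold species out: per-feeder totals
  for (s in seq_len(nsp)) Tmat[(s - 1L) * nf + seq_len(nf), ] <- diag(nf)
  n <- n_flocks
  i <- seq_len(n)
  steps <- vector("list", n_decisions)

  for (step in seq_len(n_decisions)) {
    tot_birds <- rowSums(M)
    # focal bird: uniform among all birds of the flock
    cell <- sample_rows(M, runif(n))
    sp <- (cell - 1L) %/% nf + 1L
    feeder <- cell - (sp - 1L) * nf
    M[cbind(i, cell)] <- M[cbind(i, cell)] - 1L   # focal removed

    tot <- M %*% Tmat                  # per-feeder totals, focal removed
    nc <- matrix(0L, n, nf)
    for (f in seq_len(nf)) nc[, f] <- M[cbind(i, (sp - 1L) * nf + f)]
    nh <- tot - nc

    cf <- coefs_by_sp[sp, , drop = FALSE]
    k <- cf[, "k"]
    ec <- nc * (1 + k) - k * rowSums(nc)
    eh <- nh * (1 + k) - k * rowSums(nh)
    S <- stats::plogis(ec * cf[, "lsc"] + eh * cf[, "lsh"] - cf[, "la"])
    dest <- sample_rows(S, runif(n))   # stay included: origin not excluded

    moved <- which(dest != feeder)
    if (length(moved)) {
      # events record the complete pre-move flock configuration: the mover is
      # excluded only from the counts entering its own choice, but counted at
      # its origin feeder in the emitted occupancy context
      nc_ev <- nc[moved, , drop = FALSE]
      nc_ev[cbind(seq_along(moved), feeder[moved])] <-
        nc_ev[cbind(seq_along(moved), feeder[moved])] + 1L
      steps[[step]] <- list(flock = moved, sp = sp[moved],
                            from = feeder[moved], to = dest[moved],
                            nc = nc_ev,
                            nh = nh[moved, , drop = FALSE],
                            t_dep = (step - 1L) * logging_interval)
    }
    M[cbind(i, (sp - 1L) * nf + dest)] <-
      M[cbind(i, (sp - 1L) * nf + dest)] + 1L
    stopifnot(all(rowSums(M) == tot_birds))  # bird conservation
  }

  steps <- steps[!vapply(steps, is.null, logical(1))]
  if (!length(steps)) {
    return(empty_events(nf, 2L * logging_interval, logging_interval))
  }
  ev <- do.call(rbind, lapply(steps, function(st) {
    build_events_df(
      patch_id = sprintf("flock%05d", st$flock),
      focal_tag = sprintf("agent_f%05d", st$flock),
      focal_species = labels[st$sp],
      from = st$from, to = st$to,
      t_dep = rep(st$t_dep, length(st$from)),
      t_arr = rep(st$t_dep + logging_interval, length(st$from)),
      nc = st$nc, nh = st$nh, nf = nf,
      window = 2L * logging_interval, interval = logging_interval
    )
  }))
  new_movement_events(ev, n_feeders = nf, window = 2L * logging_interval,
                      logging_interval = logging_interval)
}

#' Compare simulated movement curves to reference curves
#'
#' Bin-wise comparison of density-conditioned leaving/arrival curves from a
#' simulation against a reference — either empirical curves from data or the
#' analytic asocial prediction ([tasp_curves()]). Both inputs must be on the
#' same bins.
#'
#' @param sim Simulated `movement_events` (curves are computed with the
#'   reference's binning) or a ready `density_curve`.
#' @param reference A `density_curve` or `tasp_curve` on the same bins.
#' @param tolerance Maximum absolute per-bin discrepancy accepted (default
#'   0.05).
#' @param min_n Bins with fewer events than this (on either side, where
#'   event counts are available) are reported but excluded from the summary
#'   discrepancy (default 5, matching the curve estimator's low-n flag).
#' @return A `flock_sim_comparison`: list with per-bin table (`bin_mid`,
#'   simulated and reference curves, differences), `max_abs_discrepancy`,
#'   `tolerance` and `pass`.
#' @export
compare_simulation_to_curves <- function(sim, reference, tolerance = 0.05,
                                         min_n = 5L) {
  if (inherits(reference, "tasp_curve")) {
    ref_mid <- reference$rho
    ref_leave <- reference$p_leave
    ref_arrive <- reference$p_arrive
  } else if (inherits(reference, "density_curve")) {
    ref_mid <- reference$bin_mid
    ref_leave <- reference$p_leave
    ref_arrive <- reference$p_arrive
  } else {
    stop("`reference` must be a density_curve or tasp_curve", call. = FALSE)
  }
  if (inherits(sim, "movement_events")) {
    edges <- if (inherits(reference, "density_curve")) {
      attr(reference, "bin_edges")
    } else {
      mids_to_edges(ref_mid)
    }
    sim <- empirical_density_curves(sim, bin_edges = edges)
  }
  stopifnot(inherits(sim, "density_curve"))
  if (length(sim$bin_mid) != length(ref_mid) ||
      max(abs(sim$bin_mid - ref_mid)) > 1e-9) {
    stop("bin mismatch between simulation and reference curves", call. = FALSE)
  }
  ref_n_leave <- if (inherits(reference, "density_curve")) {
    reference$n_leave
  } else {
    rep(Inf, length(ref_mid))
  }
  ref_n_arrive <- if (inherits(reference, "density_curve")) {
    reference$n_arrive
  } else {
    rep(Inf, length(ref_mid))
  }
  tab <- data.frame(
    bin_mid = sim$bin_mid,
    p_leave_sim = sim$p_leave, p_leave_ref = ref_leave,
    d_leave = sim$p_leave - ref_leave,
    p_arrive_sim = sim$p_arrive, p_arrive_ref = ref_arrive,
    d_arrive = sim$p_arrive - ref_arrive,
    n_leave = sim$n_leave, n_arrive = sim$n_arrive
  )
  use_l <- tab$n_leave >= min_n & ref_n_leave >= min_n
  use_a <- tab$n_arrive >= min_n & ref_n_arrive >= min_n
  diffs <- c(tab$d_leave[use_l], tab$d_arrive[use_a])
  max_abs <- if (all(is.na(diffs))) NA_real_ else max(abs(diffs), na.rm = TRUE)
  structure(
    list(table = tab, max_abs_discrepancy = max_abs, tolerance = tolerance,
         pass = isTRUE(max_abs <= tolerance)),
    class = "flock_sim_comparison"
  )
}

mids_to_edges <- function(mids) {
  h <- diff(mids)
  if (length(h) == 0L) stop("need at least two bins", call. = FALSE)
  c(mids[1L] - h[1L] / 2, mids + c(h, h[length(h)]) / 2)
}

#' @export
print.flock_sim_comparison <- function(x, ...) {
  cat(sprintf("Simulation vs reference curves: max |diff| = %.4f (tolerance %.4f) — %s\n",
              x$max_abs_discrepancy, x$tolerance,
              if (x$pass) "PASS" else "FAIL"))
  print(round(as.data.frame(x$table), 4))
  invisible(x)
}
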