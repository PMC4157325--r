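#' Default density bins
#'
#' Eleven equal-width bins for relative density rho, centred on
#' 0.0, 0.1, ..., 1.0.
#'
#' @return Numeric vector of 12 bin edges spanning [-0.05, 1.05].
#' @export
default_rho_bins <- function() seq(-0.05, 1.05, by = 0.1)

bin_of <- function(rho, edges) {
  b <- findInterval(rho, edges, rightmost.closed = TRUE)
  b[b < 1L | b > length(edges) - 1L] <- NA_integer_
  b
}

# Per-event binned tabulation reused by the point estimate and the jackknife:
# M_all[i, b] counts window densities of event i in bin b (pooled departure +
# arrival windows, or one window when pooled = FALSE); bin_L / bin_A are the
# bins of the origin and destination densities (NA when undefined).
prep_curve_data <- function(events, edges, pooled = TRUE) {
  nf <- attr(events, "n_feeders")
  nb <- length(edges) - 1L
  n <- nrow(events)
  dep_rho <- as.matrix(as.data.frame(events)[sprintf("dep_rho_%d", seq_len(nf))])
  arr_rho <- as.matrix(as.data.frame(events)[sprintf("arr_rho_%d", seq_len(nf))])
  dep_ok <- events$dep_total > 0
  arr_ok <- events$arr_total > 0
  tab_rows <- function(m, ok) {
    cnt <- matrix(0L, n, nb)
    rsum <- matrix(0, n, nb)
    if (any(ok)) {
      vals <- matrix(as.numeric(m[ok, , drop = FALSE]), nrow = sum(ok))
      bm <- matrix(bin_of(as.numeric(vals), edges), nrow = sum(ok))
      for (f in seq_len(ncol(bm))) {
        idx <- which(!is.na(bm[, f]))
        if (length(idx)) {
          ii <- which(ok)[idx]
          bb <- bm[idx, f]
          cnt[cbind(ii, bb)] <- cnt[cbind(ii, bb)] + 1L
          rsum[cbind(ii, bb)] <- rsum[cbind(ii, bb)] + vals[idx, f]
        }
      }
    }
    list(cnt = cnt, rsum = rsum)
  }
  M_dep <- tab_rows(dep_rho, dep_ok)
  M_arr <- tab_rows(arr_rho, arr_ok)
  list(
    M_all_leave = if (pooled) M_dep$cnt + M_arr$cnt else M_dep$cnt,
    M_all_arrive = if (pooled) M_dep$cnt + M_arr$cnt else M_arr$cnt,
    S_all_leave = if (pooled) M_dep$rsum + M_arr$rsum else M_dep$rsum,
    S_all_arrive = if (pooled) M_dep$rsum + M_arr$rsum else M_arr$rsum,
    bin_L = ifelse(dep_ok, bin_of(events$rho_leave, edges), NA_integer_),
    bin_A = ifelse(arr_ok, bin_of(events$rho_arrive, edges), NA_integer_),
    nb = nb
  )
}

curve_from_counts <- function(H_move, n_move, H_all, n_all, prior) {
  p_rho <- H_all / n_all
  p_rho_move <- H_move / n_move
  p <- ifelse(H_all > 0, p_rho_move * prior / p_rho, NA_real_)
  # delta-method Monte Carlo standard error of the ratio estimate
  v1 <- p_rho_move * (1 - p_rho_move) / n_move
  v2 <- p_rho * (1 - p_rho) / n_all
  se <- ifelse(H_all > 0 & H_move > 0,
               p * sqrt(v1 / p_rho_move^2 + v2 / p_rho^2), NA_real_)
  list(p = p, se = se)
}

#' Empirical density-conditioned movement curves
#'
#' Estimates the probability of leaving a feeder, `P(L | rho)`, and of
#' arriving at a feeder, `P(A | rho)`, as a function of the feeder's relative
#' density rho, via Bayes' rule:
#' \deqn{P(A \mid \rho) = P(\rho \mid A)\, P(A) / P(\rho)}
#' where `P(rho)` is the frequency of densities observed on all feeders
#' across all event windows, `P(rho | A)` the frequency of densities at
#' arrival feeders, and the prior `P(A)` is fixed at `1/n_feeders` (0.25:
#' all feeders are of equal quality). The leaving curve uses origin-feeder
#' densities in the same way. Bins never observed in `P(rho)` are returned
#' as `NA` (undefined), not 0; bins with fewer than 5 events are flagged
#' `low_n`. Being ratio estimates, the curves can exceed 1 under sampling
#' noise.
#'
#' @param events A `movement_events` data frame (events whose occupancy
#'   window has a zero patch total are excluded per curve).
#' @param bin_edges Bin edges partitioning rho in [0, 1]
#'   (default [default_rho_bins()]).
#' @param prior Prior arrival/leaving probability per feeder (default 0.25).
#' @param pooled When `TRUE` (default), `P(rho)` pools departure- and
#'   arrival-window densities; otherwise each curve uses its own window.
#' @return A `density_curve` data frame with `bin_lo`, `bin_mid`, `bin_hi`,
#'   `p_leave`, `p_arrive`, per-bin event counts `n_leave`, `n_arrive`,
#'   delta-method Monte Carlo standard errors `se_leave`, `se_arrive`, the
#'   realized mean densities per bin (`rho_mean_leave`, `rho_mean_arrive`)
#'   and a `low_n` flag; bin edges, prior and usable-event counts as
#'   attributes.
#' @export
empirical_density_curves <- function(events, bin_edges = default_rho_bins(),
                                     prior = 0.25, pooled = TRUE) {
  stopifnot(inherits(events, "movement_events"))
  if (bin_edges[1L] > 0 || bin_edges[length(bin_edges)] < 1) {
    stop("`bin_edges` must cover [0, 1]", call. = FALSE)
  }
  pd <- prep_curve_data(events, bin_edges, pooled = pooled)
  n_L <- sum(!is.na(pd$bin_L))
  n_A <- sum(!is.na(pd$bin_A))
  if (n_L == 0L && n_A == 0L) {
    stop("no usable events (all occupancy windows undefined)", call. = FALSE)
  }
  H_L <- tabulate(pd$bin_L, nbins = pd$nb)
  H_A <- tabulate(pd$bin_A, nbins = pd$nb)
  H_all_L <- colSums(pd$M_all_leave)
  H_all_A <- colSums(pd$M_all_arrive)
  leave <- curve_from_counts(H_L, max(n_L, 1L), H_all_L,
                             max(sum(H_all_L), 1L), prior)
  arrive <- curve_from_counts(H_A, max(n_A, 1L), H_all_A,
                              max(sum(H_all_A), 1L), prior)
  nb <- pd$nb
  out <- data.frame(
    bin_lo = bin_edges[seq_len(nb)],
    bin_mid = (bin_edges[seq_len(nb)] + bin_edges[-1L]) / 2,
    bin_hi = bin_edges[-1L],
    p_leave = leave$p,
    p_arrive = arrive$p,
    n_leave = H_L,
    n_arrive = H_A,
    se_leave = leave$se,
    se_arrive = arrive$se,
    # realized mean density per bin (for evaluating analytic references at
    # the density the bin actually represents, not its midpoint)
    rho_mean_leave = ifelse(H_all_L > 0,
                            colSums(pd$S_all_leave) / H_all_L, NA_real_),
    rho_mean_arrive = ifelse(H_all_A > 0,
                             colSums(pd$S_all_arrive) / H_all_A, NA_real_)
  )
  out$low_n <- (H_L + H_A) < 5L
  structure(out,
            bin_edges = bin_edges, prior = prior, pooled = pooled,
            n_events_leave = n_L, n_events_arrive = n_A,
            class = c("density_curve", "data.frame"))
}

#' Jackknife variability envelope for density curves
#'
#' Delete-d jackknife: the empirical curves are recomputed `reps` times on
#' subsamples with a fixed fraction of events removed, and the per-bin
#' minimum and maximum across subsamples — the maximal variability range —
#' are returned.
#'
#' @inheritParams empirical_density_curves
#' @param reps Number of jackknife replicates (default 1000).
#' @param frac_removed Fraction of events removed per replicate (default 0.4;
#'   must be in [0, 1)).
#' @param seed Optional integer seed.
#' @return Data frame with per-bin `leave_lo`, `leave_hi`, `arrive_lo`,
#'   `arrive_hi` (NA where a bin was never defined in any subsample).
#' @export
jackknife_envelope <- function(events, bin_edges = default_rho_bins(),
                               reps = 1000L, frac_removed = 0.4, seed = NULL,
                               prior = 0.25, pooled = TRUE) {
  stopifnot(inherits(events, "movement_events"), reps >= 1L)
  if (frac_removed < 0 || frac_removed >= 1) {
    stop("`frac_removed` must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  pd <- prep_curve_data(events, bin_edges, pooled = pooled)
  n <- nrow(events)
  d <- round(frac_removed * n)
  nb <- pd$nb
  lo_L <- rep(Inf, nb); hi_L <- rep(-Inf, nb)
  lo_A <- rep(Inf, nb); hi_A <- rep(-Inf, nb)
  for (r in seq_len(reps)) {
    keep <- if (d > 0) sample.int(n, n - d) else seq_len(n)
    bl <- pd$bin_L[keep]; ba <- pd$bin_A[keep]
    H_L <- tabulate(bl, nbins = nb); H_A <- tabulate(ba, nbins = nb)
    H_all_L <- colSums(pd$M_all_leave[keep, , drop = FALSE])
    H_all_A <- colSums(pd$M_all_arrive[keep, , drop = FALSE])
    pl <- curve_from_counts(H_L, max(sum(!is.na(bl)), 1L), H_all_L,
                            max(sum(H_all_L), 1L), prior)$p
    pa <- curve_from_counts(H_A, max(sum(!is.na(ba)), 1L), H_all_A,
                            max(sum(H_all_A), 1L), prior)$p
    ok <- !is.na(pl)
    lo_L[ok] <- pmin(lo_L[ok], pl[ok]); hi_L[ok] <- pmax(hi_L[ok], pl[ok])
    ok <- !is.na(pa)
    lo_A[ok] <- pmin(lo_A[ok], pa[ok]); hi_A[ok] <- pmax(hi_A[ok], pa[ok])
  }
  fix <- function(v) ifelse(is.finite(v), v, NA_real_)
  data.frame(
    bin_mid = (bin_edges[seq_len(nb)] + bin_edges[-1L]) / 2,
    leave_lo = fix(lo_L), leave_hi = fix(hi_L),
    arrive_lo = fix(lo_A), arrive_hi = fix(hi_A)
  )
}

#' Theoretical asocial prediction (TASP) curves
#'
#' Null model for density-conditioned movement when birds carry no social
#' attraction: a uniformly chosen mover sits at a feeder with probability
#' equal to its relative density, so the leaving probability is
#' `P(L | rho) = rho`; having left, it relocates uniformly among the other
#' `n_feeders - 1` feeders, so a feeder of density rho receives the mover
#' with probability `P(A | rho) = (1 - rho) / (n_feeders - 1)`. The arrival
#' probabilities over the three non-origin feeders of a four-feeder patch
#' sum to 1 per configuration. A literal variant with arrival probability
#' `0.33 * rho` is retained behind the `literal` switch for comparison; the
#' default decreasing form is the one consistent with inverse-density
#' relocation and probability conservation.
#'
#' @param density_grid Densities in [0, 1] at which to evaluate the curves.
#' @param n_feeders Number of feeders (default 4).
#' @param literal Use the literal increasing arrival form `0.33 * rho`
#'   instead of `(1 - rho)/3` (default `FALSE`).
#' @return A `tasp_curve` data frame with `rho`, `p_leave`, `p_arrive`.
#' @export
tasp_curves <- function(density_grid = seq(0, 1, by = 0.1), n_feeders = 4L,
                        literal = FALSE) {
  stopifnot(all(density_grid >= 0 & density_grid <= 1))
  p_arrive <- if (literal) {
    0.33 * density_grid
  } else {
    (1 - density_grid) / (n_feeders - 1L)
  }
  structure(
    data.frame(rho = density_grid, p_leave = density_grid,
               p_arrive = p_arrive),
    n_feeders = n_feeders, literal = literal,
    class = c("tasp_curve", "data.frame")
  )
}
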