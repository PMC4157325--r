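# Fixtures and independent oracles used across the suite.

# Worked toy patch: focal bird "k" feeds at F1 for two intervals while four
# other birds sit 1-on-F2 / 3-on-F3, then k is next detected at F3 one
# interval later. With the focal removed, the departure-window densities are
# (0, 0.25, 0.75, 0), so rho at the origin is 0 and rho at the arrival
# feeder is 0.75.
toy_patch_stream <- function() {
  others <- expand.grid(t = c(15, 30, 45), tag = c("o1", "o2", "o3", "o4"),
                        stringsAsFactors = FALSE)
  others$f <- ifelse(others$tag == "o1", 2L, 3L)
  df <- rbind(
    data.frame(patch_id = "P", timestamp_s = c(15, 30, 60),
               feeder_id = c(1L, 1L, 3L), tag_id = "k",
               species = "great_tit", stringsAsFactors = FALSE),
    data.frame(patch_id = "P", timestamp_s = others$t, feeder_id = others$f,
               tag_id = others$tag, species = "blue_tit",
               stringsAsFactors = FALSE)
  )
  as_detection_stream(df)
}

# Independent brute-force movement extraction: plain nested loops and data
# frame scans, no shared code with extract_movements().
brute_force_extract <- function(stream, gap_threshold = 240, window = 30) {
  det <- unique(as.data.frame(stream))
  out <- list()
  for (tag in unique(det$tag_id)) {
    mine <- det[det$tag_id == tag, ]
    mine <- mine[order(mine$timestamp_s, mine$feeder_id), ]
    if (nrow(mine) < 2) next
    for (r in 2:nrow(mine)) {
      gap <- mine$timestamp_s[r] - mine$timestamp_s[r - 1]
      if (mine$feeder_id[r] != mine$feeder_id[r - 1] && gap <= gap_threshold) {
        occ <- function(t_end) {
          win <- det[det$timestamp_s >= t_end - window &
                       det$timestamp_s < t_end &
                       det$tag_id != tag, c("feeder_id", "tag_id")]
          win <- unique(win)
          sapply(1:4, function(f) sum(win$feeder_id == f))
        }
        nd <- occ(mine$timestamp_s[r - 1])
        na <- occ(mine$timestamp_s[r])
        out[[length(out) + 1]] <- data.frame(
          focal_tag = tag,
          from_feeder = mine$feeder_id[r - 1],
          to_feeder = mine$feeder_id[r],
          t_depart = mine$timestamp_s[r - 1],
          t_arrive = mine$timestamp_s[r],
          rho_leave = if (sum(nd) > 0) nd[mine$feeder_id[r - 1]] / sum(nd) else NA_real_,
          rho_arrive = if (sum(na) > 0) na[mine$feeder_id[r]] / sum(na) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$focal_tag, res$t_depart), ]
}

# Direct scalar evaluation of the decision rule, written from the formula:
# P(X_x | B) = 1 / (1 + a * s^-(n_x - k * sum(n[-x]))), two-rate variant with
# the product of conspecific and heterospecific terms.
direct_scores <- function(con, het, s_c, s_h, a, k) {
  sapply(seq_along(con), function(x) {
    ec <- con[x] - k * sum(con[-x])
    eh <- het[x] - k * sum(het[-x])
    1 / (1 + a * s_c^(-ec) * s_h^(-eh))
  })
}

# Small mixed-species generator config used across tests.
small_config <- function(seed = 1L, ...) {
  synthetic_config(n_individuals = 80L, species_pool = NULL,
                   session_length = 7200L, flock_arrival_rate = 10,
                   seed = seed, ...)
}

# Reference parameter sets and 95% ranges used as generating truth in
# recovery tests.
great_tit_params <- function() decision_params(s_c = 12.64, s_h = 2.10,
                                               k = 0.01, a = 13.48)
blue_tit_params <- function() decision_params(s_c = 3.63, s_h = 4.05,
                                              k = 0.02, a = 9.99)

great_tit_ranges <- function() list(s_c = c(5.05, 21.98), s_h = c(2.10, 5.17),
                                    a = c(7.38, 24.43), k = c(0, 0.02))
blue_tit_ranges <- function() list(s_c = c(2.10, 9.11), s_h = c(2.69, 8.42),
                                   a = c(4.83, 21.87), k = c(0, 0.05))

# Hand-built movement_events table (bypassing extraction) for estimator toys:
# each row supplies the per-feeder density vectors for both windows plus the
# origin/destination feeders.
fake_events <- function(rho_rows, from, to, n_per_feeder = 4L) {
  n <- nrow(rho_rows)
  tot <- rep(n_per_feeder, n)  # nominal positive patch totals
  nc <- round(rho_rows * n_per_feeder)
  nh <- matrix(0L, n, 4)
  df <- data.frame(
    patch_id = "T", focal_tag = sprintf("b%02d", seq_len(n)),
    focal_species = "sp", from_feeder = from, to_feeder = to,
    t_depart = (seq_len(n) - 1) * 15, t_arrive = seq_len(n) * 15,
    stringsAsFactors = FALSE
  )
  for (f in 1:4) df[[paste0("dep_nc_", f)]] <- nc[, f]
  for (f in 1:4) df[[paste0("dep_nh_", f)]] <- nh[, f]
  for (f in 1:4) df[[paste0("dep_rho_", f)]] <- rho_rows[, f]
  df$dep_total <- tot
  for (f in 1:4) df[[paste0("arr_nc_", f)]] <- nc[, f]
  for (f in 1:4) df[[paste0("arr_nh_", f)]] <- nh[, f]
  for (f in 1:4) df[[paste0("arr_rho_", f)]] <- rho_rows[, f]
  df$arr_total <- tot
  df$rho_leave <- rho_rows[cbind(seq_len(n), from)]
  df$rho_arrive <- rho_rows[cbind(seq_len(n), to)]
  df$rho_defined <- TRUE
  flockdecide:::new_movement_events(df, n_feeders = 4L, window = 30L,
                                    logging_interval = 15L)
}
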