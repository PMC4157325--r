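test_that("the worked toy stream yields one F1->F3 event with the stated densities", {
  ev <- extract_movements(toy_patch_stream())
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$from_feeder, 1L)
  expect_identical(ev$to_feeder, 3L)
  expect_equal(ev$rho_leave, 0)
  expect_equal(ev$rho_arrive, 0.75)
  # full departure-window distribution (focal removed): 0, 0.25, 0.75, 0
  expect_equal(unlist(ev[1, sprintf("dep_rho_%d", 1:4)], use.names = FALSE),
               c(0, 0.25, 0.75, 0))
})

test_that("gaps beyond the threshold break patch residency", {
  st <- as_detection_stream(data.frame(
    patch_id = "P", timestamp_s = c(0, 405), feeder_id = c(1L, 3L),
    tag_id = "k", species = "gt", stringsAsFactors = FALSE))
  expect_identical(nrow(extract_movements(st)), 0L)
  # exactly at the threshold still counts
  st2 <- as_detection_stream(data.frame(
    patch_id = "P", timestamp_s = c(0, 240), feeder_id = c(1L, 3L),
    tag_id = "k", species = "gt", stringsAsFactors = FALSE))
  expect_identical(nrow(extract_movements(st2)), 1L)
})

test_that("a bird that never changes feeder produces no events", {
  st <- as_detection_stream(data.frame(
    patch_id = "P", timestamp_s = seq(0, 150, by = 15), feeder_id = 2L,
    tag_id = "k", species = "gt", stringsAsFactors = FALSE))
  expect_identical(nrow(extract_movements(st)), 0L)
})

test_that("merging sorts, de-duplicates and rejects mixed patches", {
  a <- as_detection_stream(data.frame(
    patch_id = "P", timestamp_s = 30, feeder_id = 2L, tag_id = "x",
    species = "gt", stringsAsFactors = FALSE))
  b <- as_detection_stream(data.frame(
    patch_id = "P", timestamp_s = 15, feeder_id = 1L, tag_id = "x",
    species = "gt", stringsAsFactors = FALSE))
  m <- merge_streams(list(a, b))
  expect_identical(nrow(m), 2L)
  expect_identical(m$timestamp_s, c(15, 30))
  # duplicate record in both inputs collapses to one (idempotent merge)
  m2 <- merge_streams(list(a, a))
  expect_identical(nrow(m2), 1L)
  expect_identical(merge_streams(list(m, m)), m)
  # counting oracle: merged size equals the sum of de-duplicated inputs
  cfg <- small_config(seed = 31L)
  st <- generate_dataset(cfg)
  per_feeder <- lapply(1:4, function(f) {
    as_detection_stream(as.data.frame(st)[st$feeder_id == f, ])
  })
  merged <- merge_streams(per_feeder)
  expect_identical(nrow(merged), nrow(st))
  expect_identical(nrow(extract_movements(merged)),
                   nrow(extract_movements(st)))
  # mixed patches are an error
  cc <- as.data.frame(a); cc$patch_id <- "Q"
  expect_error(merge_streams(list(a, as_detection_stream(cc))),
               "mixed patch ids")
})

test_that("extraction matches a brute-force scan on synthetic data", {
  st <- generate_dataset(small_config(seed = 8L))
  ev <- extract_movements(st)
  bf <- brute_force_extract(st)
  expect_identical(nrow(ev), nrow(bf))
  expect_equal(ev$focal_tag[order(ev$focal_tag, ev$t_depart)], bf$focal_tag)
  o <- order(ev$focal_tag, ev$t_depart)
  expect_identical(ev$from_feeder[o], bf$from_feeder)
  expect_identical(ev$to_feeder[o], bf$to_feeder)
  expect_equal(ev$rho_leave[o], bf$rho_leave)
  expect_equal(ev$rho_arrive[o], bf$rho_arrive)
})

test_that("occupancy vectors exclude the focal and their densities sum to 1", {
  st <- generate_dataset(small_config(seed = 13L))
  ev <- extract_movements(st)
  def <- ev[ev$dep_total > 0 & ev$arr_total > 0, ]
  dep <- as.matrix(def[sprintf("dep_rho_%d", 1:4)])
  arr <- as.matrix(def[sprintf("arr_rho_%d", 1:4)])
  expect_true(all(abs(rowSums(dep) - 1) < 1e-12))
  expect_true(all(abs(rowSums(arr) - 1) < 1e-12))
  expect_true(all(dep >= 0 & dep <= 1))
  # counts decompose into conspecific + heterospecific
  tot <- as.matrix(def[sprintf("dep_nc_%d", 1:4)]) +
    as.matrix(def[sprintf("dep_nh_%d", 1:4)])
  expect_equal(unname(rowSums(tot)), def$dep_total)
})

test_that("extraction is stable under re-sorting of tied records", {
  st <- generate_dataset(small_config(seed = 17L))
  shuffled <- as.data.frame(st)
  withr::local_seed(1)
  shuffled <- shuffled[sample.int(nrow(shuffled)), ]
  st2 <- as_detection_stream(shuffled)
  expect_equal(as.data.frame(extract_movements(st)),
               as.data.frame(extract_movements(st2)))
})

test_that("dual detection within one interval uses the earlier feeder as origin", {
  st <- as_detection_stream(data.frame(
    patch_id = "P", timestamp_s = c(15, 15), feeder_id = c(2L, 4L),
    tag_id = "k", species = "gt", stringsAsFactors = FALSE))
  ev <- extract_movements(st)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$from_feeder, 2L)
  expect_identical(ev$to_feeder, 4L)
  expect_equal(ev$t_arrive - ev$t_depart, 0)
})

test_that("malformed inputs are rejected", {
  df <- data.frame(patch_id = "P", timestamp_s = c(30, 15),
                   feeder_id = c(1L, 2L), tag_id = "k", species = "gt",
                   stringsAsFactors = FALSE)
  st <- as_detection_stream(df)  # sorts
  bad <- st; bad$timestamp_s <- rev(bad$timestamp_s)
  expect_error(extract_movements(bad), "sorted")
  expect_error(extract_movements(st, window = 20), "multiple")
  expect_error(as_detection_stream(data.frame(
    patch_id = "P", timestamp_s = 7, feeder_id = 1L, tag_id = "k",
    species = "gt")), "multiples")
})

test_that("gap-threshold heuristic recovers the analytic mixture crossing", {
  withr::local_seed(2)
  n <- 20000
  fast <- rexp(round(0.8 * n), rate = 1 / 30)
  slow <- rexp(round(0.2 * n), rate = 1 / 1200)
  gaps <- sample(c(fast, slow))
  # responsibility crossing of the generating mixture:
  # log((w1 r1)/(w2 r2)) / (r1 - r2)
  truth <- log((0.8 / 30) / (0.2 / 1200)) / (1 / 30 - 1 / 1200)
  est <- estimate_gap_threshold(gaps)
  expect_lte(abs(est - truth), 15)
  # deterministic: same input twice gives the same answer
  expect_identical(est, estimate_gap_threshold(gaps))
})

test_that("gap-threshold heuristic refuses degenerate input", {
  expect_error(estimate_gap_threshold(rexp(10, 1 / 60)), "240 s default")
  expect_error(estimate_gap_threshold(rep(60, 100)), "degenerate")
})

test_that("event filters are order-preserving subsets", {
  st <- generate_dataset(small_config(seed = 23L))
  ev <- extract_movements(st)
  expect_identical(as.data.frame(filter_events(ev, rep(TRUE, nrow(ev)))),
                   as.data.frame(ev))
  expect_identical(nrow(filter_events(ev, function(e) rep(FALSE, nrow(e)))),
                   0L)
  keep <- ev$focal_species == "blue_tit"
  sp <- filter_events(ev, function(e) e$focal_species == "blue_tit")
  expect_true(all(sp$focal_species == "blue_tit"))
  want <- as.data.frame(ev)[keep, , drop = FALSE]
  rownames(want) <- NULL
  expect_identical(as.data.frame(sp), want)
  # first-day restriction on a two-day stream
  two_day <- as.data.frame(st)
  shifted <- two_day; shifted$timestamp_s <- shifted$timestamp_s + 86400
  shifted$tag_id <- paste0(shifted$tag_id, "_d2")
  ev2 <- extract_movements(as_detection_stream(rbind(two_day, shifted)))
  day1 <- filter_events(ev2, function(e) e$t_depart < min(e$t_depart) + 86400)
  expect_identical(nrow(day1), nrow(ev))
  expect_true(all(day1$t_depart < 86400))
})
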