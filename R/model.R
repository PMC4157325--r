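#' Raw site scores under the social decision rule
#'
#' Evaluates the decision rule for each feeder given the occupancy the
#' deciding bird perceives (its own presence already removed). For the
#' single-rate variant the score of feeder `x` is
#' `1 / (1 + a * s^-(n_x - k * sum(n[-x])))`; the two-rate variant uses the
#' product of conspecific and heterospecific terms. Scores are computed in
#' log space, so large rates and counts do not overflow.
#'
#' @param params A [decision_params()] object.
#' @param counts For the single-rate variant, a numeric vector of per-feeder
#'   bird counts (focal bird excluded). For the two-rate variant, a list with
#'   elements `conspecific` and `heterospecific`, each a per-feeder count
#'   vector, or a 2-row matrix with rows in that order.
#' @return Numeric vector of per-feeder scores, each strictly inside (0, 1).
#'   Scores are *not* normalized; see [choice_probabilities()].
#' @examples
#' site_scores(decision_params(s = 2, a = 1, k = 0), c(3, 0, 0, 0))
#' @export
site_scores <- function(params, counts) {
  stopifnot(inherits(params, "flock_params"))
  cc <- split_counts(params, counts)
  score_matrix(params, rbind(cc$con), rbind(cc$het))[1L, ]
}

# Normalize the two accepted `counts` shapes into conspecific/heterospecific
# vectors (heterospecific all-zero for the single variant, where only the
# total matters).
split_counts <- function(params, counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    con <- as.numeric(counts$conspecific)
    het <- as.numeric(counts$heterospecific)
  } else if (is.matrix(counts)) {
    con <- as.numeric(counts[1L, ])
    het <- as.numeric(counts[2L, ])
  } else {
    con <- as.numeric(counts)
    het <- numeric(length(con))
  }
  if (length(con) != length(het)) {
    stop("conspecific and heterospecific count vectors differ in length",
         call. = FALSE)
  }
  if (anyNA(con) || anyNA(het) || any(con < 0) || any(het < 0)) {
    stop("occupancy counts must be non-negative and non-missing", call. = FALSE)
  }
  list(con = con, het = het)
}

# Vectorized score computation: nc, nh are n-by-F matrices of focal-removed
# counts. Returns an n-by-F matrix of scores in (0, 1).
# score = plogis(e_c*log(s_c) + e_h*log(s_h) - log(a)),
# e_x = n_x - k*(rowtot - n_x) = n_x*(1+k) - k*rowtot.
score_matrix <- function(params, nc, nh) {
  k <- params$k
  a <- params$a
  if (!is.finite(k) || !is.finite(a)) stop("non-finite parameter", call. = FALSE)
  ec <- nc * (1 + k) - k * rowSums(nc)
  if (params$variant == "single") {
    eh <- nh * (1 + k) - k * rowSums(nh)
    eta <- (ec + eh) * log(params$s) - log(a)
  } else {
    eh <- nh * (1 + k) - k * rowSums(nh)
    eta <- ec * log(params$s_c) + eh * log(params$s_h) - log(a)
  }
  stats::plogis(eta)
}

#' Choice probabilities after probability matching
#'
#' Because the raw site scores of [site_scores()] can sum to more than 1,
#' a probability-matching step divides each score by the sum of the scores,
#' yielding a proper choice distribution over feeders. Probabilities are
#' always strictly positive: even an empty feeder is chosen with non-zero
#' probability.
#'
#' @inheritParams site_scores
#' @return An object of class `flock_choice`: a list with `raw_scores`,
#'   `probabilities` (summing to 1) and the `counts` used.
#' @examples
#' # With s = 1 every feeder is chosen with probability 0.25, regardless of
#' # where the other birds are:
#' choice_probabilities(decision_params(s = 1, a = 2), c(7, 0, 1, 0))
#' @export
choice_probabilities <- function(params, counts) {
  raw <- site_scores(params, counts)
  structure(
    list(raw_scores = raw, probabilities = raw / sum(raw), counts = counts),
    class = "flock_choice"
  )
}

#' @export
print.flock_choice <- function(x, ...) {
  cat("Feeder choice distribution\n")
  m <- rbind(score = x$raw_scores, probability = x$probabilities)
  colnames(m) <- paste0("F", seq_along(x$raw_scores))
  print(round(m, 4))
  invisible(x)
}

#' Choice-probability surface over conspecific/heterospecific occupancy
#'
#' Computes the probability of choosing a focal feeder `x` for every
#' combination of conspecific count `c` (0..`n_c_total`) and heterospecific
#' count `h` (0..`n_h_total`) at that feeder, holding the flock size fixed.
#' Birds not at feeder `x` are split as evenly as integer counts allow across
#' the other feeders (remainders assigned to the lowest-numbered ones); the
#' convention is recorded in the returned object. The `P = 0.25` contour —
#' the threshold above which a site is chosen more often than at random —
#' is traced with [grDevices::contourLines()].
#'
#' @param params A [decision_params()] object.
#' @param n_c_total,n_h_total Total conspecifics and heterospecifics in the
#'   patch (focal bird excluded).
#' @param n_feeders Number of feeders in the patch (default 4).
#' @return An object of class `flock_surface`: list with `grid` (data frame
#'   of `n_c`, `n_h`, `p_choose`), `contour_25` (list of data frames tracing
#'   P = 0.25), totals, and the allocation convention string.
#' @export
choice_surface <- function(params, n_c_total, n_h_total, n_feeders = 4L) {
  stopifnot(n_c_total >= 0, n_h_total >= 0, n_feeders >= 2)
  cs <- 0:n_c_total
  hs <- 0:n_h_total
  grid <- expand.grid(n_c = cs, n_h = hs)
  p <- mapply(function(cx, hx) {
    con <- c(cx, spread_evenly(n_c_total - cx, n_feeders - 1L))
    het <- c(hx, spread_evenly(n_h_total - hx, n_feeders - 1L))
    choice_probabilities(params, list(conspecific = con,
                                      heterospecific = het))$probabilities[1L]
  }, grid$n_c, grid$n_h)
  grid$p_choose <- as.numeric(p)
  z <- matrix(grid$p_choose, nrow = length(cs), ncol = length(hs))
  contour25 <- list()
  if (length(cs) > 1 && length(hs) > 1 && diff(range(z)) > 0) {
    cl <- grDevices::contourLines(x = cs, y = hs, z = z, levels = 0.25)
    contour25 <- lapply(cl, function(l) data.frame(n_c = l$x, n_h = l$y))
  }
  structure(
    list(grid = grid, contour_25 = contour25,
         n_c_total = n_c_total, n_h_total = n_h_total, n_feeders = n_feeders,
         params = params,
         allocation = "remaining birds split evenly across non-focal feeders; integer remainders to lowest-numbered feeders"),
    class = "flock_surface"
  )
}

# Split n birds over m feeders as evenly as integers allow.
spread_evenly <- function(n, m) {
  base <- n %/% m
  extra <- n %% m
  base + c(rep(1L, extra), rep(0L, m - extra))
}

#' Minimal occupancy at which a feeder beats random choice
#'
#' Smallest count of the stated class (conspecific or heterospecific) at a
#' focal feeder such that the probability of choosing that feeder reaches
#' `1/n_feeders` (0.25 in a four-feeder patch), holding the patch totals
#' fixed under the allocation convention of [choice_surface()]. The count of
#' the other class at the focal feeder is held at 0 by default.
#'
#' @param params A [decision_params()] object.
#' @param class `"conspecific"` or `"heterospecific"` — the class whose count
#'   at the focal feeder is varied.
#' @param totals Named list or vector with patch totals `n_c` and `n_h`
#'   (focal excluded).
#' @param other_at_focal Count of the other class at the focal feeder
#'   (default 0).
#' @param n_feeders Number of feeders (default 4).
#' @return Integer count, 0 when even an empty feeder clears the threshold.
#' @export
threshold_count <- function(params, class = c("conspecific", "heterospecific"),
                            totals, other_at_focal = 0L, n_feeders = 4L) {
  class <- match.arg(class)
  n_c <- totals[["n_c"]]
  n_h <- totals[["n_h"]]
  stopifnot(n_c + n_h >= 1)
  total_focal <- if (class == "conspecific") n_c else n_h
  thr <- 1 / n_feeders
  for (cnt in 0:total_focal) {
    if (class == "conspecific") {
      con <- c(cnt, spread_evenly(n_c - cnt, n_feeders - 1L))
      het <- c(other_at_focal, spread_evenly(n_h - other_at_focal, n_feeders - 1L))
    } else {
      het <- c(cnt, spread_evenly(n_h - cnt, n_feeders - 1L))
      con <- c(other_at_focal, spread_evenly(n_c - other_at_focal, n_feeders - 1L))
    }
    p <- choice_probabilities(params, list(conspecific = con,
                                           heterospecific = het))$probabilities[1L]
    if (p >= thr - 1e-12) return(cnt)
  }
  total_focal + 1L
}
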