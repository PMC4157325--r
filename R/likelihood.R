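# Extract likelihood-ready matrices from a movement_events table.
# context: which occupancy window provides the information available when the
# destination was chosen.
prep_likelihood_data <- function(events, context = c("arrival", "departure")) {
  context <- match.arg(context)
  nf <- attr(events, "n_feeders")
  pre <- if (context == "arrival") "arr" else "dep"
  ev <- as.data.frame(events)
  ok <- ev[[sprintf("%s_total", pre)]] > 0
  if (any(!ok)) {
    warning(sprintf("%d event(s) with undefined %s-window occupancy skipped",
                    sum(!ok), context), call. = FALSE)
  }
  ev <- ev[ok, , drop = FALSE]
  list(
    nc = as.matrix(ev[sprintf("%s_nc_%d", pre, seq_len(nf))]),
    nh = as.matrix(ev[sprintf("%s_nh_%d", pre, seq_len(nf))]),
    from = ev$from_feeder,
    to = ev$to_feeder,
    species = ev$focal_species,
    n_feeders = nf
  )
}

# Vectorized per-event log-likelihood given prepared matrices.
ll_core <- function(params, dat, convention = c("conditional", "unconditional")) {
  convention <- match.arg(convention)
  S <- score_matrix(params, dat$nc, dat$nh)
  i <- seq_len(nrow(S))
  num <- S[cbind(i, dat$to)]
  den <- if (convention == "conditional") {
    rowSums(S) - S[cbind(i, dat$from)]
  } else {
    rowSums(S)
  }
  unname(log(num) - log(den))
}

#' Log-likelihood of observed movement decisions
#'
#' Probability of each observed movement under the decision rule. The default
#' `"conditional"` convention conditions on the fact that a move was observed
#' and scores the choice of arrival feeder among the `n_feeders - 1`
#' non-origin alternatives (choice probabilities renormalized over those
#' alternatives); the `"unconditional"` convention scores the arrival feeder
#' against all feeders including the origin ("stay"). The occupancy context
#' is the arrival window by default — the information available when the
#' destination was chosen.
#'
#' @param params A [decision_params()] object.
#' @param events A `movement_events` data frame. Events whose context window
#'   has a zero patch total are skipped with a warning.
#' @param convention `"conditional"` (default) or `"unconditional"`.
#' @param context `"arrival"` (default) or `"departure"` occupancy window.
#' @return Numeric vector of per-event log-probabilities (finite, negative).
#' @examples
#' # with s = 1 every event has probability 1/3: log-likelihood -1.0986 each
#' @export
event_log_likelihood <- function(params, events,
                                 convention = c("conditional", "unconditional"),
                                 context = c("arrival", "departure")) {
  stopifnot(inherits(params, "flock_params"),
            inherits(events, "movement_events"))
  dat <- prep_likelihood_data(events, context)
  ll_core(params, dat, convention)
}

theta_to_params <- function(theta, variant) {
  if (variant == "single") {
    decision_params(s = exp(theta[1L]), a = exp(theta[2L]), k = theta[3L])
  } else {
    decision_params(s_c = exp(theta[1L]), s_h = exp(theta[2L]),
                    a = exp(theta[3L]), k = theta[4L])
  }
}

params_to_theta <- function(params) {
  if (params$variant == "single") {
    c(log_s = log(params$s), log_a = log(params$a), k = params$k)
  } else {
    c(log_s_c = log(params$s_c), log_s_h = log(params$s_h),
      log_a = log(params$a), k = params$k)
  }
}

default_bounds <- function(variant) {
  if (variant == "single") {
    list(lower = c(-3, -3, 0), upper = c(6, 6, 5))
  } else {
    list(lower = c(-3, -3, -3, 0), upper = c(6, 6, 6, 5))
  }
}

default_start <- function(variant) {
  if (variant == "single") c(log(2), log(2), 0.01) else
    c(log(2), log(2), log(2), 0.01)
}

dispersed_starts <- function(variant) {
  if (variant == "single") {
    list(c(0, 0, 0), c(2, 1, 0.1), c(-1, 2, 0.5), c(3, 3, 0.01), c(1, -1, 1))
  } else {
    list(c(0, 0, 0, 0), c(2, 1, 1, 0.1), c(-1, -1, 2, 0.5),
         c(3, 1, 3, 0.01), c(1, 2, -1, 1))
  }
}

#' Fit the social decision-making model by maximum likelihood
#'
#' Maximizes the total log-likelihood of the observed movement decisions over
#' the decision-rule parameters. Optimization runs on `log(s)` (or
#' `log(s_c)`, `log(s_h)`), `log(a)` and raw `k` with box constraints
#' (`log` scale in [-3, 6], `k` in [0, 5]) via `L-BFGS-B`; on failure, five
#' dispersed starts are tried and the best retained. The fit is deterministic
#' given identical inputs and start.
#'
#' @param events A `movement_events` data frame.
#' @param variant `"two_species"` (separate conspecific/heterospecific rates;
#'   default) or `"single"`.
#' @param species Optional focal-species filter (character vector); only
#'   decisions by these species enter the likelihood.
#' @param convention,context Passed to [event_log_likelihood()].
#' @param bounds Optional list with `lower` and `upper` on the transformed
#'   scale.
#' @param start Optional start on the transformed scale.
#' @param compute_ci Compute 95% profile-likelihood intervals for all
#'   parameters (slower; default `FALSE`). [profile_ci()] can be called
#'   later.
#' @return A `flock_fit` object: point estimates as [decision_params()],
#'   total log-likelihood, the `s = 1` null log-likelihood on the same
#'   events, event count, convergence diagnostics and (optionally) profile
#'   CIs.
#' @export
fit_decision_model <- function(events, variant = c("two_species", "single"),
                               species = NULL,
                               convention = c("conditional", "unconditional"),
                               context = c("arrival", "departure"),
                               bounds = NULL, start = NULL,
                               compute_ci = FALSE) {
  variant <- match.arg(variant)
  convention <- match.arg(convention)
  context <- match.arg(context)
  stopifnot(inherits(events, "movement_events"))
  if (!is.null(species)) {
    events <- filter_events(events, events$focal_species %in% species)
  }
  dat <- prep_likelihood_data(events, context)
  n <- length(dat$to)
  if (n == 0L) stop("no usable events to fit", call. = FALSE)
  if (n < 20L) {
    warning(sprintf("only %d usable events; estimates will be unstable", n),
            call. = FALSE)
  }
  bounds <- bounds %||% default_bounds(variant)
  start <- start %||% default_start(variant)

  nll <- function(theta) {
    p <- theta_to_params(theta, variant)
    v <- -sum(ll_core(p, dat, convention))
    if (!is.finite(v)) 1e10 else v
  }
  run <- function(th0) {
    tryCatch(
      optim(th0, nll, method = "L-BFGS-B", lower = bounds$lower,
            upper = bounds$upper, control = list(maxit = 500L)),
      error = function(e) NULL
    )
  }
  opt <- run(start)
  if (is.null(opt) || opt$convergence != 0) {
    cands <- c(list(opt), lapply(dispersed_starts(variant), run))
    cands <- cands[!vapply(cands, is.null, logical(1))]
    if (!length(cands)) stop("optimization failed from all starts", call. = FALSE)
    opt <- cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]
  }
  params <- theta_to_params(opt$par, variant)
  null_ll <- sum(ll_core(decision_params(s = 1), dat, convention))
  fit <- structure(
    list(params = params, log_likelihood = -opt$value,
         null_log_likelihood = null_ll, n_events = n,
         variant = variant, convention = convention, context = context,
         species_filter = species,
         converged = opt$convergence == 0,
         iterations = opt$counts[["function"]],
         theta = opt$par, bounds = bounds,
         data = dat),
    class = "flock_fit"
  )
  if (compute_ci) {
    fit$ci <- lapply(setNames(nm = fit_param_names(variant)),
                     function(pn) profile_ci(fit, pn))
  }
  fit
}

fit_param_names <- function(variant) {
  if (variant == "single") c("s", "a", "k") else c("s_c", "s_h", "a", "k")
}

#' @export
print.flock_fit <- function(x, ...) {
  cat("Social decision-model fit (", x$variant, " variant, ",
      x$convention, " likelihood)\n", sep = "")
  if (!is.null(x$species_filter)) {
    cat("  species:", paste(x$species_filter, collapse = ", "), "\n")
  }
  cat("  ", format(x$params), "\n", sep = "")
  cat(sprintf("  logLik = %.2f on %d events (s = 1 null: %.2f)\n",
              x$log_likelihood, x$n_events, x$null_log_likelihood))
  if (!is.null(x$ci)) {
    for (pn in names(x$ci)) {
      ci <- x$ci[[pn]]
      cat(sprintf("  %-4s 95%% CI [%.3g, %.3g]%s\n", pn, ci$lower, ci$upper,
                  if (ci$boundary_lower || ci$boundary_upper) " (at bound)" else ""))
    }
  }
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

# position of a named parameter in the transformed theta vector, plus its
# transform
param_slot <- function(variant, parameter) {
  names <- fit_param_names(variant)
  j <- match(parameter, names)
  if (is.na(j)) {
    stop(sprintf("parameter '%s' not in this fit (has: %s)", parameter,
                 paste(names, collapse = ", ")), call. = FALSE)
  }
  list(index = j, log_scale = parameter != "k")
}

#' Profile-likelihood confidence interval
#'
#' For one parameter of a fitted decision model, finds the set of values
#' whose profile log-likelihood (re-optimizing all other parameters) lies
#' within `qchisq(level, 1)/2` (1.92 at 95%) of the maximum. Endpoints are
#' located by expanding steps and bisection on the transformed scale, and
#' are clipped at the optimization bounds with a boundary flag — e.g. the
#' lower limit of `k` often sits at the `k >= 0` bound.
#'
#' @param fit A `flock_fit` from [fit_decision_model()].
#' @param parameter One of `"s"`, `"s_c"`, `"s_h"`, `"a"`, `"k"` (matching
#'   the fit's variant).
#' @param level Confidence level (default 0.95).
#' @param tol Bisection tolerance on the transformed scale.
#' @return List with `lower`, `upper` (on the natural scale), `estimate`,
#'   `level`, and flags `boundary_lower`, `boundary_upper`, `flat_profile`.
#' @export
profile_ci <- function(fit, parameter, level = 0.95, tol = 1e-3) {
  stopifnot(inherits(fit, "flock_fit"))
  slot <- param_slot(fit$variant, parameter)
  j <- slot$index
  dat <- fit$data
  convention <- fit$convention
  variant <- fit$variant
  lower_b <- fit$bounds$lower
  upper_b <- fit$bounds$upper
  cutoff <- qchisq(level, 1) / 2
  nll_max <- -fit$log_likelihood
  theta_hat <- fit$theta

  free <- setdiff(seq_along(theta_hat), j)
  warm <- theta_hat[free]
  prof_nll <- function(v) {
    if (!length(free)) {
      th <- theta_hat; th[j] <- v
      p <- theta_to_params(th, variant)
      return(-sum(ll_core(p, dat, convention)))
    }
    fn <- function(th_free) {
      th <- numeric(length(theta_hat))
      th[j] <- v
      th[free] <- th_free
      p <- theta_to_params(th, variant)
      out <- -sum(ll_core(p, dat, convention))
      if (!is.finite(out)) 1e10 else out
    }
    o <- optim(warm, fn, method = "L-BFGS-B", lower = lower_b[free],
               upper = upper_b[free], control = list(maxit = 300L))
    warm <<- o$par
    o$value
  }

  excess <- function(v) prof_nll(v) - nll_max - cutoff

  find_end <- function(dir) {
    bound <- if (dir > 0) upper_b[j] else lower_b[j]
    step <- 0.25
    v0 <- theta_hat[j]
    warm <<- theta_hat[free]
    repeat {
      v1 <- v0 + dir * step
      if ((dir > 0 && v1 >= bound) || (dir < 0 && v1 <= bound)) {
        if (excess(bound) <= 0) {
          return(list(value = bound, boundary = TRUE))
        }
        v1 <- bound
        break
      }
      if (excess(v1) > 0) break
      v0 <- v1
      step <- step * 1.6
    }
    # bisect between v0 (inside) and v1 (outside)
    for (i in seq_len(40L)) {
      if (abs(v1 - v0) < tol) break
      vm <- (v0 + v1) / 2
      if (excess(vm) > 0) v1 <- vm else v0 <- vm
    }
    list(value = (v0 + v1) / 2, boundary = FALSE)
  }

  up <- find_end(+1)
  lo <- find_end(-1)
  back <- function(v) if (slot$log_scale) exp(v) else v
  flat <- up$boundary && lo$boundary
  list(parameter = parameter,
       estimate = back(theta_hat[j]),
       lower = back(lo$value), upper = back(up$value),
       level = level,
       boundary_lower = lo$boundary, boundary_upper = up$boundary,
       flat_profile = flat)
}
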