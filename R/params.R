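#' Decision-rule parameters
#'
#' Container for the parameters of the Bayesian social decision-making rule
#' used throughout the package. The rule scores a candidate feeding site `x`
#' from the occupancy of all sites:
#' \deqn{P(X_x \mid B) = \frac{1}{1 + a\, s^{-(n_x - k \sum_{i \ne x} n_i)}}}
#' where `n_x` is the number of birds at site `x` (the deciding bird
#' excluded). The two-species variant replaces the single social term by a
#' product of conspecific and heterospecific terms,
#' \eqn{s_c^{-(n_{cx} - k\sum n_{ci})} \, s_h^{-(n_{hx} - k\sum n_{hi})}},
#' counting same-species and other-species birds separately.
#'
#' Interpretation of the parameters:
#' * `s` (or `s_c`, `s_h`): rate of social information use — how much more
#'   often other individuals (conspecific / heterospecific) are judged to
#'   make a good choice than a bad one. `s = 1` means no social response.
#' * `k`: weight by which occupancy at the other sites discounts a site's
#'   estimated quality (relative vs absolute comparison). `k = 0` means the
#'   absolute count at a site is used.
#' * `a`: quality of nonsocial information; `a > 1` penalizes low-occupancy
#'   sites.
#'
#' @param s Social information use rate (single-rate variant). `s > 0`.
#' @param s_c,s_h Conspecific and heterospecific rates (two-rate variant).
#' @param k Cross-site influence weight, `k >= 0`.
#' @param a Nonsocial information quality, `a > 0`.
#' @return An object of class `flock_params` with fields `variant`
#'   (`"single"` or `"two_species"`), the rate parameter(s), `k` and `a`.
#' @examples
#' decision_params(s = 2, k = 0, a = 1)
#' decision_params(s_c = 12.64, s_h = 2.10, k = 0.01, a = 13.48)
#' @export
decision_params <- function(s = NULL, s_c = NULL, s_h = NULL, k = 0, a = 1) {
  two <- !is.null(s_c) || !is.null(s_h)
  if (two && !is.null(s)) {
    stop("supply either `s` (single variant) or `s_c` and `s_h`, not both",
         call. = FALSE)
  }
  if (two) {
    if (is.null(s_c) || is.null(s_h)) {
      stop("two-species variant needs both `s_c` and `s_h`", call. = FALSE)
    }
    chk_pos(s_c, "s_c"); chk_pos(s_h, "s_h")
  } else {
    if (is.null(s)) s <- 1
    chk_pos(s, "s")
  }
  chk_pos(a, "a")
  if (!is.finite(k) || k < 0) stop("`k` must be finite and >= 0", call. = FALSE)
  out <- if (two) {
    list(variant = "two_species", s_c = s_c, s_h = s_h, k = k, a = a)
  } else {
    list(variant = "single", s = s, k = k, a = a)
  }
  structure(out, class = "flock_params")
}

chk_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single finite positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.flock_params <- function(x, ...) {
  if (x$variant == "single") {
    cat(sprintf("Decision rule (single rate): s = %.4g, k = %.4g, a = %.4g\n",
                x$s, x$k, x$a))
  } else {
    cat(sprintf(
      "Decision rule (two rates): s_c = %.4g, s_h = %.4g, k = %.4g, a = %.4g\n",
      x$s_c, x$s_h, x$k, x$a))
  }
  invisible(x)
}

#' @export
format.flock_params <- function(x, ...) {
  if (x$variant == "single") {
    sprintf("single[s=%.4g,k=%.4g,a=%.4g]", x$s, x$k, x$a)
  } else {
    sprintf("two_species[s_c=%.4g,s_h=%.4g,k=%.4g,a=%.4g]", x$s_c, x$s_h,
            x$k, x$a)
  }
}

# Coerce a list (e.g. parsed JSON/YAML) back into flock_params.
as_flock_params <- function(x) {
  if (inherits(x, "flock_params")) return(x)
  if (!is.null(x$s)) {
    decision_params(s = x$s, k = x$k %||% 0, a = x$a %||% 1)
  } else {
    decision_params(s_c = x$s_c, s_h = x$s_h, k = x$k %||% 0, a = x$a %||% 1)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
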