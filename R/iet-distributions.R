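# Discrete waiting-time laws on {1, 2, ...}: probability mass, survival and
# hazard accessors. The hazard at gap g, pmf(g) / sum_{i >= g} pmf(i), is the
# conditional activation probability that drives every renewal update.

#' Tail of the generalized zeta sum
#'
#' Computes `sum_{i >= from} i^(-alpha)` by summing an explicit window and
#' closing the remainder with an Euler-Maclaurin correction. Accurate to well
#' below 1e-12 relative error for `alpha > 1`.
#'
#' @param alpha exponent, must exceed 1.
#' @param from first index of the sum (integer >= 1); may be a vector.
#' @return numeric vector of tail sums, same length as `from`.
#' @keywords internal
zeta_tail <- function(alpha, from = 1L) {
  stopifnot(alpha > 1, all(from >= 1))
  one <- function(g) {
    M <- max(g, 512L)
    s <- if (M > g) sum(seq.int(g, M - 1L)^(-alpha)) else 0
    s + M^(1 - alpha) / (alpha - 1) + M^(-alpha) / 2 +
      alpha * M^(-alpha - 1) / 12 -
      alpha * (alpha + 1) * (alpha + 2) * M^(-alpha - 3) / 720
  }
  vapply(as.numeric(from), one, numeric(1))
}

#' Construct a target inter-event time distribution
#'
#' Builds a discrete waiting-time law on \{1, 2, ...\}. Two parametric
#' families are supported: `"power_law"` with `pmf(dt) = dt^(-alpha) /
#' zeta(alpha)` (bursty activity, requires `exponent > 1`) and
#' `"discrete_exponential"` with `pmf(dt)` proportional to the integral of
#' `alpha * exp(-alpha x)` over `[dt - 1/2, dt + 1/2]`, i.e. a geometric law
#' with ratio `exp(-exponent)` (Poisson-like activity, requires
#' `exponent > 0`).
#'
#' The probability mass function is normalized over the full infinite
#' support; `support_max` only bounds the explicitly tabulated part. A unit
#' whose waiting time exceeds `support_max` is forced to activate
#' (`iet_hazard()` returns 1 beyond the table), so the effective law places
#' the residual tail mass at `support_max + 1`. Constructions choose
#' `support_max = t_tol + 1` so the forcing rule is never reached within the
#' horizon and all hazards used in a run are the exact untruncated ones.
#'
#' @param kind `"power_law"` or `"discrete_exponential"`.
#' @param exponent distribution parameter (`alpha`); `> 1` for the power law,
#'   `> 0` for the discrete exponential.
#' @param support_max largest waiting time with explicit mass (integer >= 1).
#' @return an object of class `iet_dist` with fields `kind`, `exponent`,
#'   `support_max`, `pmf` (length `support_max`), `tail`
#'   (length `support_max + 1`, `tail[g] = P(T >= g)`) and `hazard`.
#' @examples
#' d <- iet_distribution("power_law", 2, 100)
#' iet_pmf(d, 1)        # 1 / zeta(2)
#' iet_survival(d, 1)   # 1 - 1 / zeta(2)
#' iet_hazard(d, 2)
#' @export
iet_distribution <- function(kind = c("power_law", "discrete_exponential"),
                             exponent, support_max) {
  kind <- match.arg(kind)
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent))
    stop("'exponent' must be a single finite number", call. = FALSE)
  if (!is.numeric(support_max) || length(support_max) != 1L || support_max < 1)
    stop("'support_max' must be a positive integer", call. = FALSE)
  support_max <- as.integer(support_max)
  dt <- seq_len(support_max)

  if (kind == "power_law") {
    if (exponent <= 1)
      stop("power-law targets require exponent > 1", call. = FALSE)
    Z <- zeta_tail(exponent, 1L)
    pmf <- dt^(-exponent) / Z
    tail_end <- zeta_tail(exponent, support_max + 1L) / Z
    tl <- c(rev(cumsum(rev(pmf))) + tail_end, tail_end)
  } else {
    if (exponent <= 0)
      stop("discrete-exponential targets require exponent > 0", call. = FALSE)
    # integral of a*exp(-a x) over [dt-1/2, dt+1/2], normalized over dt >= 1:
    # geometric with success probability 1 - exp(-a)
    pmf <- (1 - exp(-exponent)) * exp(-exponent * (dt - 1))
    tl <- exp(-exponent * (0:support_max))
  }

  new_iet_dist(kind, exponent, support_max, pmf, tl)
}

new_iet_dist <- function(kind, exponent, support_max, pmf, tl) {
  structure(
    list(kind = kind, exponent = exponent, support_max = support_max,
         pmf = pmf, tail = tl,
         hazard = pmin(pmf / tl[seq_along(pmf)], 1)),
    class = "iet_dist")
}

#' Wrap an observed gap sample as an empirical IET distribution
#'
#' Normalizes the histogram of positive integer gaps into a waiting-time law,
#' e.g. to replay a fitted empirical target through the construction. Beyond
#' the largest observed gap the hazard is 1 (forced activation).
#'
#' @param gaps vector of positive integer gaps.
#' @return an `iet_dist` of kind `"empirical"` (`exponent` is `NA`).
#' @export
empirical_iet <- function(gaps) {
  gaps <- as.integer(gaps)
  if (length(gaps) < 1L || any(gaps < 1L))
    stop("'gaps' must be positive integers", call. = FALSE)
  support_max <- max(gaps)
  pmf <- tabulate(gaps, nbins = support_max) / length(gaps)
  tl <- c(rev(cumsum(rev(pmf))), 0)
  new_iet_dist("empirical", NA_real_, support_max, pmf, tl)
}

#' @export
print.iet_dist <- function(x, ...) {
  cat(sprintf("<iet_dist> kind=%s exponent=%s support_max=%d\n",
              x$kind, format(x$exponent), x$support_max))
  invisible(x)
}

#' Probability mass of an IET distribution
#'
#' @param dist an `iet_dist`.
#' @param dt waiting time(s), integer >= 1. Values beyond `support_max`
#'   return 0 (their mass is carried by the forced-activation rule).
#' @return numeric vector of probabilities.
#' @export
iet_pmf <- function(dist, dt) {
  stopifnot(inherits(dist, "iet_dist"))
  if (any(dt < 1)) stop("'dt' must be >= 1", call. = FALSE)
  out <- numeric(length(dt))
  ok <- dt <= dist$support_max
  out[ok] <- dist$pmf[dt[ok]]
  out
}

#' Survival function of an IET distribution
#'
#' Returns `P(T > dt)`. Decays like `dt^(-exponent + 1)` for the power law
#' and like `exp(-exponent * dt)` for the discrete exponential.
#'
#' @inheritParams iet_pmf
#' @param dt waiting time(s), integer >= 0.
#' @return numeric vector of survival probabilities.
#' @export
iet_survival <- function(dist, dt) {
  stopifnot(inherits(dist, "iet_dist"))
  if (any(dt < 0)) stop("'dt' must be >= 0", call. = FALSE)
  out <- numeric(length(dt))
  ok <- dt <= dist$support_max
  out[ok] <- dist$tail[dt[ok] + 1L]
  out # forced activation at support_max + 1 => survival 0 beyond
}

#' Hazard (conditional activation probability) of an IET distribution
#'
#' `pmf(gap) / sum_{i >= gap} pmf(i)`: the probability of activating now
#' given the current waiting time equals `gap`. Gaps beyond `support_max`
#' return 1 (forced activation), never a division by zero.
#'
#' @inheritParams iet_pmf
#' @param gap current waiting time(s), integer >= 1.
#' @return numeric vector of hazards in `[0, 1]`.
#' @export
iet_hazard <- function(dist, gap) {
  stopifnot(inherits(dist, "iet_dist"))
  if (any(gap < 1)) stop("'gap' must be >= 1", call. = FALSE)
  out <- rep(1, length(gap))
  ok <- gap <= dist$support_max
  out[ok] <- dist$hazard[gap[ok]]
  out
}

#' First-activation probability after an all-silent history
#'
#' Closed forms for the conditional probability that a unit, active only at
#' time 0, activates at time `n`: for a power law with exponent `alpha` the
#' approximation `1 - ((n + 1/2) / (n - 1/2))^(-alpha + 1)`, and for a
#' discrete exponential the constant `1 - exp(-alpha)`. These are the
#' quantities entering the analytic consistency conditions; the simulator
#' itself always uses exact hazards.
#'
#' @param kind `"power_law"` or `"discrete_exponential"`.
#' @param exponent distribution parameter.
#' @param n time of first activation, integer >= 1.
#' @return numeric vector of probabilities.
#' @export
first_activation_prob <- function(kind = c("power_law", "discrete_exponential"),
                                  exponent, n) {
  kind <- match.arg(kind)
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  if (kind == "power_law") {
    if (exponent <= 1) stop("power law requires exponent > 1", call. = FALSE)
    1 - ((n + 0.5) / (n - 0.5))^(-exponent + 1)
  } else {
    if (exponent <= 0)
      stop("discrete exponential requires exponent > 0", call. = FALSE)
    rep(1 - exp(-exponent), length(n))
  }
}

#' Sample waiting times from an IET distribution
#'
#' Draws from the effective law: the tabulated pmf plus the residual tail
#' mass placed at `support_max + 1` by the forced-activation rule.
#'
#' @param n number of draws.
#' @param dist an `iet_dist`.
#' @return integer vector of waiting times.
#' @export
riet <- function(n, dist) {
  stopifnot(inherits(dist, "iet_dist"))
  p <- c(dist$pmf, dist$tail[dist$support_max + 1L])
  sample.int(dist$support_max + 1L, size = n, replace = TRUE, prob = p)
}

#' Serialize / deserialize an IET distribution as JSON
#'
#' Parametric kinds round-trip through `{"kind", "exponent", "support_max"}`;
#' the empirical kind additionally carries its pmf.
#'
#' @param dist an `iet_dist`.
#' @param txt JSON string produced by `iet_to_json()`.
#' @return `iet_to_json()` a JSON string; `iet_from_json()` an `iet_dist`.
#' @export
iet_to_json <- function(dist) {
  stopifnot(inherits(dist, "iet_dist"))
  x <- list(kind = dist$kind, exponent = dist$exponent,
            support_max = dist$support_max)
  if (dist$kind == "empirical") x$pmf <- dist$pmf
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname iet_to_json
#' @export
iet_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  if (identical(x$kind, "empirical")) {
    pmf <- as.numeric(x$pmf)
    tl <- c(rev(cumsum(rev(pmf))), 0)
    new_iet_dist("empirical", NA_real_, length(pmf), pmf, tl)
  } else {
    iet_distribution(x$kind, x$exponent, x$support_max)
  }
}

# Resolve a target specification into an iet_dist: either an iet_dist already
# or list(kind=, exponent=) completed with the run's support_max.
as_iet_dist <- function(x, support_max) {
  if (inherits(x, "iet_dist")) return(x)
  if (is.list(x) && !is.null(x$kind))
    return(iet_distribution(x$kind, x$exponent,
                            if (is.null(x$support_max)) support_max
                            else x$support_max))
  stop("target must be an 'iet_dist' or list(kind=, exponent=)", call. = FALSE)
}
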