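# Interval extraction and summary statistics: node/link inter-event times,
# node inter-communication times (what contact data actually records),
# burstiness and memory, and aggregated weighted networks.

#' Extract inter-event / inter-communication intervals
#'
#' * `node_iet` — gaps between consecutive active states of each node.
#' * `link_iet` — gaps between consecutive active states of each link (a
#'   link is active when both endpoints are; branch activity is derived
#'   lazily from the endpoint activation lists).
#' * `node_ict` — gaps between consecutive times a node has at least one
#'   active incident link; only such moments are observable in empirical
#'   contact data.
#'
#' The final open interval of every unit is censored at the end of its
#' lifetime and is not a gap; its length is returned in the `"censored"`
#' attribute so likelihoods can account for it. Units with fewer than two
#' activations contribute no gaps.
#'
#' @param net a `temporal_network`.
#' @param mode `"node_iet"`, `"link_iet"` or `"node_ict"`.
#' @param scope `"aggregated"` pools all units into one gap vector;
#'   `"per_unit"` returns a named list.
#' @return integer gap vector with attributes `censored` and `n_units`
#'   (aggregated), or a named list of such vectors (per unit).
#' @export
extract_intervals <- function(net,
                              mode = c("node_iet", "link_iet", "node_ict"),
                              scope = c("aggregated", "per_unit")) {
  stopifnot(inherits(net, "temporal_network"))
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (net$t_tol < 1L) stop("network has fewer than 2 steps", call. = FALSE)

  unit_times <- switch(mode,
    node_iet = {
      ids <- which(!is.na(net$node_t0))
      out <- lapply(ids, function(v)
        list(times = net$node_act[[v]], t_end = net$node_t1[v]))
      names(out) <- as.character(ids)
      out
    },
    link_iet = {
      el <- unique(net$edge_log[, c("i", "j")])
      out <- lapply(seq_len(nrow(el)), function(r) {
        a <- link_activations(net, el$i[r], el$j[r])
        rows <- net$edge_log$i == el$i[r] & net$edge_log$j == el$j[r]
        list(times = a, t_end = max(net$edge_log$t1[rows]))
      })
      names(out) <- edge_key(el$i, el$j)
      out
    },
    node_ict = {
      ids <- which(!is.na(net$node_t0))
      adj <- lapply(igraph::as_adj_list(net$topology), as.integer)
      out <- lapply(ids, function(v) {
        nb <- adj[[v]]
        nb_act <- unique(unlist(net$node_act[nb], use.names = FALSE))
        list(times = sort(intersect(net$node_act[[v]], nb_act)),
             t_end = net$node_t1[v])
      })
      names(out) <- as.character(ids)
      out
    })

  per_unit <- lapply(unit_times, function(u) {
    g <- diff(u$times)
    cens <- if (length(u$times)) u$t_end - max(u$times) else NA_integer_
    attr(g, "censored") <- if (!is.na(cens) && cens >= 1L) cens
                           else integer(0)
    g
  })
  if (scope == "per_unit") return(per_unit)
  pooled <- unlist(per_unit, use.names = FALSE)
  if (is.null(pooled)) pooled <- integer(0)
  attr(pooled, "censored") <- unlist(lapply(per_unit, attr, "censored"),
                                     use.names = FALSE)
  attr(pooled, "n_units") <- length(per_unit)
  attr(pooled, "mode") <- mode
  pooled
}

#' Burstiness parameter and activity memory
#'
#' The burstiness parameter is `B = (sigma - mu) / (sigma + mu)` over the
#' gaps, in `[-1, 1]`: positive for heavy-tailed (bursty) gap laws, negative
#' for Poisson-like ones, -1 for constant gaps. Memory is summarized by the
#' autocorrelation of the binary activity series (mean-centred, biased
#' normalization), averaged across units when several series are given.
#'
#' @param gaps integer gap vector (e.g. from [extract_intervals()]).
#' @param activity optional binary 0/1 series or list of series.
#' @param max_lag largest lag of the autocorrelation.
#' @return list of class `burstiness_summary` with `B` and `autocorrelation`
#'   (named vector over lags `0..max_lag`, or `NULL`).
#' @export
burstiness_and_memory <- function(gaps, activity = NULL, max_lag = 20L) {
  gaps <- as.numeric(gaps)
  if (length(gaps) < 2L) stop("need at least 2 gaps", call. = FALSE)
  mu <- mean(gaps)
  sigma <- sd(gaps)
  if (sigma + mu == 0) stop("degenerate gap sample", call. = FALSE)
  B <- (sigma - mu) / (sigma + mu)
  ac <- NULL
  if (!is.null(activity)) {
    if (!is.list(activity)) activity <- list(activity)
    acs <- lapply(activity, function(a) {
      a <- as.numeric(a[!is.na(a)])
      x <- a - mean(a)
      den <- sum(x^2)
      vapply(0:max_lag, function(k) {
        if (den == 0 || k >= length(x)) return(NA_real_)
        sum(x[seq_len(length(x) - k)] * x[seq_len(length(x) - k) + k]) / den
      }, numeric(1))
    })
    wts <- vapply(activity, length, numeric(1))
    ac <- colSums(do.call(rbind, acs) * wts / sum(wts))
    names(ac) <- 0:max_lag
  }
  structure(list(B = B, autocorrelation = ac), class = "burstiness_summary")
}

#' @export
print.burstiness_summary <- function(x, ...) {
  cat(sprintf("<burstiness_summary> B = %.4f\n", x$B))
  if (!is.null(x$autocorrelation))
    cat("  autocorrelation[lag 1] =",
        format(x$autocorrelation[["1"]], digits = 4), "\n")
  invisible(x)
}

#' Aggregate activity into a weighted network and node strengths
#'
#' Collates all link activations from time `t = 1` through `t = t_agg` into
#' edge weights (activation counts) and node strengths (sums of incident
#' weights). When `t_base` is given, strengths are additionally rescaled by
#' `t_base / t_agg`: for a sufficiently long baseline the rescaled strength
#' survival curves collapse onto the baseline curve for any `t_agg`.
#'
#' @param net a `temporal_network`.
#' @param t_agg aggregation time, `1 <= t_agg <= t_tol`.
#' @param t_base optional baseline time, `1 <= t_base <= t_agg`.
#' @return list of class `aggregated_network` with `t_agg`, `t_base`,
#'   `weights` (data frame `i, j, w`) and `strengths` (per node).
#' @export
aggregate_and_strengths <- function(net, t_agg, t_base = NULL) {
  stopifnot(inherits(net, "temporal_network"))
  if (t_agg < 1 || t_agg > net$t_tol)
    stop("need 1 <= t_agg <= t_tol", call. = FALSE)
  if (!is.null(t_base) && (t_base < 1 || t_base > t_agg))
    stop("need 1 <= t_base <= t_agg", call. = FALSE)
  el <- unique(net$edge_log[, c("i", "j")])
  w <- vapply(seq_len(nrow(el)), function(r) {
    a <- link_activations(net, el$i[r], el$j[r])
    sum(a >= 1L & a <= t_agg)
  }, numeric(1))
  n <- length(net$node_act)
  strengths <- numeric(n)
  for (r in seq_len(nrow(el))) {
    strengths[el$i[r]] <- strengths[el$i[r]] + w[r]
    strengths[el$j[r]] <- strengths[el$j[r]] + w[r]
  }
  structure(list(t_agg = as.integer(t_agg),
                 t_base = if (is.null(t_base)) NA_integer_
                          else as.integer(t_base),
                 weights = data.frame(i = el$i, j = el$j, w = w),
                 strengths = strengths),
            class = "aggregated_network")
}

#' @export
print.aggregated_network <- function(x, ...) {
  cat(sprintf(
    "<aggregated_network> t_agg=%d, total weight %g, %d node(s)\n",
    x$t_agg, sum(x$weights$w), length(x$strengths)))
  invisible(x)
}

#' Survival curve of (normalized) node strengths
#'
#' @param agg an `aggregated_network`.
#' @param normalized rescale strengths by `t_base / t_agg` (requires
#'   `t_base`).
#' @param drop_zero drop zero-strength nodes (isolated or dead).
#' @return data frame with columns `s` (strength) and `surv` (`P(S > s)`).
#' @export
strength_survival <- function(agg, normalized = !is.na(agg$t_base),
                              drop_zero = TRUE) {
  stopifnot(inherits(agg, "aggregated_network"))
  s <- agg$strengths
  if (drop_zero) s <- s[s > 0]
  if (normalized) {
    if (is.na(agg$t_base)) stop("no t_base set", call. = FALSE)
    s <- s * agg$t_base / agg$t_agg
  }
  s <- sort(s)
  n <- length(s)
  data.frame(s = s, surv = (n - seq_len(n)) / n)
}

#' Sup distance between two survival curves
#'
#' Evaluates both step curves on the pooled abscissa grid and returns the
#' largest absolute difference (used for normalization-collapse checks).
#'
#' @param a,b data frames as returned by [strength_survival()].
#' @return the sup distance.
#' @export
survival_sup_distance <- function(a, b) {
  step_eval <- function(curve, x) {
    idx <- findInterval(x, curve$s)
    out <- curve$surv[pmax(idx, 1L)]
    out[idx == 0L] <- 1
    out
  }
  grid <- sort(unique(c(a$s, b$s)))
  max(abs(step_eval(a, grid) - step_eval(b, grid)))
}
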