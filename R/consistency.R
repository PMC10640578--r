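# Consistency of a target triple (F, G, H): all four joint step probabilities
# must stay in [0, 1] on every reachable trajectory pair. Checked either by
# exhaustive enumeration of reachable waiting-time states up to a horizon, or
# by the closed-form conditions for the two parametric families.

# Exact untruncated power-law hazard at gap g for exponent a.
pl_hazard_exact <- function(a, g) g^(-a) / zeta_tail(a, g)

#' Check consistency of a target triple
#'
#' A combination `(F, G, H)` of target IET laws is consistent when the joint
#' step probabilities `p1..p4` lie in `[0, 1]` for all reachable trajectory
#' pairs of any length; only then does the coupled construction realize the
#' targets. Three checkers are provided:
#'
#' * `"enumerate"` — exhaustive search over all reachable waiting-time states
#'   `(g_x, g_y, g_z)` up to `horizon` steps (the joint chain is Markov in the
#'   three gaps, so this covers every trajectory pair of that length). On
#'   violation, the first offending trajectory pair is returned as a witness.
#' * `"bursty_analytic"` — the closed-form condition for power-law targets
#'   with a common node exponent: `alpha_node >= alpha_link`,
#'   `p_x(1) + p_y(2) < 1`, and `p_x(1) + p_y(1) < 1 + p_z(1)`, evaluated
#'   with exact zeta hazards. Valid for any horizon.
#' * `"poisson_analytic"` — the closed-form condition for discrete
#'   exponential targets: `0 <= alpha_node - alpha_link <= ln 2`.
#'
#' Boundary cases (a margin within 1e-9 of zero) are reported as
#' `"marginal"` rather than guessed either way.
#'
#' @param F,G,H target `iet_dist`s for the two nodes and the link.
#' @param mode checker to use (see above).
#' @param horizon number of steps enumerated in `"enumerate"` mode.
#' @return a list of class `consistency_check` with `verdict`
#'   (`"consistent"`, `"marginal"` or `"inconsistent"`), `mode`, `margin`
#'   (smallest slack observed; negative when inconsistent), and for the
#'   enumerate mode `witness` (list with `traj_x`, `traj_y`, `time`,
#'   `p_name`, `p_value`) plus `n_states`.
#' @export
check_consistency <- function(F, G, H,
                              mode = c("enumerate", "bursty_analytic",
                                       "poisson_analytic"),
                              horizon = 12L) {
  mode <- match.arg(mode)
  stopifnot(inherits(F, "iet_dist"), inherits(G, "iet_dist"),
            inherits(H, "iet_dist"))
  switch(mode,
         enumerate = check_enumerate(F, G, H, as.integer(horizon)),
         bursty_analytic = check_bursty(F, G, H),
         poisson_analytic = check_poisson(F, G, H))
}

verdict_from_margin <- function(margin, tol = 1e-9) {
  if (margin < -tol) "inconsistent"
  else if (margin <= tol) "marginal"
  else "consistent"
}

check_enumerate <- function(F, G, H, horizon) {
  stopifnot(horizon >= 1L)
  key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L], sep = ",")
  pred <- new.env(parent = emptyenv())   # state key -> c(parent key, move)
  cur <- matrix(c(1L, 1L, 1L), ncol = 3L)
  assign("1,1,1", c(NA_character_, ""), envir = pred)
  min_margin <- Inf
  n_states <- 1L
  moves <- list(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))

  for (t in seq_len(horizon)) {
    hx <- iet_hazard(F, cur[, 1L])
    hy <- iet_hazard(G, cur[, 2L])
    hz <- iet_hazard(H, cur[, 3L])
    p <- cbind(p1 = hz, p2 = hx - hz, p3 = hy - hz, p4 = 1 + hz - hx - hy)
    worst <- apply(p, 1L, min)
    min_margin <- min(min_margin, worst)
    if (any(worst < -1e-9)) {
      i <- which.min(worst)
      j <- which.min(p[i, ])
      w <- witness_path(pred, key(cur[i, , drop = FALSE]))
      return(structure(list(
        verdict = "inconsistent", mode = "enumerate", margin = worst[i],
        witness = list(traj_x = w$x, traj_y = w$y, time = t,
                       p_name = colnames(p)[j], p_value = p[i, j]),
        n_states = n_states), class = "consistency_check"))
    }
    if (t == horizon) break
    # expand: four joint moves, kept when their probability is positive
    nxt <- vector("list", 4L)
    for (k in seq_along(moves)) {
      keep <- p[, k] > 1e-15
      if (!any(keep)) next
      mv <- moves[[k]]
      sub <- cur[keep, , drop = FALSE]
      gx <- if (mv[1L] == 1L) rep(1L, nrow(sub)) else sub[, 1L] + 1L
      gy <- if (mv[2L] == 1L) rep(1L, nrow(sub)) else sub[, 2L] + 1L
      gz <- if (mv[1L] == 1L && mv[2L] == 1L) rep(1L, nrow(sub))
            else sub[, 3L] + 1L
      nk <- paste(gx, gy, gz, sep = ",")
      fresh <- !vapply(nk, exists, logical(1), envir = pred)
      if (!any(fresh)) next
      pk <- key(sub)[fresh]
      nkf <- nk[fresh]
      first <- !duplicated(nkf)
      for (ii in which(first))
        assign(nkf[ii], c(pk[ii], paste(mv, collapse = "")), envir = pred)
      nxt[[k]] <- cbind(gx, gy, gz)[fresh, , drop = FALSE][first, ,
                                                           drop = FALSE]
    }
    nxt <- do.call(rbind, nxt)
    if (is.null(nxt) || nrow(nxt) == 0L) break
    nxt <- nxt[!duplicated(key(nxt)), , drop = FALSE]
    cur <- nxt
    n_states <- n_states + nrow(cur)
  }
  structure(list(verdict = verdict_from_margin(min_margin),
                 mode = "enumerate", margin = min_margin, witness = NULL,
                 n_states = n_states),
            class = "consistency_check")
}

# Reconstruct the (x, y) state sequences leading to a state key.
witness_path <- function(pred, k) {
  mvs <- character(0)
  while (TRUE) {
    rec <- get(k, envir = pred)
    if (is.na(rec[1L])) break
    mvs <- c(rec[2L], mvs)
    k <- rec[1L]
  }
  x <- c(1L, as.integer(substr(mvs, 1L, 1L)))
  y <- c(1L, as.integer(substr(mvs, 2L, 2L)))
  list(x = x, y = y)
}

check_bursty <- function(F, G, H) {
  if (F$kind != "power_law" || G$kind != "power_law" ||
      H$kind != "power_law")
    stop("bursty_analytic requires power-law targets", call. = FALSE)
  if (!isTRUE(all.equal(F$exponent, G$exponent)))
    stop("bursty_analytic requires a common node exponent; ",
         "use mode = \"enumerate\" for asymmetric node targets",
         call. = FALSE)
  a <- F$exponent; b <- H$exponent
  h1 <- pl_hazard_exact(a, 1L)
  h2 <- pl_hazard_exact(a, 2L)
  hb1 <- pl_hazard_exact(b, 1L)
  margins <- c(exponent_order = a - b,
               first_second = 1 - (h1 + h2),
               simultaneous = 1 + hb1 - 2 * h1)
  m <- min(margins)
  structure(list(verdict = verdict_from_margin(m), mode = "bursty_analytic",
                 margin = m, margins = margins, witness = NULL),
            class = "consistency_check")
}

check_poisson <- function(F, G, H) {
  if (F$kind != "discrete_exponential" || G$kind != "discrete_exponential" ||
      H$kind != "discrete_exponential")
    stop("poisson_analytic requires discrete-exponential targets",
         call. = FALSE)
  if (!isTRUE(all.equal(F$exponent, G$exponent)))
    stop("poisson_analytic requires a common node exponent; ",
         "use mode = \"enumerate\" for asymmetric node targets",
         call. = FALSE)
  d <- F$exponent - H$exponent
  margins <- c(lower = d, upper = log(2) - d)
  m <- min(margins)
  structure(list(verdict = verdict_from_margin(m), mode = "poisson_analytic",
                 margin = m, margins = margins, witness = NULL),
            class = "consistency_check")
}

#' @export
print.consistency_check <- function(x, ...) {
  cat(sprintf("<consistency_check> mode=%s verdict=%s margin=%.6g\n",
              x$mode, x$verdict, x$margin))
  if (!is.null(x$witness))
    cat(sprintf("  witness at t=%d: %s = %.6g, traj_x=%s traj_y=%s\n",
                x$witness$time, x$witness$p_name, x$witness$p_value,
                paste(x$witness$traj_x, collapse = ""),
                paste(x$witness$traj_y, collapse = "")))
  invisible(x)
}

#' Numeric consistency boundary for Poisson-like targets
#'
#' Locates, by bisection over the enumerated consistency verdict, the largest
#' admissible difference between the node rate and the link rate of discrete
#' exponential targets. The analytic value is `ln 2`.
#'
#' @param alpha common node rate (must exceed the boundary being located).
#' @param tol bisection tolerance on the rate difference.
#' @param horizon enumeration horizon per verdict.
#' @return the located supremum rate difference.
#' @export
poisson_consistency_boundary <- function(alpha = 1, tol = 1e-6,
                                         horizon = 12L) {
  stopifnot(alpha > 0.75)
  support <- as.integer(horizon) + 2L
  ok <- function(d) {
    Fn <- iet_distribution("discrete_exponential", alpha, support)
    Hl <- iet_distribution("discrete_exponential", alpha - d, support)
    check_consistency(Fn, Fn, Hl, "enumerate", horizon)$verdict !=
      "inconsistent"
  }
  lo <- 0
  hi <- min(0.75, alpha - 1e-9)
  if (ok(hi)) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
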