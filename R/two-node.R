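# Coupled two-node renewal systems: a pair of nodes x, y and the link z
# between them, with z active exactly when both nodes are active. The joint
# next-step law (p1..p4) couples the three marginal renewal processes.

#' Binary activity trajectory of one unit
#'
#' A trajectory records the 0/1 state of a unit at times `0..n` and its last
#' activation time. Every unit starts active at time 0.
#'
#' @param states integer 0/1 vector, `states[1]` is time 0 and must be 1.
#' @return an object of class `trajectory` with fields `states` and
#'   `last_activation` (a time, 0-based).
#' @export
new_trajectory <- function(states = 1L) {
  states <- as.integer(states)
  if (length(states) < 1L || states[1L] != 1L)
    stop("trajectories start active at time 0", call. = FALSE)
  if (!all(states %in% c(0L, 1L)))
    stop("trajectory states must be 0/1", call. = FALSE)
  structure(list(states = states,
                 last_activation = max(which(states == 1L)) - 1L),
            class = "trajectory")
}

#' @rdname new_trajectory
#' @param traj a `trajectory`.
#' @param state 0 or 1 to append at the next time step.
#' @export
traj_append <- function(traj, state) {
  stopifnot(inherits(traj, "trajectory"))
  state <- as.integer(state)
  traj$states <- c(traj$states, state)
  if (state == 1L) traj$last_activation <- length(traj$states) - 1L
  traj
}

traj_time <- function(traj) length(traj$states) - 1L

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> t=0..", traj_time(x), ": ",
      paste(x$states, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Conditional activation probability of a unit at the next step
#'
#' Given a trajectory observed through time `n`, the probability that the
#' unit is active at `n + 1` is the hazard of its target law at the current
#' waiting time `n + 1 - m`, where `m` is the last activation time:
#' `F(n + 1 - m) / sum_{i >= n + 1 - m} F(i)`.
#'
#' @param traj a `trajectory`.
#' @param dist the unit's target `iet_dist`.
#' @return a probability.
#' @export
conditional_activation_probability <- function(traj, dist) {
  stopifnot(inherits(traj, "trajectory"))
  gap <- traj_time(traj) + 1L - traj$last_activation
  iet_hazard(dist, gap)
}

#' Two-node system with target IET laws F, G, H
#'
#' @param F,G,H target `iet_dist`s for node x, node y and the link z.
#' @return an object of class `two_node_system` holding the three targets and
#'   trajectories `x`, `y`, `z` (all initialized active at time 0; the link
#'   trajectory is always the elementwise product of the node trajectories).
#' @export
two_node_system <- function(F, G, H) {
  stopifnot(inherits(F, "iet_dist"), inherits(G, "iet_dist"),
            inherits(H, "iet_dist"))
  structure(list(F = F, G = G, H = H,
                 x = new_trajectory(), y = new_trajectory(),
                 z = new_trajectory()),
            class = "two_node_system")
}

# Classed error raised when target laws are incompatible: some joint
# probability p_i falls below 0 on a reachable trajectory pair.
stop_inconsistency <- function(time, trajectories, p_name, p_value,
                               unit = NULL) {
  msg <- sprintf(
    "inconsistent targets: %s = %.6g < 0 at time %d%s",
    p_name, p_value, time,
    if (is.null(unit)) "" else sprintf(" (unit %s)", unit))
  cond <- structure(
    class = c("burstnet_inconsistency", "error", "condition"),
    list(message = msg, call = sys.call(-1L), time = time,
         trajectories = trajectories, p_name = p_name, p_value = p_value,
         unit = unit))
  stop(cond)
}

#' Joint next-step probabilities of a two-node system
#'
#' The quadruple `(p1, p2, p3, p4)` for the four joint next-step node states
#' (both active / x only / y only / neither): `p1 = h_z`, `p2 = h_x - h_z`,
#' `p3 = h_y - h_z`, `p4 = 1 + h_z - h_x - h_y`, where `h_u` is the
#' conditional activation probability of unit `u`. Values in `(-1e-12, 0)`
#' are clipped to 0 (rounding noise); a genuinely negative value raises a
#' `burstnet_inconsistency` error identifying the violated component.
#'
#' @param system a `two_node_system` with trajectories aligned to a common
#'   current time.
#' @return a list with components `p1..p4` (class `joint_step_probs`).
#' @export
joint_step_probabilities <- function(system) {
  stopifnot(inherits(system, "two_node_system"))
  hx <- conditional_activation_probability(system$x, system$F)
  hy <- conditional_activation_probability(system$y, system$G)
  hz <- conditional_activation_probability(system$z, system$H)
  p <- c(p1 = hz, p2 = hx - hz, p3 = hy - hz, p4 = 1 + hz - hx - hy)
  bad <- which(p < -1e-12)
  if (length(bad)) {
    i <- bad[which.min(p[bad])]
    stop_inconsistency(time = traj_time(system$x) + 1L,
                       trajectories = list(x = system$x, y = system$y,
                                           z = system$z),
                       p_name = names(p)[i], p_value = p[[i]])
  }
  p <- pmax(p, 0)
  structure(as.list(p), class = "joint_step_probs")
}

#' Advance a two-node system by one time step
#'
#' Samples the state of x with probability `h_x`, then the state of y with
#' probability `p1 / h_x` if x is active and `p3 / (1 - h_x)` otherwise, and
#' sets the link state to the product. The activation order (x then y) is
#' fixed for reproducibility; it does not affect the resulting laws.
#'
#' @param system a consistent `two_node_system`.
#' @return the updated system, one time step longer.
#' @export
step_two_node <- function(system) {
  p <- joint_step_probabilities(system)
  hx <- p$p1 + p$p2
  u1 <- runif(1)
  x_on <- u1 < hx
  cond <- if (x_on) {
    if (hx > 0) p$p1 / hx else 1
  } else {
    if (hx < 1) p$p3 / (1 - hx) else 0
  }
  u2 <- runif(1)
  y_on <- u2 < min(max(cond, 0), 1)
  system$x <- traj_append(system$x, x_on)
  system$y <- traj_append(system$y, y_on)
  system$z <- traj_append(system$z, x_on && y_on)
  system
}
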