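# Reference (pure R) stepping engine. Holds the mutable construction state in
# an environment so that dynamic-topology drivers can interleave structural
# changes with activity steps. The C++ kernel in src/engine.cpp is a fast
# path for fixed forests; both consume one uniform deviate per node per step
# in the same (breadth-first) order, so they are draw-for-draw identical.

# Distribution registry: hazard tables shared between units with identical
# targets (the common-exponent case uses just two tables).
same_dist <- function(a, b) {
  a$kind == b$kind && a$support_max == b$support_max &&
    ((is.na(a$exponent) && is.na(b$exponent) && identical(a$pmf, b$pmf)) ||
       isTRUE(all.equal(a$exponent, b$exponent)))
}

reg_add <- function(st, d) {
  for (k in seq_along(st$dists))
    if (same_dist(st$dists[[k]], d)) return(k)
  st$dists[[length(st$dists) + 1L]] <- d
  st$tables[[length(st$tables) + 1L]] <- d$hazard
  length(st$dists)
}

# Resolve a user-facing target spec for a given unit. `spec` may be a single
# iet_dist, a list(kind=, exponent=) prototype, or a per-unit named list.
resolve_target <- function(st, spec, key) {
  if (!inherits(spec, "iet_dist") && is.list(spec) && is.null(spec$kind)) {
    if (is.null(spec[[key]]))
      stop("no target assigned to unit ", key, call. = FALSE)
    spec <- spec[[key]]
  }
  as_iet_dist(spec, st$support_max)
}

haz_lookup <- function(st, tab, gaps) {
  out <- numeric(length(gaps))
  for (k in unique(tab)) {
    i <- tab == k
    h <- st$tables[[k]]
    g <- gaps[i]
    o <- rep(1, length(g))
    ok <- g <= length(h)
    o[ok] <- h[g[ok]]
    out[i] <- o
  }
  out
}

#' Initialize a construction state
#'
#' Builds the mutable state used by [step_network()]: the spanning forest,
#' per-unit hazard tables, waiting-time bookkeeping and the state history.
#' Most users want [construct_static()]; the explicit state is for stepwise
#' drivers (time-varying topologies, custom stopping rules).
#'
#' @param topology an `igraph` undirected simple graph.
#' @param node_target,trunk_target an `iet_dist`, a `list(kind=, exponent=)`
#'   prototype (completed with `support_max = t_tol + 1`), or a per-unit
#'   named list (nodes keyed by vertex id, trunks by `"i-j"` with `i < j`).
#' @param t_tol time horizon (steps after the all-active start at t = 0).
#' @param tree optional precomputed [select_spanning_tree()] result.
#' @param tree_method tree selection method when `tree` is `NULL`.
#' @param n_max,t_max capacity reserved for growth (defaults: no growth).
#' @return an environment of class `network_state`.
#' @export
network_state <- function(topology, node_target, trunk_target, t_tol,
                          tree = NULL, tree_method = "uniform",
                          n_max = NULL, t_max = t_tol,
                          alloc_states = TRUE) {
  n <- igraph::vcount(topology)
  if (is.null(n_max)) n_max <- n
  if (is.null(tree)) tree <- select_spanning_tree(topology, tree_method)
  st <- new.env(parent = emptyenv())
  class(st) <- "network_state"
  st$t <- 0L
  st$t_max <- as.integer(t_max)
  st$n_max <- as.integer(n_max)
  st$support_max <- as.integer(t_max) + 1L
  st$tol <- 1e-12
  st$dists <- list()
  st$tables <- list()
  st$node_target_spec <- node_target
  st$trunk_target_spec <- trunk_target

  st$alive <- c(rep(TRUE, n), rep(FALSE, n_max - n))
  st$t0 <- c(rep(0L, n), rep(NA_integer_, n_max - n))
  st$death <- rep(NA_integer_, n_max)
  st$parent <- c(tree$parent, rep(0L, n_max - n))
  st$layer <- c(tree$layer, rep(NA_integer_, n_max - n))
  st$gens <- unname(split(seq_len(n), tree$layer))

  st$node_tab <- rep(NA_integer_, n_max)
  st$trunk_tab <- rep(NA_integer_, n_max)   # keyed by child node
  for (v in seq_len(n))
    st$node_tab[v] <- reg_add(st, resolve_target(st, node_target,
                                                 as.character(v)))
  ch <- which(tree$parent > 0L)
  for (v in ch)
    st$trunk_tab[v] <- reg_add(st, resolve_target(
      st, trunk_target, edge_key(v, tree$parent[v])))

  el <- igraph::as_edgelist(topology, names = FALSE)
  st$edges <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  st$log_i <- st$edges[, 1L]
  st$log_j <- st$edges[, 2L]
  st$log_t0 <- rep(0L, nrow(st$edges))
  st$log_t1 <- rep(NA_integer_, nrow(st$edges))
  st$log_open <- seq_len(nrow(st$edges))   # edge row -> open log entry

  st$last_node <- rep(0L, n_max)
  st$last_trunk <- rep(0L, n_max)
  st$hcur <- rep(NA_real_, n_max)
  st$scur <- c(rep(TRUE, n), rep(FALSE, n_max - n))
  if (alloc_states) {
    st$S <- matrix(NA_integer_, nrow = n_max, ncol = st$t_max + 1L)
    st$S[seq_len(n), 1L] <- 1L
  }
  st
}

#' Advance a construction state by one time step
#'
#' Updates the root(s) from their own hazards, then each child within the
#' two-node system formed with its parent (layer by layer outward), and
#' leaves branch states implicit (a branch is active exactly when both of
#' its endpoints are). Raises a `burstnet_inconsistency` error naming the
#' offending trunk if the targets are incompatible.
#'
#' @param state a `network_state`.
#' @param exclude node ids excluded from sampling this step (they are held
#'   active; used when units are inserted mid-run).
#' @return the state, invisibly, advanced by one step.
#' @export
step_network <- function(state, exclude = integer(0)) {
  st <- state
  t <- st$t + 1L
  if (t > st$t_max) stop("time horizon exhausted", call. = FALSE)
  if (length(exclude)) {
    gaps <- pmax(t - st$last_node[exclude], 1L)
    st$hcur[exclude] <- haz_lookup(st, st$node_tab[exclude], gaps)
    st$scur[exclude] <- TRUE
    st$S[cbind(exclude, t + 1L)] <- 1L
    st$last_node[exclude] <- t
  }
  for (li in seq_along(st$gens)) {
    v <- st$gens[[li]]
    v <- v[st$alive[v]]
    if (length(exclude)) v <- setdiff(v, exclude)
    if (!length(v)) next
    hv <- haz_lookup(st, st$node_tab[v], t - st$last_node[v])
    u <- runif(length(v))
    rooted <- st$parent[v] == 0L
    on <- logical(length(v))
    if (any(rooted)) on[rooted] <- u[rooted] < hv[rooted]
    if (any(!rooted)) {
      i <- which(!rooted)
      vi <- v[i]
      p <- st$parent[vi]
      hp <- st$hcur[p]
      sp <- st$scur[p]
      hz <- haz_lookup(st, st$trunk_tab[vi], t - st$last_trunk[vi])
      p2 <- hp - hz
      p3 <- hv[i] - hz
      p4 <- 1 + hz - hp - hv[i]
      bad <- which(p2 < -st$tol | p3 < -st$tol | p4 < -st$tol)
      if (length(bad)) {
        b <- bad[1L]
        pv <- c(p2 = p2[b], p3 = p3[b], p4 = p4[b])
        w <- which.min(pv)
        stop_inconsistency(
          time = t,
          trajectories = list(parent = st$S[p[b], seq_len(t)],
                              child = st$S[vi[b], seq_len(t)]),
          p_name = names(pv)[w], p_value = pv[[w]],
          unit = sprintf("trunk %d-%d", p[b], vi[b]))
      }
      hz <- pmin(hz, hp, hv[i])
      cond <- ifelse(sp,
                     ifelse(hp > 0, hz / hp, 1),
                     ifelse(hp < 1, (hv[i] - hz) / (1 - hp), 0))
      oni <- u[i] < pmin(pmax(cond, 0), 1)
      on[i] <- oni
      tr_on <- vi[oni & sp]
      if (length(tr_on)) st$last_trunk[tr_on] <- t
    }
    st$hcur[v] <- hv
    st$scur[v] <- on
    st$S[cbind(v, t + 1L)] <- as.integer(on)
    if (any(on)) st$last_node[v[on]] <- t
  }
  st$t <- t
  invisible(st)
}

# Force units active at the current time (newly inserted elements and the
# endpoints of newly inserted links start active; older elements are updated
# accordingly). Refreshes trunk bookkeeping afterwards.
force_active <- function(st, ids) {
  if (!length(ids)) return(invisible(st))
  t <- st$t
  st$S[cbind(ids, t + 1L)] <- 1L
  st$scur[ids] <- TRUE
  st$last_node[ids] <- t
  ch <- which(st$alive & st$parent > 0L)
  both <- st$scur[ch] & st$scur[st$parent[ch]]
  st$last_trunk[ch[both]] <- t
  invisible(st)
}

# Recompute layers and generations from the parent vector (after repairs).
rebuild_tree_struct <- function(st) {
  alive <- which(st$alive)
  kids <- split(alive[st$parent[alive] > 0L],
                st$parent[alive][st$parent[alive] > 0L])
  frontier <- sort(alive[st$parent[alive] == 0L])
  l <- 0L
  seen <- 0L
  gens <- list()
  while (length(frontier)) {
    st$layer[frontier] <- l
    gens[[l + 1L]] <- frontier
    seen <- seen + length(frontier)
    frontier <- sort(unlist(kids[as.character(frontier)], use.names = FALSE))
    l <- l + 1L
  }
  if (seen != length(alive))
    stop("internal error: forest structure corrupted", call. = FALSE)
  st$gens <- gens
  invisible(st)
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> t=%d/%d, %d node(s) alive, %d edge(s)\n",
              x$t, x$t_max, sum(x$alive), nrow(x$edges)))
  invisible(x)
}

#' Finalize a construction state into a temporal network
#'
#' @param state a `network_state` that has been stepped to its horizon (or
#'   any earlier time).
#' @return a `temporal_network`.
#' @export
as_temporal_network <- function(state) {
  st <- state
  ids <- which(!is.na(st$t0))
  acts <- vector("list", st$n_max)
  for (v in ids) {
    row <- st$S[v, seq_len(st$t + 1L)]
    acts[[v]] <- which(!is.na(row) & row == 1L) - 1L
  }
  t1 <- ifelse(is.na(st$death), st$t, st$death - 1L)
  topo <- igraph::graph_from_edgelist(st$edges, directed = FALSE)
  topo <- igraph::add_vertices(topo,
                               max(0L, st$n_max - igraph::vcount(topo)))
  parent <- st$parent
  parent[!st$alive] <- 0L
  new_temporal_network(
    node_act = acts, node_t0 = st$t0, node_t1 = as.integer(t1),
    edge_log = data.frame(i = st$log_i, j = st$log_j, t0 = st$log_t0,
                          t1 = ifelse(is.na(st$log_t1), st$t, st$log_t1)),
    topology = topo, tree = tree_from_parent(parent, topo),
    t_tol = st$t, engine = "r")
}
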