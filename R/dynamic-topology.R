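# Time-varying underlying topologies: the temporal Barabasi-Albert model
# (one activity step, then one preferential-attachment arrival per step) and
# a general delta-driven driver with spanning-tree repair. Newly added
# elements start active; the endpoints of a newly added link are forced
# active so the product identity holds from insertion.

# ---- structural mutations on a network_state --------------------------------

st_add_edge_record <- function(st, a, b, t) {
  st$edges <- rbind(st$edges, c(min(a, b), max(a, b)))
  st$log_i <- c(st$log_i, min(a, b))
  st$log_j <- c(st$log_j, max(a, b))
  st$log_t0 <- c(st$log_t0, t)
  st$log_t1 <- c(st$log_t1, NA_integer_)
  st$log_open <- c(st$log_open, length(st$log_i))
  invisible(st)
}

st_root_of <- function(st, v) {
  while (st$parent[v] > 0L) v <- st$parent[v]
  v
}

# Reverse parent pointers along the path from `newroot` up to the current
# root of its tree component, carrying trunk bookkeeping (keyed by child)
# along the reversed edges.
st_reroot <- function(st, newroot) {
  chain <- newroot
  v <- newroot
  while (st$parent[v] > 0L) {
    v <- st$parent[v]
    chain <- c(chain, v)
  }
  if (length(chain) == 1L) return(invisible(st))
  old_tab <- st$trunk_tab[chain]
  old_last <- st$last_trunk[chain]
  for (k in seq_len(length(chain) - 1L)) {
    st$parent[chain[k + 1L]] <- chain[k]
    st$trunk_tab[chain[k + 1L]] <- old_tab[k]
    st$last_trunk[chain[k + 1L]] <- old_last[k]
  }
  st$parent[newroot] <- 0L
  invisible(st)
}

st_descendants <- function(st, v) {
  alive <- which(st$alive)
  kids <- split(alive[st$parent[alive] > 0L],
                st$parent[alive][st$parent[alive] > 0L])
  out <- v
  frontier <- v
  while (length(frontier)) {
    frontier <- unlist(kids[as.character(frontier)], use.names = FALSE)
    out <- c(out, frontier)
  }
  out
}

# Last time both endpoints were simultaneously active (from the state
# history); used when a branch is promoted to a trunk.
st_last_common <- function(st, a, b) {
  w <- which(st$S[a, ] == 1L & st$S[b, ] == 1L)
  if (!length(w)) 0L else max(w) - 1L
}

st_add_node <- function(st, v, t) {
  if (v > st$n_max) stop("node id exceeds reserved capacity", call. = FALSE)
  if (st$alive[v]) stop("node ", v, " already present", call. = FALSE)
  st$alive[v] <- TRUE
  st$t0[v] <- t
  st$death[v] <- NA_integer_
  st$parent[v] <- 0L
  st$layer[v] <- 0L
  st$node_tab[v] <- reg_add(st, resolve_target(st, st$node_target_spec,
                                               as.character(v)))
  st$last_node[v] <- t
  st$scur[v] <- TRUE
  st$S[v, t + 1L] <- 1L
  st$gens[[1L]] <- c(st$gens[[1L]], v)
  invisible(st)
}

st_add_edge <- function(st, a, b, t) {
  if (a == b) stop("self-loop in topology delta", call. = FALSE)
  if (!st$alive[a] || !st$alive[b])
    stop("topology delta references unknown node", call. = FALSE)
  if (any(st$edges[, 1L] == min(a, b) & st$edges[, 2L] == max(a, b))) {
    warning("duplicate edge ", min(a, b), "-", max(a, b), " ignored")
    return(invisible(st))
  }
  st_add_edge_record(st, a, b, t)
  if (st_root_of(st, a) != st_root_of(st, b)) {
    # components merge: the new edge becomes a trunk, b's side re-rooted at b
    st_reroot(st, b)
    st$parent[b] <- a
    st$trunk_tab[b] <- reg_add(st, resolve_target(st, st$trunk_target_spec,
                                                  edge_key(a, b)))
    st$last_trunk[b] <- t   # endpoints are forced active at insertion
    rebuild_tree_struct(st)
  }
  invisible(st)
}

# Repair after losing the trunk above child `c`: reattach the orphaned
# subtree through a uniformly chosen surviving edge to the rest of its old
# component; if none exists, the subtree becomes its own tree rooted at `c`.
st_repair_trunk <- function(st, c) {
  st$parent[c] <- 0L
  sub <- st_descendants(st, c)
  in_sub_1 <- st$edges[, 1L] %in% sub
  in_sub_2 <- st$edges[, 2L] %in% sub
  cand <- which(xor(in_sub_1, in_sub_2))
  if (length(cand)) {
    r <- cand[sample.int(length(cand), 1L)]
    if (in_sub_1[r]) { y <- st$edges[r, 1L]; x <- st$edges[r, 2L] }
    else             { y <- st$edges[r, 2L]; x <- st$edges[r, 1L] }
    st_reroot(st, y)
    st$parent[y] <- x
    st$trunk_tab[y] <- reg_add(st, resolve_target(st, st$trunk_target_spec,
                                                  edge_key(x, y)))
    st$last_trunk[y] <- st_last_common(st, x, y)
  }
  rebuild_tree_struct(st)
  invisible(st)
}

st_remove_edge <- function(st, a, b, t) {
  i <- min(a, b); j <- max(a, b)
  r <- which(st$edges[, 1L] == i & st$edges[, 2L] == j)
  if (!length(r)) stop("edge ", i, "-", j, " not present", call. = FALSE)
  r <- r[1L]
  st$log_t1[st$log_open[r]] <- t - 1L
  st$edges <- st$edges[-r, , drop = FALSE]
  st$log_open <- st$log_open[-r]
  is_trunk_ab <- st$parent[j] == i || st$parent[i] == j
  if (is_trunk_ab) {
    child <- if (st$parent[j] == i) j else i
    st_repair_trunk(st, child)
  }
  invisible(st)
}

st_remove_node <- function(st, v, t) {
  if (!st$alive[v]) stop("node ", v, " not present", call. = FALSE)
  inc <- which(st$edges[, 1L] == v | st$edges[, 2L] == v)
  orphans <- integer(0)
  if (length(inc)) {
    # close all incident edges first so repairs cannot route through them
    st$log_t1[st$log_open[inc]] <- t - 1L
    kids <- which(st$alive & st$parent == v)
    orphans <- kids
    st$edges <- st$edges[-inc, , drop = FALSE]
    st$log_open <- st$log_open[-inc]
  }
  st$alive[v] <- FALSE
  st$death[v] <- t
  st$parent[v] <- 0L
  st$scur[v] <- FALSE
  for (c in orphans) st_repair_trunk(st, c)
  rebuild_tree_struct(st)
  invisible(st)
}

# ---- temporal Barabasi-Albert ------------------------------------------------

#' Configuration of the temporal Barabasi-Albert model
#'
#' @param m0 initial node count (the initial snapshot is a clique, so that
#'   degree-preferential attachment is well defined from the first arrival).
#' @param m links per arriving node, `1 <= m <= m0`.
#' @param final_N size at which growth stops.
#' @param g further activity-only steps on the frozen topology, `g >= 0`.
#' @return a list of class `temporal_ba_config`.
#' @export
temporal_ba_config <- function(m0 = 3L, m = 3L, final_N, g = 0L) {
  m0 <- as.integer(m0); m <- as.integer(m); final_N <- as.integer(final_N)
  g <- as.integer(g)
  if (!(1L <= m && m <= m0 && m0 < final_N))
    stop("need 1 <= m <= m0 < final_N", call. = FALSE)
  if (g < 0L) stop("g must be >= 0", call. = FALSE)
  structure(list(m0 = m0, m = m, final_N = final_N, g = g),
            class = "temporal_ba_config")
}

#' Construct a temporal network on a growing (temporal BA) topology
#'
#' Starts from a clique on `m0` nodes with a randomly selected spanning
#' tree. Each step: the existing system advances one activity step; then one
#' node arrives with `m` edges attached to distinct existing nodes chosen
#' with probability proportional to degree; the arriving node, its new links
#' (and hence their endpoints) start active; the spanning tree gains the new
#' node through one of its `m` links chosen uniformly. After `final_N` is
#' reached, `g` further activity-only steps run on the frozen topology.
#'
#' @param config a [temporal_ba_config()].
#' @param node_target,trunk_target targets as in [construct_static()].
#' @param seed optional integer seed.
#' @return a `temporal_network`.
#' @export
construct_temporal_ba <- function(config, node_target, trunk_target,
                                  seed = NULL) {
  stopifnot(inherits(config, "temporal_ba_config"))
  if (!is.null(seed)) set.seed(seed)
  t_tol <- (config$final_N - config$m0) + config$g
  clique <- igraph::make_full_graph(config$m0)
  st <- network_state(clique, node_target, trunk_target, t_tol,
                      tree_method = "uniform",
                      n_max = config$final_N, t_max = t_tol)
  precheck_consistency(st)
  deg <- integer(config$final_N)
  deg[seq_len(config$m0)] <- config$m0 - 1L

  for (t in seq_len(t_tol)) {
    step_network(st)
    if (t <= config$final_N - config$m0) {
      v <- config$m0 + t
      existing <- seq_len(v - 1L)
      targets <- if (length(existing) == config$m) existing
                 else sample(existing, config$m, prob = deg[existing])
      st_add_node(st, v, t)
      st$parent[v] <- targets[sample.int(length(targets), 1L)]
      st$layer[v] <- st$layer[st$parent[v]] + 1L
      st$trunk_tab[v] <- reg_add(st, resolve_target(
        st, st$trunk_target_spec, edge_key(st$parent[v], v)))
      st$last_trunk[v] <- t
      st$gens[[1L]] <- setdiff(st$gens[[1L]], v)
      lv <- st$layer[v] + 1L
      if (lv > length(st$gens)) st$gens[[lv]] <- v
      else st$gens[[lv]] <- c(st$gens[[lv]], v)
      for (w in targets) st_add_edge_record(st, w, v, t)
      force_active(st, c(v, targets))
      deg[targets] <- deg[targets] + 1L
      deg[v] <- config$m
    }
  }
  as_temporal_network(st)
}

# Preferential-attachment edge sequence alone (no activity); used to sanity
# check the degree law of the growth model at larger sizes.
ba_growth_edges <- function(m0, m, final_N) {
  deg <- integer(final_N)
  deg[seq_len(m0)] <- m0 - 1L
  el <- utils::combn(m0, 2L)
  edges <- list(t(el))
  for (v in (m0 + 1L):final_N) {
    existing <- seq_len(v - 1L)
    targets <- if (length(existing) == m) existing
               else sample(existing, m, prob = deg[existing])
    edges[[length(edges) + 1L]] <- cbind(targets, v)
    deg[targets] <- deg[targets] + 1L
    deg[v] <- m
  }
  do.call(rbind, edges)
}

# ---- general time-varying topologies ----------------------------------------

#' Construct a temporal network on a time-varying topology
#'
#' Drives the construction over an explicit sequence of topology deltas. At
#' each step `t`, the deltas scheduled for `t` are applied (node removals,
#' edge removals, node additions, edge additions, in that order), the
#' spanning forest is repaired, and the activity advances one step. Newly
#' added nodes and the endpoints of newly added edges start active. With no
#' deltas the run is identical in law to [construct_static()].
#'
#' Tree repair: when a trunk is removed, the orphaned subtree is reattached
#' through a uniformly chosen surviving edge to its old component (re-rooting
#' the subtree at the attachment point); if no such edge exists, the subtree
#' becomes a separate tree rooted at the orphan-side endpoint of the lost
#' trunk.
#'
#' @param topology initial `igraph` topology.
#' @param deltas list of deltas, each a list with `t` (step at which it is
#'   applied, `1 <= t <= t_tol`) and any of `add_nodes` (integer ids;
#'   reserve capacity via `n_max`), `add_edges` / `del_edges` (two-column
#'   matrices or lists of pairs), `del_nodes`. See [read_topology_deltas()].
#' @param node_target,trunk_target targets as in [construct_static()].
#' @param t_tol horizon.
#' @param seed optional integer seed.
#' @param tree,tree_method as in [construct_static()].
#' @param n_max node capacity (defaults to the largest id referenced).
#' @param validate check spanning-forest validity after every delta
#'   (slower; used by tests).
#' @return a `temporal_network`.
#' @export
construct_time_varying <- function(topology, deltas, node_target,
                                   trunk_target, t_tol, seed = NULL,
                                   tree = NULL, tree_method = "uniform",
                                   n_max = NULL, validate = FALSE) {
  stopifnot(t_tol >= 1)
  t_tol <- as.integer(t_tol)
  if (!is.null(seed)) set.seed(seed)
  ids <- unlist(lapply(deltas, function(d) d$add_nodes), use.names = FALSE)
  if (is.null(n_max))
    n_max <- max(igraph::vcount(topology), ids, 0L)
  st <- network_state(topology, node_target, trunk_target, t_tol,
                      tree = tree, tree_method = tree_method,
                      n_max = n_max, t_max = t_tol)
  precheck_consistency(st)
  by_t <- split(deltas, vapply(deltas, function(d) as.integer(d$t),
                               integer(1)))

  as_pairs <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) return(x)
    do.call(rbind, lapply(x, function(e) as.integer(unlist(e))))
  }

  for (t in seq_len(t_tol)) {
    forced <- integer(0)
    fresh <- integer(0)
    for (d in by_t[[as.character(t)]] %||% list()) {
      for (v in d$del_nodes %||% integer(0)) st_remove_node(st, v, t)
      de <- as_pairs(d$del_edges)
      for (r in seq_len(NROW(de))) st_remove_edge(st, de[r, 1L], de[r, 2L], t)
      for (v in d$add_nodes %||% integer(0)) {
        st_add_node(st, v, t)
        fresh <- c(fresh, v)
      }
      ae <- as_pairs(d$add_edges)
      for (r in seq_len(NROW(ae))) {
        st_add_edge(st, ae[r, 1L], ae[r, 2L], t)
        forced <- c(forced, ae[r, 1L], ae[r, 2L])
      }
      if (validate) {
        chk <- validate_state_forest(st)
        if (!isTRUE(chk)) stop("forest invalid after delta at t=", t, ": ",
                               chk, call. = FALSE)
      }
    }
    step_network(st, exclude = unique(c(fresh, forced)))
    force_active(st, unique(c(fresh, forced)))
  }
  as_temporal_network(st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Forest validity of a live state (trunks are current edges, layers
# consistent, trunk count = alive N - #components of the live topology).
validate_state_forest <- function(st) {
  alive <- which(st$alive)
  g <- igraph::graph_from_edgelist(st$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, st$n_max - igraph::vcount(g)))
  g <- igraph::induced_subgraph(g, alive)
  idx <- match(seq_len(st$n_max), alive)   # old id -> new id
  parent <- st$parent[alive]
  parent[parent > 0L] <- idx[parent[parent > 0L]]
  tr <- tryCatch(tree_from_parent(parent, g), error = function(e) NULL)
  if (is.null(tr)) return("parent vector is not a forest")
  validate_spanning_forest(tr, g)
}

#' Read topology deltas from a JSON-lines file
#'
#' Each line is a JSON object
#' `{"t": 5, "add_nodes": [11], "add_edges": [[3, 11]], "del_edges": [[1, 2]],
#' "del_nodes": [7]}`; absent fields mean no change of that kind.
#'
#' @param path file path.
#' @return a list of deltas suitable for [construct_time_varying()].
#' @export
read_topology_deltas <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    d <- jsonlite::fromJSON(l, simplifyMatrix = TRUE)
    d$t <- as.integer(d$t)
    d
  })
}
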