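# Container for a constructed temporal network: per-node activation time
# lists plus the edge history. Link activity is never stored: a link is
# active exactly when both its endpoints are, so link activation times are
# computed lazily as intersections of endpoint activation lists. This keeps
# construction cost O(N * t_tol), independent of edge density.

new_temporal_network <- function(node_act, node_t0, node_t1, edge_log,
                                 topology, tree, t_tol, engine) {
  structure(list(node_act = node_act, node_t0 = node_t0, node_t1 = node_t1,
                 edge_log = edge_log, topology = topology, tree = tree,
                 t_tol = as.integer(t_tol), engine = engine),
            class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf(
    "<temporal_network> %d node(s), %d edge record(s), t = 0..%d (%s engine)\n",
    sum(!is.na(x$node_t0)), nrow(x$edge_log), x$t_tol, x$engine))
  invisible(x)
}

#' Activation times of nodes and links
#'
#' Activation times are 0-based (every unit present from the start is active
#' at t = 0). Link activations are derived lazily: a link is active exactly
#' when both endpoints are active and the link exists, so its activation
#' times are the intersection of the endpoint activation lists restricted to
#' the link's lifetime.
#'
#' @param net a `temporal_network`.
#' @param v node id (integer); if `NULL`, a list over all nodes.
#' @return integer vector(s) of activation times.
#' @export
node_activations <- function(net, v = NULL) {
  stopifnot(inherits(net, "temporal_network"))
  if (is.null(v)) return(net$node_act)
  net$node_act[[v]]
}

#' @rdname node_activations
#' @param i,j endpoints of a link present in the topology.
#' @export
link_activations <- function(net, i, j) {
  stopifnot(inherits(net, "temporal_network"))
  a <- min(i, j); b <- max(i, j)
  rows <- which(net$edge_log$i == a & net$edge_log$j == b)
  if (!length(rows)) stop("no such edge: ", a, "-", b, call. = FALSE)
  common <- intersect(net$node_act[[a]], net$node_act[[b]])
  out <- integer(0)
  for (r in rows)
    out <- c(out, common[common >= net$edge_log$t0[r] &
                           common <= net$edge_log$t1[r]])
  sort(unique(out))
}

#' Binary state vector of one node
#'
#' @param net a `temporal_network`.
#' @param v node id.
#' @return integer 0/1 vector indexed by time `0..t_tol` (`NA` outside the
#'   node's lifetime).
#' @export
node_states <- function(net, v) {
  stopifnot(inherits(net, "temporal_network"))
  out <- rep(NA_integer_, net$t_tol + 1L)
  if (is.na(net$node_t0[v])) return(out)
  live <- seq.int(net$node_t0[v], net$node_t1[v]) + 1L
  out[live] <- 0L
  out[net$node_act[[v]] + 1L] <- 1L
  out
}

#' Active links at one time step
#'
#' @param net a `temporal_network`.
#' @param t time step in `0..t_tol`.
#' @return two-column matrix of edges whose both endpoints are active at `t`
#'   (and which exist at `t`).
#' @export
active_links <- function(net, t) {
  stopifnot(inherits(net, "temporal_network"), t >= 0, t <= net$t_tol)
  on <- vapply(seq_along(net$node_act), function(v) {
    a <- net$node_act[[v]]
    !is.null(a) && t %in% a
  }, logical(1))
  el <- net$edge_log
  live <- el$t0 <= t & el$t1 >= t & on[el$i] & on[el$j]
  unique(cbind(i = el$i[live], j = el$j[live]))
}
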