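# Spanning trees / forests of the underlying topology. Edges inside the tree
# are "trunks" (their activity is sampled by the coupled renewal updates);
# edges outside are "branches" (their activity is derived as the product of
# their endpoint states).

edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

# Assemble layers, update order and trunk/branch split from a parent vector.
tree_from_parent <- function(parent, topology = NULL) {
  n <- length(parent)
  roots <- which(parent == 0L)
  kids <- split(which(parent > 0L), parent[parent > 0L])
  layer <- rep(NA_integer_, n)
  ord <- integer(0)
  frontier <- sort(roots)
  l <- 0L
  while (length(frontier)) {
    layer[frontier] <- l
    ord <- c(ord, frontier)
    # sorted within layers so the update (and RNG draw) order is canonical
    frontier <- sort(unlist(kids[as.character(frontier)], use.names = FALSE))
    l <- l + 1L
  }
  if (length(ord) != n)
    stop("parent vector does not describe a forest", call. = FALSE)
  child <- which(parent > 0L)
  trunks <- cbind(parent = parent[child], child = child)
  branches <- NULL
  if (!is.null(topology)) {
    el <- igraph::as_edgelist(topology, names = FALSE)
    is_trunk <- edge_key(el[, 1L], el[, 2L]) %in%
      edge_key(trunks[, 1L], trunks[, 2L])
    branches <- el[!is_trunk, , drop = FALSE]
  }
  structure(list(n = n, parent = parent, layer = layer, order = ord,
                 roots = roots, trunks = trunks, branches = branches),
            class = "spanning_tree")
}

#' Select a spanning tree (or forest) of an underlying topology
#'
#' `method = "uniform"` samples uniformly among all spanning trees of each
#' connected component using Wilson's loop-erased random-walk algorithm;
#' `method = "bfs"` grows a breadth-first tree from a random root (faster,
#' not uniform). Disconnected topologies yield a spanning forest with one
#' root per component.
#'
#' @param topology an `igraph` undirected simple graph.
#' @param method `"uniform"` or `"bfs"`.
#' @param root optional root vertex id; components not containing it get a
#'   random root.
#' @return an object of class `spanning_tree` with fields `parent` (0 for
#'   roots), `layer` (hop distance from the root), `order` (update order,
#'   parents before children), `roots`, `trunks` (two-column matrix
#'   parent/child) and `branches` (two-column matrix of off-tree edges).
#' @export
select_spanning_tree <- function(topology, method = c("uniform", "bfs"),
                                 root = NULL) {
  method <- match.arg(method)
  n <- igraph::vcount(topology)
  if (n < 1L) stop("empty topology", call. = FALSE)
  adj <- lapply(igraph::as_adj_list(topology), as.integer)
  comp <- igraph::components(topology)$membership
  parent <- integer(n)
  in_tree <- logical(n)

  for (cc in unique(comp)) {
    vs <- which(comp == cc)
    r <- if (!is.null(root) && root %in% vs) as.integer(root)
         else vs[sample.int(length(vs), 1L)]
    in_tree[r] <- TRUE
    if (method == "uniform") {
      nxt <- integer(n)
      for (v in vs) {
        if (in_tree[v]) next
        u <- v
        while (!in_tree[u]) {             # random walk until hitting the tree
          nb <- adj[[u]]
          u2 <- nb[sample.int(length(nb), 1L)]
          nxt[u] <- u2
          u <- u2
        }
        u <- v
        while (!in_tree[u]) {             # retrace the loop-erased path
          in_tree[u] <- TRUE
          parent[u] <- nxt[u]
          u <- nxt[u]
        }
      }
    } else {
      frontier <- r
      while (length(frontier)) {
        nxt_frontier <- integer(0)
        for (u in frontier) {
          nb <- adj[[u]]
          nb <- nb[!in_tree[nb]]
          if (length(nb)) {
            in_tree[nb] <- TRUE
            parent[nb] <- u
            nxt_frontier <- c(nxt_frontier, nb)
          }
        }
        frontier <- nxt_frontier
      }
    }
  }
  tree_from_parent(parent, topology)
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf(
    "<spanning_tree> %d nodes, %d trunk(s), %d branch(es), %d root(s)\n",
    x$n, nrow(x$trunks),
    if (is.null(x$branches)) NA_integer_ else nrow(x$branches),
    length(x$roots)))
  invisible(x)
}

# Structural validity of a spanning forest against a topology: trunks are
# real edges, parents sit one layer above children, trunk count matches
# N - (#components), and tree components coincide with graph components.
validate_spanning_forest <- function(tree, topology) {
  n <- igraph::vcount(topology)
  if (tree$n != n) return("node count mismatch")
  el <- igraph::as_edgelist(topology, names = FALSE)
  ek <- edge_key(el[, 1L], el[, 2L])
  tk <- edge_key(tree$trunks[, 1L], tree$trunks[, 2L])
  if (!all(tk %in% ek)) return("trunk not in topology")
  if (anyDuplicated(tk)) return("duplicated trunk")
  nc <- igraph::components(topology)$no
  if (nrow(tree$trunks) != n - nc) return("trunk count != N - #components")
  ch <- which(tree$parent > 0L)
  if (!all(tree$layer[ch] == tree$layer[tree$parent[ch]] + 1L))
    return("parent not in previous layer")
  comp <- igraph::components(topology)$membership
  if (!all(comp[ch] == comp[tree$parent[ch]]))
    return("trunk crosses components")
  TRUE
}
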