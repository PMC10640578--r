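# Contact-file input/output (SocioPatterns-style timestamped triplets),
# edge-list files and seeded fixture topologies. File convention: node ids
# are 0-based and timesteps 1-based in files (aggregation runs from t = 1);
# in-memory vertex ids are 1-based igraph ids.

#' Write a temporal network as a contact-triplet file
#'
#' One line per active link per step, tab-separated `t i j` with `t >= 1`,
#' 0-based node ids and `i < j`, sorted by `t` then `(i, j)` — mirroring the
#' format of empirical face-to-face contact data.
#'
#' @param net a `temporal_network`.
#' @param path output file.
#' @return number of lines written, invisibly.
#' @export
write_contacts <- function(net, path) {
  stopifnot(inherits(net, "temporal_network"))
  el <- unique(net$edge_log[, c("i", "j")])
  rows <- lapply(seq_len(nrow(el)), function(r) {
    a <- link_activations(net, el$i[r], el$j[r])
    a <- a[a >= 1L]
    if (!length(a)) return(NULL)
    data.frame(t = a, i = el$i[r] - 1L, j = el$j[r] - 1L)
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev)) ev <- data.frame(t = integer(), i = integer(),
                                    j = integer())
  ev <- ev[order(ev$t, ev$i, ev$j), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d\t%d\t%d", ev$t, ev$i, ev$j), con)
  invisible(nrow(ev))
}

#' Read a contact-triplet file
#'
#' Lines are whitespace-separated `t i j`; the `"sociopatterns"` dialect
#' tolerates extra metadata columns and raw epoch timestamps. Raw timestamps
#' are compressed to consecutive integers starting at 1 (one integer per
#' distinct raw timestamp); node ids are remapped densely to `1..N`.
#' Self-contacts are skipped with a warning; duplicate triplets collapse to
#' one event; a malformed line is a parse error reporting the line number.
#'
#' @param path input file.
#' @param dialect `"triplet"` (exactly three fields) or `"sociopatterns"`.
#' @return list with `events` (data frame `t, i, j`, internal ids),
#'   `node_map` (data frame `original`, `id`), `time_map` (data frame `raw`,
#'   `t`) and `t_tol` (number of distinct timestamps).
#' @export
read_contacts <- function(path, dialect = c("triplet", "sociopatterns")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  lineno <- which(keep)
  nf <- lengths(toks)
  bad <- if (dialect == "triplet") nf != 3L else nf < 3L
  first3 <- lapply(toks, function(x) suppressWarnings(as.numeric(x[1:3])))
  bad <- bad | vapply(first3, anyNA, logical(1))
  if (any(bad))
    stop("malformed contact line ", lineno[which(bad)[1L]], " in ", path,
         call. = FALSE)
  m <- do.call(rbind, first3)
  if (nrow(m) == 0L || is.null(m))
    return(list(events = data.frame(t = integer(), i = integer(),
                                    j = integer()),
                node_map = data.frame(original = numeric(), id = integer()),
                time_map = data.frame(raw = numeric(), t = integer()),
                t_tol = 0L))
  self <- m[, 2L] == m[, 3L]
  if (any(self)) {
    warning(sum(self), " self-contact(s) skipped")
    m <- m[!self, , drop = FALSE]
  }
  raw_t <- sort(unique(m[, 1L]))
  t <- match(m[, 1L], raw_t)
  raw_ids <- sort(unique(c(m[, 2L], m[, 3L])))
  i <- match(m[, 2L], raw_ids)
  j <- match(m[, 3L], raw_ids)
  ev <- unique(data.frame(t = t, i = pmin(i, j), j = pmax(i, j)))
  ev <- ev[order(ev$t, ev$i, ev$j), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev,
       node_map = data.frame(original = raw_ids,
                             id = seq_along(raw_ids)),
       time_map = data.frame(raw = raw_t, t = seq_along(raw_t)),
       t_tol = length(raw_t))
}

#' Aggregate contact events into an underlying topology
#'
#' Link `(i, j)` exists if individuals `i` and `j` interact at least once.
#'
#' @param events data frame `t, i, j` as returned by [read_contacts()].
#' @return an `igraph` undirected simple graph.
#' @export
build_topology_from_events <- function(events) {
  if (nrow(events) == 0L) stop("empty event stream", call. = FALSE)
  pairs <- unique(cbind(events$i, events$j))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  want <- max(events$i, events$j)
  igraph::add_vertices(g, max(0L, want - igraph::vcount(g)))
}

#' Generate a seeded fixture topology
#'
#' Reproducible graphs from named families: Barabasi-Albert (`"ba"`, `m0 = m`
#' clique seed, so `|E| = choose(m, 2) + (n - m) m`), Watts-Strogatz
#' (`"ws"`), random regular (`"random_regular"`), and the deterministic
#' `"complete"`, `"path"`, `"star"`.
#'
#' @param family one of `"ba"`, `"ws"`, `"random_regular"`, `"complete"`,
#'   `"path"`, `"star"`.
#' @param n number of nodes.
#' @param m edges per new node (`ba`).
#' @param k degree (`random_regular`).
#' @param nei,p neighborhood radius and rewiring probability (`ws`).
#' @param seed optional integer seed.
#' @return an `igraph` graph.
#' @export
generate_fixture_topology <- function(family = c("ba", "ws",
                                                 "random_regular",
                                                 "complete", "path", "star"),
                                      n, m = 3L, k = 4L, nei = 3L, p = 0.1,
                                      seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  if (n < 1) stop("n must be positive", call. = FALSE)
  switch(family,
    ba = igraph::sample_pa(n, m = m, directed = FALSE,
                           start.graph = igraph::make_full_graph(m)),
    ws = igraph::sample_smallworld(1, n, nei, p),
    random_regular = igraph::sample_k_regular(n, k),
    complete = igraph::make_full_graph(n),
    path = igraph::make_ring(n, circular = FALSE),
    star = igraph::make_star(n, mode = "undirected"))
}

#' Read / write an edge-list file
#'
#' Two whitespace-separated columns of 0-based node ids, one edge per line.
#'
#' @param path file path.
#' @param n optional node count (defaults to `max id + 1`).
#' @return `read_edgelist()` an `igraph`; `write_edgelist()` the path,
#'   invisibly.
#' @export
read_edgelist <- function(path, n = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   col.names = c("i", "j")))
  g <- igraph::graph_from_edgelist(m + 1L, directed = FALSE)
  if (!is.null(n) && n > igraph::vcount(g))
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' @rdname read_edgelist
#' @param topology an `igraph` graph.
#' @export
write_edgelist <- function(topology, path) {
  el <- igraph::as_edgelist(topology, names = FALSE) - 1L
  utils::write.table(el, path, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}
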