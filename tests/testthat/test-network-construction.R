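# Static construction: reduction to the two-node sampler, engine agreement,
# the product identity, synchrony on stars, trunk-count identity, topology
# and tree-choice robustness, branch IET tail bounds.

nt_pl2 <- list(kind = "power_law", exponent = 2)
tt_pl19 <- list(kind = "power_law", exponent = 1.9)

test_that("two-node topology reduces exactly to the two-node sampler", {
  g <- generate_fixture_topology("path", n = 2)
  tree <- burstnet:::tree_from_parent(c(0L, 1L), g)
  t_tol <- 400L
  set.seed(17)
  net <- construct_static(g, nt_pl2, tt_pl19, t_tol, tree = tree,
                          engine = "r")
  set.seed(17)
  sys <- two_node_system(pl(2, t_tol + 1L), pl(2, t_tol + 1L),
                         pl(1.9, t_tol + 1L))
  for (k in seq_len(t_tol)) sys <- step_two_node(sys)
  expect_identical(node_states(net, 1), sys$x$states)
  expect_identical(node_states(net, 2), sys$y$states)
  expect_identical(link_activations(net, 1, 2) + 1L,
                   which(sys$z$states == 1L))
})

test_that("compiled and reference engines are draw-for-draw identical", {
  g <- generate_fixture_topology("ba", n = 80, m = 3, seed = 5)
  set.seed(2)
  tree <- select_spanning_tree(g, "uniform")
  set.seed(7)
  n1 <- construct_static(g, nt_pl2, tt_pl19, 250L, tree = tree,
                         engine = "cpp")
  set.seed(7)
  n2 <- construct_static(g, nt_pl2, tt_pl19, 250L, tree = tree, engine = "r")
  expect_identical(lapply(n1$node_act, as.integer),
                   lapply(unname(n2$node_act), as.integer))
})

test_that("star with F = G = H is fully synchronous", {
  g <- generate_fixture_topology("star", n = 8)
  net <- construct_static(g, nt_pl2, nt_pl2, 300L, seed = 5)
  ref <- node_states(net, 1)
  for (v in 2:8) expect_identical(node_states(net, v), ref)
  # and so is every link
  for (v in 2:8)
    expect_identical(link_activations(net, 1, v), node_activations(net, 1))
})

test_that("product identity holds for every edge at every step", {
  g <- generate_fixture_topology("ws", n = 25, nei = 2, p = 0.2, seed = 3)
  net <- construct_static(g, nt_pl2, tt_pl19, 120L, seed = 8)
  S <- vapply(seq_len(25), function(v) node_states(net, v),
              integer(net$t_tol + 1L))
  el <- igraph::as_edgelist(net$topology, names = FALSE)
  for (r in seq_len(nrow(el))) {
    la <- link_activations(net, el[r, 1], el[r, 2])
    prod_on <- which(S[, el[r, 1]] * S[, el[r, 2]] == 1L) - 1L
    expect_identical(la, prod_on)
  }
  # active link count at a step = edges with both endpoints active
  for (t in c(0L, 13L, 120L))
    expect_equal(nrow(active_links(net, t)),
                 sum(S[t + 1L, el[, 1]] * S[t + 1L, el[, 2]]))
})

test_that("trunk-count identity and forests on disconnected topologies", {
  g <- igraph::disjoint_union(generate_fixture_topology("ba", n = 20, m = 2,
                                                        seed = 1),
                              generate_fixture_topology("complete", n = 6))
  net <- construct_static(g, nt_pl2, tt_pl19, 60L, seed = 12)
  expect_equal(nrow(net$tree$trunks), 26L - 2L)
  expect_true(isTRUE(burstnet:::validate_spanning_forest(net$tree,
                                                         net$topology)))
})

test_that("t_tol = 1 yields two snapshots with an all-active start", {
  g <- generate_fixture_topology("path", n = 3)
  net <- construct_static(g, nt_pl2, tt_pl19, 1L, seed = 2)
  expect_equal(net$t_tol, 1L)
  for (v in 1:3) expect_equal(node_states(net, v)[1], 1L)
})

test_that("inconsistent targets abort with the offending trunk identified", {
  g <- generate_fixture_topology("path", n = 3)
  err <- tryCatch(
    construct_static(g, list(kind = "discrete_exponential", exponent = 1),
                     list(kind = "discrete_exponential", exponent = 0.2),
                     50L, seed = 1),
    condition = identity)
  expect_s3_class(err, "burstnet_inconsistency")
})

test_that("node exponents are robust to topology (sparse vs well-mixed)", {
  fits <- sapply(c(5, 199), function(k) {
    mean(sapply(1:3, function(s) {
      set.seed(1000 + 7 * k + s)
      g <- generate_fixture_topology("random_regular", n = 200, k = k)
      net <- construct_static(g, nt_pl2, tt_pl19, 3000L)
      fit_discrete_power_law(extract_intervals(net, "node_iet"))$exponent_hat
    }))
  })
  expect_lt((max(fits) - min(fits)) / min(fits), 0.04)
})

test_that("the construction is stable to the choice of spanning tree", {
  fit_both <- function(method, s) {
    set.seed(3000 + s)
    g <- generate_fixture_topology("ba", n = 100, m = 3)
    net <- construct_static(g, nt_pl2, tt_pl19, 2000L, tree_method = method)
    c(node = fit_discrete_power_law(
        extract_intervals(net, "node_iet"))$exponent_hat,
      link = fit_discrete_power_law(
        extract_intervals(net, "link_iet"))$exponent_hat)
  }
  eu <- vapply(1:20, function(s) fit_both("uniform", s), numeric(2))
  eb <- vapply(1:20, function(s) fit_both("bfs", s), numeric(2))
  # node laws are tree-independent exactly: means agree within 3 s.e.
  se_n <- sqrt(var(eu["node", ]) / 20 + var(eb["node", ]) / 20)
  expect_lt(abs(mean(eu["node", ]) - mean(eb["node", ])), 3 * se_n)
  # pooled link fits shift slightly with the branch mix (branches pull the
  # exponent below the trunk target); stability is a <= 4% relative
  # deviation between tree methods, the same scale as topology robustness
  ml <- c(mean(eu["link", ]), mean(eb["link", ]))
  expect_lte((max(ml) - min(ml)) / min(ml), 0.04)
  expect_true(all(ml < 1.9))     # branches pull the fit below the target
  expect_true(all(ml > 1.6))
})

test_that("branch IET survival slopes bracket the trunk target", {
  set.seed(31)
  g <- generate_fixture_topology("complete", n = 50)
  net <- construct_static(g, nt_pl2, tt_pl19, 5000L)
  per <- extract_intervals(net, "link_iet", "per_unit")
  trunk_keys <- burstnet:::edge_key(net$tree$trunks[, 1],
                                    net$tree$trunks[, 2])
  slopes <- c()
  for (nm in setdiff(names(per), trunk_keys)) {
    gp <- per[[nm]]
    if (length(gp) < 300) next
    x <- 2:100
    surv <- vapply(x, function(v) mean(gp > v), numeric(1))
    keep <- surv > 20 / length(gp)
    if (sum(keep) < 10) next
    slopes <- c(slopes, unname(coef(lm(log(surv[keep]) ~ log(x[keep])))[2]))
  }
  expect_gt(length(slopes), 100)
  expect_lt(abs(median(slopes) - (-(1.9 - 1))), 0.3)
})

test_that("per-unit target maps are honoured", {
  g <- generate_fixture_topology("path", n = 3)
  tree <- burstnet:::tree_from_parent(c(0L, 1L, 2L), g)
  nt <- list(`1` = list(kind = "power_law", exponent = 2),
             `2` = list(kind = "power_law", exponent = 2),
             `3` = list(kind = "power_law", exponent = 2.0))
  tt <- list(`1-2` = list(kind = "power_law", exponent = 1.9),
             `2-3` = list(kind = "power_law", exponent = 1.8))
  net <- construct_static(g, nt, tt, 2000L, seed = 6, tree = tree)
  per <- extract_intervals(net, "link_iet", "per_unit")
  f12 <- fit_discrete_power_law(per[["1-2"]], censored = NULL, min_n = 30)
  f23 <- fit_discrete_power_law(per[["2-3"]], censored = NULL, min_n = 30)
  expect_lt(abs(f12$exponent_hat - 1.9), 3 * f12$se + 0.1)
  expect_lt(abs(f23$exponent_hat - 1.8), 3 * f23$se + 0.1)
  expect_error(construct_static(g, nt[1:2], tt, 50L, tree = tree),
               "no target")
})
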