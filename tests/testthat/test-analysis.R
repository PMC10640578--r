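# Interval extraction, MLE fits, burstiness/memory, aggregation.

mini_net <- function(acts, t_tol, edges = NULL) {
  n <- length(acts)
  el <- if (is.null(edges))
    data.frame(i = integer(), j = integer(), t0 = integer(), t1 = integer())
  else data.frame(i = edges[, 1], j = edges[, 2], t0 = 0L, t1 = t_tol)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  burstnet:::new_temporal_network(
    node_act = acts, node_t0 = rep(0L, n), node_t1 = rep(t_tol, n),
    edge_log = el, topology = g, tree = NULL, t_tol = t_tol, engine = "r")
}

test_that("interval extraction follows the definitions", {
  # node trajectory 1,0,0,1,1 -> IETs {3, 1}
  net <- mini_net(list(c(0L, 3L, 4L)), 4L)
  per <- extract_intervals(net, "node_iet", "per_unit")
  expect_identical(as.integer(per[["1"]]), c(3L, 1L))
  expect_length(attr(per[["1"]], "censored"), 0L)  # active at the end
  # censored tail when the last activation is not at t_tol
  net2 <- mini_net(list(c(0L, 2L)), 6L)
  agg <- extract_intervals(net2, "node_iet")
  expect_identical(as.integer(agg), 2L)
  expect_identical(attr(agg, "censored"), 4L)
  # units with < 2 activations contribute no gaps, silently
  net3 <- mini_net(list(c(0L, 1L, 5L), c(0L)), 5L,
                   edges = cbind(1L, 2L))
  agg3 <- extract_intervals(net3, "node_iet")
  expect_identical(as.integer(agg3), c(1L, 4L))
  expect_equal(attr(agg3, "n_units"), 2L)
})

test_that("pooling equals the union of per-unit multisets", {
  g <- generate_fixture_topology("ba", n = 30, m = 2, seed = 2)
  net <- construct_static(g, list(kind = "power_law", exponent = 2),
                          list(kind = "power_law", exponent = 1.9),
                          200L, seed = 3)
  for (mode in c("node_iet", "link_iet", "node_ict")) {
    per <- extract_intervals(net, mode, "per_unit")
    agg <- extract_intervals(net, mode, "aggregated")
    expect_identical(as.integer(agg),
                     as.integer(unlist(per, use.names = FALSE)))
  }
})

test_that("on a two-node system the node ICT equals the link IET", {
  g <- generate_fixture_topology("path", n = 2)
  net <- construct_static(g, list(kind = "power_law", exponent = 2),
                          list(kind = "power_law", exponent = 1.9),
                          400L, seed = 21)
  ict <- extract_intervals(net, "node_ict", "per_unit")
  liet <- extract_intervals(net, "link_iet", "per_unit")[["1-2"]]
  expect_identical(as.integer(ict[["1"]]), as.integer(liet))
  expect_identical(as.integer(ict[["2"]]), as.integer(liet))
})

test_that("node ICT converges to the IET as degree grows (median KS)", {
  ks_one <- function(k, s) {
    set.seed(8000 + 13 * k + s)
    g <- generate_fixture_topology("random_regular", n = 64, k = k)
    net <- construct_static(g, list(kind = "power_law", exponent = 2),
                            list(kind = "power_law", exponent = 1.9), 1500L)
    iet <- extract_intervals(net, "node_iet")
    ict <- extract_intervals(net, "node_ict")
    xs <- 1:50
    f1 <- vapply(xs, function(v) mean(iet <= v), numeric(1))
    f2 <- vapply(xs, function(v) mean(ict <= v), numeric(1))
    max(abs(f1 - f2))
  }
  med <- vapply(c(2, 8, 32), function(k)
    median(vapply(1:10, function(s) ks_one(k, s), numeric(1))), numeric(1))
  expect_gt(med[1], med[2])
  expect_gt(med[2], med[3])
})

test_that("discrete power-law MLE recovers a known exponent", {
  set.seed(5)
  d <- iet_distribution("power_law", 2.5, 100000L)
  f <- fit_discrete_power_law(riet(1e5, d))
  expect_lt(abs(f$exponent_hat - 2.5), 0.05)
  expect_lt(f$ks_distance, 0.01)
  expect_error(fit_discrete_power_law(rep(3L, 100)), "degenerate")
  expect_error(fit_discrete_power_law(c(1L, 2L)), "too few")
})

test_that("xmin handling: explicit xmin and the Clauset-style scan", {
  set.seed(6)
  d <- iet_distribution("power_law", 2.2, 100000L)
  # exact power-law tail conditioned on g >= 5, contaminated below
  tail5 <- sample(5:100000, 3e4, replace = TRUE, prob = d$pmf[5:100000])
  x <- c(tail5, sample(1:4, 2e4, replace = TRUE))
  f5 <- fit_discrete_power_law(x, xmin = 5L)
  expect_lt(abs(f5$exponent_hat - 2.2), 3 * f5$se + 0.01)
  fs <- fit_discrete_power_law(x, scan_xmin = TRUE)
  expect_gt(fs$xmin, 1L)
  expect_lt(fs$ks_distance, fit_discrete_power_law(x)$ks_distance)
  expect_lt(fs$ks_distance, 0.02)
})

test_that("discrete exponential MLE: closed form, boundary flag", {
  set.seed(7)
  d <- iet_distribution("discrete_exponential", 2, 1000L)
  f <- fit_discrete_exponential(riet(1e5, d))
  expect_lt(abs(f$exponent_hat - 2), 0.02)
  fb <- fit_discrete_exponential(rep(1L, 100))
  expect_true(fb$boundary)
  expect_identical(fb$exponent_hat, Inf)
  # censoring enters the closed form: A / (A + n)
  f2 <- fit_discrete_exponential(c(2L, 2L), censored = c(10L), min_n = 1L)
  expect_equal(f2$exponent_hat, -log(12 / 14), tolerance = 1e-12)
})

test_that("burstiness is signed by construction type; memoryless acf ~ 0", {
  expect_equal(burstiness_and_memory(rep(4, 10))$B, -1)
  g <- generate_fixture_topology("ba", n = 40, m = 2, seed = 4)
  bursty <- construct_static(g, list(kind = "power_law", exponent = 2),
                             list(kind = "power_law", exponent = 1.9),
                             800L, seed = 5)
  pois <- construct_static(g, list(kind = "discrete_exponential",
                                   exponent = 2.5),
                           list(kind = "discrete_exponential", exponent = 2),
                           800L, seed = 5)
  expect_gt(burstiness_and_memory(extract_intervals(bursty, "node_iet"))$B, 0)
  expect_lt(burstiness_and_memory(extract_intervals(pois, "node_iet"))$B, 0)
  # constant-hazard activity is an iid Bernoulli series: acf at lag >= 1 ~ 0
  act <- lapply(1:10, function(v) node_states(pois, v))
  bm <- burstiness_and_memory(extract_intervals(pois, "node_iet"),
                              activity = act, max_lag = 5L)
  expect_equal(unname(bm$autocorrelation["0"]), 1, tolerance = 1e-12)
  expect_lt(max(abs(bm$autocorrelation[-1])), 3 / sqrt(800))
  # bursty activity carries memory
  bmb <- burstiness_and_memory(extract_intervals(bursty, "node_iet"),
                               activity = lapply(1:10, function(v)
                                 node_states(bursty, v)), max_lag = 5L)
  expect_gt(bmb$autocorrelation[["1"]], 3 / sqrt(800))
  expect_error(burstiness_and_memory(integer(0)), "at least 2")
})

test_that("aggregation counts activations and satisfies the handshake identity", {
  # single edge active at t in {1, 3} within a 3-step toy -> weight 2
  net <- mini_net(list(c(0L, 1L, 3L), c(0L, 1L, 2L, 3L)), 3L,
                  edges = cbind(1L, 2L))
  agg <- aggregate_and_strengths(net, 3L)
  expect_equal(agg$weights$w, 2)
  expect_equal(sum(agg$strengths), 2 * sum(agg$weights$w))
  expect_error(aggregate_and_strengths(net, 3L, t_base = 5L), "t_base")
  # conservation: total weight = number of (t, active link) events, t >= 1
  g <- generate_fixture_topology("ws", n = 20, nei = 2, p = 0.1, seed = 6)
  net2 <- construct_static(g, list(kind = "power_law", exponent = 2),
                           list(kind = "power_law", exponent = 1.9),
                           100L, seed = 7)
  agg2 <- aggregate_and_strengths(net2, 100L)
  events <- sum(vapply(1:100, function(t) nrow(active_links(net2, t)),
                       numeric(1)))
  expect_equal(sum(agg2$weights$w), events)
})

test_that("BA strength survival keeps the degree-law slope across t_agg", {
  set.seed(33)
  g <- generate_fixture_topology("ba", n = 600, m = 3)
  net <- construct_static(g, list(kind = "discrete_exponential",
                                  exponent = 2.5),
                          list(kind = "discrete_exponential", exponent = 2),
                          2000L)
  slope_surv <- function(x, lo, hi) {
    xs <- sort(unique(x))
    sv <- vapply(xs, function(v) mean(x > v), numeric(1))
    k <- xs >= lo & xs <= hi & sv > 0
    unname(coef(lm(log(sv[k]) ~ log(xs[k])))[2])
  }
  dslope <- slope_surv(igraph::degree(g), 4, 40)
  sl <- vapply(c(500L, 2000L), function(ta) {
    s <- aggregate_and_strengths(net, ta)$strengths
    slope_surv(s, quantile(s, 0.5), quantile(s, 0.99))
  }, numeric(1))
  expect_lt(abs(sl[1] - sl[2]), 0.2)          # independent of t_agg
  expect_lt(abs(mean(sl) - dslope), 0.35)     # same exponent as the topology
})

test_that("survival sup distance behaves as a metric on step curves", {
  a <- data.frame(s = c(1, 2, 3), surv = c(2 / 3, 1 / 3, 0))
  b <- data.frame(s = c(1.5, 2.5, 3.5), surv = c(2 / 3, 1 / 3, 0))
  expect_equal(survival_sup_distance(a, a), 0)
  expect_equal(survival_sup_distance(a, b), 1 / 3)
  # the strength-survival collapse check itself lives in test-acceptance.R
})
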