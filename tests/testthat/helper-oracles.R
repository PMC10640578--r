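# Independent oracles used across tests. These recompute hazards and joint
# step probabilities from raw probability-mass vectors with their own
# arithmetic, so they share no code path with the package's samplers.

# Effective waiting-time law of a distribution object: tabulated pmf plus
# the residual tail mass forced onto support_max + 1.
or_eff_pmf <- function(d) {
  res <- max(0, 1 - sum(d$pmf))
  c(d$pmf, res)
}

or_haz <- function(pe, g) {
  if (g >= length(pe)) return(1)
  s <- sum(pe[g:length(pe)])
  if (s <= 0) 1 else pe[g] / s
}

# Exact distribution of the first re-activation gap of node x in the coupled
# two-node chain, by dynamic programming over histories in which x has stayed
# inactive (the chain is Markov in the waiting-time triple, and while x is
# silent its gap equals the elapsed time).
or_first_gap_node <- function(Fd, Gd, Hd, horizon) {
  pf <- or_eff_pmf(Fd); pg <- or_eff_pmf(Gd); ph <- or_eff_pmf(Hd)
  mass <- c("1,1" = 1)          # (g_y, g_z) for x-silent histories
  out <- numeric(horizon)
  for (t in seq_len(horizon)) {
    nxt <- list()
    hx <- or_haz(pf, t)
    for (k in names(mass)) {
      g <- as.integer(strsplit(k, ",")[[1]])
      hy <- or_haz(pg, g[1]); hz <- or_haz(ph, g[2])
      m <- mass[[k]]
      out[t] <- out[t] + m * hx
      p3 <- hy - hz; p4 <- 1 + hz - hx - hy
      for (mv in list(c(p3, 1L, g[2] + 1L), c(p4, g[1] + 1L, g[2] + 1L))) {
        if (mv[1] <= 0) next
        kk <- paste(mv[2], mv[3], sep = ",")
        nxt[[kk]] <- (nxt[[kk]] %||% 0) + m * mv[1]
      }
    }
    mass <- unlist(nxt)
  }
  out
}

# Same for the link z (first time both nodes are simultaneously active).
or_first_gap_link <- function(Fd, Gd, Hd, horizon) {
  pf <- or_eff_pmf(Fd); pg <- or_eff_pmf(Gd); ph <- or_eff_pmf(Hd)
  mass <- c("1,1" = 1)          # (g_x, g_y) for z-silent histories
  out <- numeric(horizon)
  for (t in seq_len(horizon)) {
    nxt <- list()
    hz <- or_haz(ph, t)
    for (k in names(mass)) {
      g <- as.integer(strsplit(k, ",")[[1]])
      hx <- or_haz(pf, g[1]); hy <- or_haz(pg, g[2])
      m <- mass[[k]]
      out[t] <- out[t] + m * hz
      for (mv in list(c(hx - hz, 1L, g[2] + 1L),
                      c(hy - hz, g[1] + 1L, 1L),
                      c(1 + hz - hx - hy, g[1] + 1L, g[2] + 1L))) {
        if (mv[1] <= 0) next
        kk <- paste(mv[2], mv[3], sep = ",")
        nxt[[kk]] <- (nxt[[kk]] %||% 0) + m * mv[1]
      }
    }
    mass <- unlist(nxt)
  }
  out
}

# Brute force: enumerate every joint (x, y) state path up to `horizon`,
# weighting each path by the product of its joint step probabilities, and
# accumulate the first-gap laws of x and z plus the total path mass.
or_brute_force <- function(Fd, Gd, Hd, horizon = 6L) {
  pf <- or_eff_pmf(Fd); pg <- or_eff_pmf(Gd); ph <- or_eff_pmf(Hd)
  fx <- numeric(horizon); fz <- numeric(horizon)
  total <- 0
  rec <- function(t, gx, gy, gz, prob, x_first, z_first) {
    if (t > horizon) {
      total <<- total + prob
      return(invisible(NULL))
    }
    hx <- or_haz(pf, gx); hy <- or_haz(pg, gy); hz <- or_haz(ph, gz)
    p <- c(hz, hx - hz, hy - hz, 1 + hz - hx - hy)
    xs <- c(1L, 1L, 0L, 0L); ys <- c(1L, 0L, 1L, 0L)
    for (k in 1:4) {
      if (p[k] <= 0) next
      if (xs[k] == 1L && x_first == 0L) fx[t] <<- fx[t] + prob * p[k]
      if (xs[k] == 1L && ys[k] == 1L && z_first == 0L)
        fz[t] <<- fz[t] + prob * p[k]
      rec(t + 1L,
          if (xs[k] == 1L) 1L else gx + 1L,
          if (ys[k] == 1L) 1L else gy + 1L,
          if (xs[k] == 1L && ys[k] == 1L) 1L else gz + 1L,
          prob * p[k],
          max(x_first, xs[k]), max(z_first, xs[k] * ys[k]))
    }
    invisible(NULL)
  }
  rec(1L, 1L, 1L, 1L, 1, 0L, 0L)
  list(fx = fx, fz = fz, total = total)
}

# Double counting guard for fx: contributions are only added while
# x_first == 0, and every branch where x activates sets x_first = 1, so each
# path contributes to fx at most once; same for fz.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small constructors used by many tests.
pl <- function(a, sm = 50L) iet_distribution("power_law", a, sm)
de <- function(a, sm = 50L) iet_distribution("discrete_exponential", a, sm)

trajectory_of <- function(states) {
  tr <- new_trajectory()
  for (s in states[-1]) tr <- traj_append(tr, s)
  tr
}
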