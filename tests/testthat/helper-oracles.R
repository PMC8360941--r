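# slow, independent reference implementations used as oracles

# triple-loop path enumeration: every (d', p') with all three hops present
brute_paths3 <- function(net, x, y) {
  count <- 0L
  for (dp in net$v2) {
    if (dp == y) next
    for (pp in net$v1) {
      if (pp == x) next
      if (net$B[x, dp] > 0 && net$B[pp, dp] > 0 && net$B[pp, y] > 0) {
        count <- count + 1L
      }
    }
  }
  count
}

# two-hop breadth-first reach
brute_second_neighbors <- function(net, v) {
  out <- character(0)
  for (z in neighbors(net, v)) out <- union(out, neighbors(net, z))
  sort(out)
}

# all-pairs comparison AUC
brute_auc <- function(sp, sn) {
  cmp <- outer(sp, sn, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
}

# random graph battery shared by the property tests
random_net_battery <- function(n = 10, seed = 42) {
  cfg <- expand.grid(n1 = c(4, 8, 15), n2 = c(3, 7, 12), p = c(0.15, 0.35))
  lapply(seq_len(min(n, nrow(cfg))), function(i) {
    random_bipartite(cfg$n1[i], cfg$n2[i], cfg$p[i], seed = seed + i)
  })
}

# tiny temporal cohort written by hand: 4 patients, 3 diseases
tiny_cohort <- function() {
  temporal_bipartite_network(data.frame(
    p = c("p1", "p1", "p2", "p2", "p2", "p3", "p3", "p4", "p4"),
    d = c("A", "B", "A", "B", "C", "A", "C", "B", "C"),
    t = c("2001-01-01", "2002-01-01",
          "2001-06-01", "2001-03-01", "2003-01-01",
          "2002-01-01", "2001-01-01",
          "2001-01-01", "2001-01-01"),
    stringsAsFactors = FALSE
  ))
}

options(biplink.quiet = TRUE)
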