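# build a GBI directly from a list of member-tag vectors
make_gbi <- function(member_list) {
  events <- do.call(rbind, lapply(seq_along(member_list), function(i) {
    data.frame(feeder = "F", start = i * 100, end = i * 100 + 10,
               n_members = length(member_list[[i]]),
               n_reads = length(member_list[[i]]),
               day = 1L, members = I(list(sort(member_list[[i]]))),
               stringsAsFactors = FALSE)
  }))
  events_to_gbi(events)
}

# independent brute-force SRI: loop over pairs and events
brute_sri <- function(gbi) {
  tags <- colnames(gbi)
  n <- length(tags)
  w <- matrix(0, n, n, dimnames = list(tags, tags))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    t_ab <- 0; d_ab <- 0
    for (e in seq_len(nrow(gbi))) {
      a <- gbi[e, i] == 1; b <- gbi[e, j] == 1
      if (a && b) t_ab <- t_ab + 1
      if (a || b) d_ab <- d_ab + 1
    }
    w[i, j] <- if (d_ab > 0) t_ab / d_ab else 0
  }
  w
}

# symmetric weight matrix from an edge list
toy_net <- function(nodes, edges) {
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) {
    w[e[[1]], e[[2]]] <- e[[3]]
    w[e[[2]], e[[1]]] <- e[[3]]
  }
  w
}

# a random GBI with guaranteed non-degenerate margins
random_gbi <- function(n_birds, n_events, p = 0.3) {
  tags <- sprintf("b%02d", seq_len(n_birds))
  m <- matrix(rbinom(n_events * n_birds, 1, p), n_events, n_birds,
              dimnames = list(sprintf("e%d", seq_len(n_events)), tags))
  # ensure every event nonempty
  empty <- rowSums(m) == 0
  m[empty, sample(n_birds, sum(empty), replace = TRUE)] <- 1
  m
}

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_sites = 1, birds_per_site = 12, days_pre = 2,
                   days_exp = 3, eligibility_min_reads = 20, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}
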