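two_clique_net <- function(n_per = 5) {
  nodes <- sprintf("n%02d", seq_len(2 * n_per))
  w <- matrix(0, 2 * n_per, 2 * n_per, dimnames = list(nodes, nodes))
  w[seq_len(n_per), seq_len(n_per)] <- 0.5
  w[n_per + seq_len(n_per), n_per + seq_len(n_per)] <- 0.8
  diag(w) <- 0
  list(net = w, labels = setNames(rep(c("low", "high"), each = n_per), nodes))
}

test_that("assortativity hits its analytic extremes", {
  tc <- two_clique_net()
  expect_equal(assortativity_discrete(tc$net, tc$labels), 1)

  # balanced complete bipartite, all edges between types
  nodes <- sprintf("n%d", 1:10)
  w <- matrix(0, 10, 10, dimnames = list(nodes, nodes))
  w[1:5, 6:10] <- 0.3
  w <- w + t(w)
  labs <- setNames(rep(c("low", "high"), each = 5), nodes)
  expect_equal(assortativity_discrete(w, labs), -1)
})

test_that("assortativity matches the hand-evaluated mixing matrix example", {
  w <- toy_net(letters[1:4],
               list(list("a", "b", 1), list("c", "d", 1), list("b", "c", 1)))
  labs <- c(a = "low", b = "low", c = "high", d = "high")
  expect_equal(assortativity_discrete(w, labs), 1 / 3)
})

test_that("single-label networks are flagged undefined, not silently NaN", {
  w <- toy_net(c("a", "b", "c"), list(list("a", "b", 1), list("b", "c", 1)))
  expect_warning(r <- assortativity_discrete(w, c(a = "x", b = "x", c = "x")),
                 "undefined")
  expect_true(is.na(r))
  w0 <- toy_net(c("a", "b"), list())
  expect_error(assortativity_discrete(w0, c(a = "x", b = "y")), "edge")
})

test_that("assortativity is invariant to uniform edge rescaling and bounded", {
  set.seed(41)
  for (rep in 1:10) {
    w <- sri_network(random_gbi(10, 25))
    labs <- setNames(sample(c("low", "high"), 10, replace = TRUE),
                     rownames(w))
    if (length(unique(labs)) < 2) next
    r <- suppressWarnings(assortativity_discrete(w, labs))
    if (is.na(r)) next
    expect_equal(assortativity_discrete(w * 3.7, labs), r)
    expect_gte(r, -1)
    expect_lte(r, 1)
  }
})

test_that("weighted assortativity equals igraph's discrete version on binary networks", {
  set.seed(42)
  for (rep in 1:15) {
    w <- (sri_network(random_gbi(10, 20)) > 0) * 1
    labs <- setNames(sample(c("low", "high"), 10, replace = TRUE),
                     rownames(w))
    if (length(unique(labs)) < 2 || sum(w) == 0) next
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
    r_ig <- igraph::assortativity_nominal(g, factor(labs))
    r_fl <- suppressWarnings(assortativity_discrete(w, labs))
    if (is.nan(r_ig) || is.na(r_fl)) next
    expect_equal(r_fl, r_ig, tolerance = 1e-12)
  }
})

test_that("edge jackknife SE matches enumeration and symmetry expectations", {
  # perfectly assorted: every leave-one-out r stays 1
  tc <- two_clique_net(4)
  expect_equal(jackknife_se(tc$net, tc$labels), 0)

  # hand-enumerated 3-edge example
  w <- toy_net(letters[1:4],
               list(list("a", "b", 1), list("c", "d", 1), list("b", "c", 1)))
  labs <- c(a = "low", b = "low", c = "high", d = "high")
  r_full <- 1 / 3
  r_minus <- c(
    assortativity_discrete(toy_net(letters[1:4],
      list(list("c", "d", 1), list("b", "c", 1))), labs),
    assortativity_discrete(toy_net(letters[1:4],
      list(list("a", "b", 1), list("b", "c", 1))), labs),
    assortativity_discrete(toy_net(letters[1:4],
      list(list("a", "b", 1), list("c", "d", 1))), labs))
  expect_equal(jackknife_se(w, labs), sqrt(sum((r_minus - r_full)^2)))

  # single edge -> undefined
  w1 <- toy_net(c("a", "b"), list(list("a", "b", 1)))
  expect_warning(se1 <- jackknife_se(w1, c(a = "x", b = "y")), "fewer")
  expect_true(is.na(se1))

  # node relabelling leaves se unchanged on a symmetric graph
  perm <- c("c", "d", "a", "b")
  w_p <- w[perm, perm]
  expect_equal(jackknife_se(w_p, labs[perm]), jackknife_se(w, labs))
})

test_that("the permutation null is centred at zero with calibrated p-values", {
  set.seed(43)
  gbi <- random_gbi(20, 60)
  net <- sri_network(gbi)
  labs <- setNames(rep(c("low", "high"), 10), rownames(net))
  res <- assortment_null(net, labs, n_perm = 1000, seed = 7)
  nulls <- attr(res, "null")
  sem <- sd(nulls) / sqrt(length(nulls))
  # the permutation expectation of Newman's r carries a finite-size offset
  # of order -1/(n-1) (exactly -1/(n-1) on a complete graph), so "centred
  # at zero" holds up to that offset
  expect_lt(abs(mean(nulls)), 1 / (nrow(net) - 1) + 3 * sem)
  expect_true(res$null_low <= res$null_high)
  expect_gt(res$p, 0)
  expect_lte(res$p, 1)

  # perfect assortment on a 20-node network is extreme under the null
  tc <- two_clique_net(10)
  res_tc <- assortment_null(tc$net, tc$labels, n_perm = 1000, seed = 8)
  expect_lte(res_tc$p, 0.01)

  expect_warning(assortment_null(net, labs, n_perm = 50, seed = 1), "small")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(44)
  gbi <- random_gbi(14, 40)
  net <- sri_network(gbi)
  ps <- vapply(1:200, function(r) {
    labs <- setNames(sample(rep(c("low", "high"), 7)), rownames(net))
    suppressWarnings(
      assortment_null(net, labs, n_perm = 99, seed = 1000 + r)$p)
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  rej <- mean(ps <= 0.05)
  expect_lt(rej, 0.12)
})

test_that("daily assortment applies the two-per-treatment exclusion", {
  make_daily <- function(tags, day) {
    gbi <- make_gbi(list(tags, tags[-1], tags[-length(tags)]))
    list(day = day, feeder = "F1", site = "S1",
         network = sri_network(gbi), gbi = gbi)
  }
  daily <- list(make_daily(c("a", "b", "c", "d"), 1L),
                make_daily(c("a", "b", "c", "d", "e"), 2L))
  labs <- c(a = "low", b = "low", c = "high", d = "high", e = "high")
  res <- daily_assortment(daily, labs, n_perm = 100, seed = 5)
  expect_identical(nrow(res), 2L)

  # one low bird only -> skipped
  labs1 <- c(a = "low", b = "high", c = "high", d = "high", e = "high")
  res1 <- daily_assortment(daily, labs1, n_perm = 100, seed = 5)
  expect_identical(nrow(res1), 0L)
  expect_identical(nrow(attr(res1, "skipped")), 2L)
  expect_identical(attr(res1, "skipped")$reason[1],
                   "fewer_than_two_per_treatment")

  # empty input -> empty result, no failure
  res_empty <- daily_assortment(list(), labs, n_perm = 100, seed = 5)
  expect_identical(nrow(res_empty), 0L)
})
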