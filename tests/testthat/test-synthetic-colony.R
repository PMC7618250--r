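test_that("sim_config validates its fields", {
  expect_s3_class(small_cfg(), "sim_config")
  expect_error(small_cfg(pair_fraction = 1.2), "pair_fraction")
  expect_error(small_cfg(flock_size_mean = 0), "flock_size_mean")
  expect_error(small_cfg(days_pre = 0), "days_pre")
  expect_error(sim_config(n_sites = 1), "seed")
})

test_that("population pairing follows the configured fraction", {
  pop0 <- simulate_population(small_cfg(pair_fraction = 0))
  expect_identical(nrow(pop0$pair_bonds), 0L)

  pop1 <- simulate_population(sim_config(n_sites = 1, birds_per_site = 10,
                                         pair_fraction = 1, seed = 3))
  expect_identical(nrow(pop1$pair_bonds), 5L)
})

test_that("preference matrix is symmetric with bonded pairs elevated", {
  pop <- simulate_population(small_cfg(pair_fraction = 0.5))
  w <- pop$preference
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
  bonded <- as.matrix(pop$pair_bonds)
  bonded_w <- w[bonded]
  baseline <- w[w > 0]
  baseline <- baseline[!(baseline %in% bonded_w)]
  expect_true(min(bonded_w) > max(baseline))
})

test_that("population and visit streams are deterministic given the seed", {
  a <- simulate_population(small_cfg())
  b <- simulate_population(small_cfg())
  expect_identical(a$preference, b$preference)

  s1 <- simulate_colony(small_cfg())
  s2 <- simulate_colony(small_cfg())
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$truth, s2$truth)
})

test_that("zero flock rate yields an empty stream", {
  cfg <- small_cfg(flock_rate = 0)
  pop <- simulate_population(cfg)
  feeders <- data.frame(site = "S1", feeder = c("S1_F1", "S1_F2"),
                        role = c("low", "high"))
  tr <- data.frame(tag = pop$birds$tag, site = "S1", treatment = "high")
  des <- experiment_design(feeders, tr, cfg$days_pre, cfg$days_exp)
  out <- simulate_visits(pop, cfg, des)
  expect_identical(nrow(out$visits), 0L)
  expect_identical(nrow(out$truth), 0L)
})

test_that("simulate_visits rejects a mismatched design", {
  cfg <- small_cfg()
  pop <- simulate_population(cfg)
  feeders <- data.frame(site = "OTHER", feeder = c("X1", "X2"),
                        role = c("low", "high"))
  tr <- data.frame(tag = "t1", site = "OTHER", treatment = "high")
  des <- experiment_design(feeders, tr, cfg$days_pre, cfg$days_exp)
  expect_error(simulate_visits(pop, cfg, des), "sites")
})

test_that("reads respect the daily window and event membership", {
  sim <- simulate_colony(small_cfg())
  tod <- sim$visits$time %% 86400
  expect_true(all(tod >= sim$config$day_start & tod <= sim$config$day_end))
  expect_true(all(sim$visits$day ==
                    floor(sim$visits$time / 86400) + 1))
  # every member emits >= 1 read
  expect_true(all(sim$truth$n_reads >= sim$truth$n_members))
  # members are site birds
  site_tags <- sim$population$birds$tag
  expect_true(all(unlist(strsplit(sim$truth$members, ";")) %in% site_tags))
})

test_that("full compliance gives the exact access-granted bipartite split", {
  sim <- simulate_colony(small_cfg(compliance = 1))
  d <- sim$visits[sim$visits$period == "during" & sim$visits$access == 1, ]
  roles <- setNames(sim$design$feeders$role, sim$design$feeders$feeder)
  treat <- setNames(sim$design$treatments$treatment, sim$design$treatments$tag)
  expect_true(all(
    (roles[d$feeder] == "low" & treat[d$tag] == "low") |
    (roles[d$feeder] == "high" & treat[d$tag] != "low")
  ))
})

test_that("partial compliance puts the expected share of low-bird reads at the assigned feeder", {
  # with every eligible bird low-assigned, availability at the two feeders
  # is symmetric, so the per-event Bernoulli(c) choice is the only thing
  # setting where reads land
  cfg <- sim_config(n_sites = 1, birds_per_site = 12, days_pre = 2,
                    days_exp = 20, eligibility_min_reads = 20,
                    compliance = 0.5, low_fraction = 1, seed = 9)
  sim <- simulate_colony(cfg)
  treat <- setNames(sim$design$treatments$treatment, sim$design$treatments$tag)
  roles <- setNames(sim$design$feeders$role, sim$design$feeders$feeder)
  d <- sim$visits[sim$visits$period == "during" &
                    treat[sim$visits$tag] == "low", ]
  prop_low <- mean(roles[d$feeder] == "low")
  # reads cluster within events, so allow a generous margin around 0.5
  expect_gt(prop_low, 0.42)
  expect_lt(prop_low, 0.58)
  expect_gt(nrow(d), 5000)
})

test_that("discovery trial generator respects its degenerate limits", {
  net <- toy_net(paste0("n", 1:6),
                 list(list("n1", "n2", 0.5), list("n2", "n3", 0.4)))
  cfg0 <- small_cfg(discovery_base = 0, social_effect = 0)
  arr <- simulate_discovery_trial(net, cfg0, trial_length = 3600)
  expect_true(all(is.na(arr)))
  expect_named(arr, paste0("n", 1:6))
  expect_error(simulate_discovery_trial(net, cfg0, trial_length = 0),
               "trial_length")
})

test_that("without social transmission, arrival latency is unrelated to strength", {
  set.seed(5)
  gbi <- random_gbi(20, 60)
  net <- sri_network(gbi)
  strength <- rowSums(net)
  cfg <- small_cfg(discovery_base = 0.003, social_effect = 0)
  cors <- vapply(1:200, function(r) {
    arr <- simulate_discovery_trial(net, cfg, trial_length = 86400, seed = r)
    suppressWarnings(cor(strength, arr, method = "spearman",
                         use = "complete.obs"))
  }, numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.05)
})

test_that("strong social transmission makes well-connected birds faster", {
  set.seed(6)
  gbi <- random_gbi(20, 60)
  net <- sri_network(gbi)
  strength <- rowSums(net)
  top <- strength >= quantile(strength, 0.75)
  bottom <- strength <= quantile(strength, 0.25)
  cfg <- small_cfg(discovery_base = 0.0005, social_effect = 50)
  diffs <- vapply(1:200, function(r) {
    arr <- simulate_discovery_trial(net, cfg, trial_length = 86400, seed = r)
    mean(arr[top], na.rm = TRUE) - mean(arr[bottom], na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(diffs, na.rm = TRUE), 0)
})
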