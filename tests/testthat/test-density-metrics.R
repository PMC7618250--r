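test_that("feeder roles follow the majority rule at a random half of sites", {
  pre <- data.frame(site = rep(sprintf("S%d", 1:6), each = 2),
                    feeder = sprintf("S%d_F%d", rep(1:6, each = 2), 1:2),
                    reads = rep(c(100, 900), 6))
  roles <- assign_feeder_roles(pre, sprintf("S%d", 1:6), seed = 2)
  # exactly half the sites have majority feeder -> high
  maj_high <- vapply(sprintf("S%d", 1:6), function(s) {
    r <- roles[roles$site == s, ]
    r$role[which.max(pre$reads[pre$site == s])] == "high"
  }, logical(1))
  expect_identical(sum(maj_high), 3L)
  # each experimental site has one low + one high
  for (s in sprintf("S%d", 1:6)) {
    expect_setequal(roles$role[roles$site == s], c("low", "high"))
  }
  # determinism
  expect_identical(roles, assign_feeder_roles(pre, sprintf("S%d", 1:6),
                                              seed = 2))
})

test_that("control sites keep control roles and ties are logged", {
  pre <- data.frame(site = rep(c("S1", "S2"), each = 2),
                    feeder = c("S1_F1", "S1_F2", "S2_F1", "S2_F2"),
                    reads = c(500, 500, 10, 20))
  expect_message(roles <- assign_feeder_roles(pre, "S1", seed = 1), "tie")
  expect_identical(roles$role[roles$site == "S2"], c("control", "control"))
  expect_setequal(roles$role[roles$site == "S1"], c("low", "high"))
})

test_that("treatment assignment samples the right number of eligible birds", {
  pre <- data.frame(tag = sprintf("b%02d", 1:25), site = "S1",
                    reads = c(rep(150, 20), rep(50, 5)))
  tr <- assign_bird_treatments(pre, min_records = 100, low_fraction = 0.2,
                               seed = 3)
  expect_identical(sum(tr$treatment == "low"), 4L)  # 20% of 20 eligible
  expect_identical(nrow(tr), 25L)
  # ineligible birds can never be assigned low
  low_tags <- tr$tag[tr$treatment == "low"]
  expect_true(all(pre$reads[match(low_tags, pre$tag)] >= 100))
  # determinism
  expect_identical(tr, assign_bird_treatments(pre, seed = 3))
})

test_that("a bird below the eligibility threshold is never sampled low", {
  pre <- data.frame(tag = c(sprintf("b%02d", 1:10), "shy"),
                    site = "S1", reads = c(rep(200, 10), 99))
  for (s in 1:25) {
    tr <- assign_bird_treatments(pre, seed = s)
    expect_identical(tr$treatment[tr$tag == "shy"], "high")
  }
  pre0 <- data.frame(tag = "b1", site = "S1", reads = 10)
  expect_error(assign_bird_treatments(pre0, seed = 1), "eligible")
})

test_that("failed-day filter drops one-silent and no-data site-days", {
  feeders <- data.frame(site = "S1", feeder = c("F1", "F2"),
                        role = c("low", "high"))
  tr <- data.frame(tag = "b1", site = "S1", treatment = "high")
  des <- experiment_design(feeders, tr, days_pre = 1, days_exp = 2)
  visits <- data.frame(
    time = c(100, 200, 86400 + 100), tag = "b1",
    feeder = c("F1", "F2", "F1"), site = "S1", access = 1L,
    day = c(1L, 1L, 2L), period = c("pre", "pre", "during"))
  out <- filter_failed_days(visits, des)
  expect_identical(sort(unique(out$visits$day)), 1L)   # day 2 one-silent
  expect_identical(nrow(out$excluded), 2L)             # day 2 + empty day 3
  expect_setequal(out$excluded$reason, c("one_feeder_silent", "no_data"))
  expect_equal(out$exclusion_fraction, 2 / 3)
})

test_that("planted feeder outages are recovered at the planted rate", {
  cfg <- sim_config(n_sites = 2, birds_per_site = 12, days_pre = 10,
                    days_exp = 15, eligibility_min_reads = 20,
                    failure_rate = 0.22, seed = 17)
  sim <- simulate_colony(cfg)
  out <- filter_failed_days(sim$visits, sim$design)
  # 2 sites x 25 days = 50 site-day draws; binomial error allows a wide band
  expect_gt(out$exclusion_fraction, 0.10)
  expect_lt(out$exclusion_fraction, 0.36)
})

test_that("site density series computes proportions, counts and flock sizes", {
  feeders <- data.frame(site = "S1", feeder = c("F1", "F2"),
                        role = c("low", "high"))
  tr <- data.frame(tag = c("b1", "b2"), site = "S1",
                   treatment = c("low", "high"))
  des <- experiment_design(feeders, tr, days_pre = 1, days_exp = 1)
  visits <- data.frame(
    time = c(seq(100, by = 10, length.out = 90),
             seq(120, by = 10, length.out = 10)),
    tag = c(rep("b1", 90), rep("b2", 10)),
    feeder = c(rep("F1", 90), rep("F2", 10)),
    site = "S1", access = 1L, day = 1L, period = "pre")
  events <- data.frame(feeder = "F1", start = 100, end = 990,
                       n_members = c(2L, 3L, 4L), n_reads = 30L, day = 1L,
                       members = I(list("b1", "b1", "b1")), site = "S1")
  s <- site_density_series(visits, events, des)
  expect_equal(s$prop_recordings[s$feeder == "F1"], 0.9)
  expect_equal(s$prop_recordings[s$feeder == "F2"], 0.1)
  expect_equal(sum(s$prop_recordings), 1)
  expect_identical(s$n_individuals[s$feeder == "F1"], 1L)
  expect_equal(s$mean_flock_size[s$feeder == "F1"], 3)
})

test_that("site-day proportions always sum to one over the two feeders", {
  sim <- simulate_colony(small_cfg())
  filt <- filter_failed_days(sim$visits, sim$design)
  ev <- detect_flocks(filt$visits, method = "window")
  s <- site_density_series(filt$visits, ev, sim$design)
  sums <- tapply(s$prop_recordings, interaction(s$site, s$day, drop = TRUE),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("individual series enforces the both-period read threshold", {
  feeders <- data.frame(site = "S1", feeder = c("F1", "F2"),
                        role = c("low", "high"))
  tr <- data.frame(tag = c("in", "out"), site = "S1",
                   treatment = c("low", "high"))
  des <- experiment_design(feeders, tr, days_pre = 1, days_exp = 1)
  mk <- function(tag, day, feeder, n) {
    data.frame(time = (day - 1) * 86400 + seq(100, by = 5, length.out = n),
               tag = tag, feeder = feeder, site = "S1", access = 1L,
               day = day)
  }
  visits <- rbind(mk("in", 1, "F1", 100), mk("in", 2, "F1", 80),
                  mk("in", 2, "F2", 20),
                  mk("out", 1, "F1", 100), mk("out", 2, "F2", 99))
  out <- individual_density_series(visits, flocknet:::empty_events(), des,
                                   min_records = 100)
  expect_identical(sort(unique(out$tag)), "in")  # "out" has 99 during reads
  during <- out[out$period == "during", ]
  expect_equal(during$prop_assigned, 0.8)        # 80 of 100 at assigned F1
})

test_that("full compliance gives assigned-feeder proportion 1 during the experiment", {
  cfg <- sim_config(n_sites = 1, birds_per_site = 12, days_pre = 3,
                    days_exp = 4, eligibility_min_reads = 20,
                    compliance = 1, seed = 19)
  sim <- simulate_colony(cfg)
  ev <- detect_flocks(sim$visits, method = "window")
  out <- individual_density_series(sim$visits, ev, sim$design,
                                   min_records = 20)
  during <- out[out$period == "during" & !is.na(out$prop_assigned), ]
  expect_gt(nrow(during), 0)
  expect_true(all(during$prop_assigned == 1))
})

test_that("bird in flocks of 3 and 5 has mean flock size 4", {
  feeders <- data.frame(site = "S1", feeder = c("F1", "F2"),
                        role = c("low", "high"))
  tr <- data.frame(tag = "b1", site = "S1", treatment = "high")
  des <- experiment_design(feeders, tr, days_pre = 1, days_exp = 1)
  visits <- data.frame(
    time = c(seq(1, by = 1, length.out = 100),
             86400 + seq(1, by = 1, length.out = 100)),
    tag = "b1", feeder = "F2", site = "S1", access = 1L,
    day = rep(1:2, each = 100))
  events <- data.frame(feeder = "F2", start = c(1, 50), end = c(40, 90),
                       n_members = c(3L, 5L), n_reads = 10L, day = 1L,
                       members = I(list(c("b1", "x", "y"),
                                        c("b1", "x", "y", "z", "u"))),
                       site = "S1")
  out <- individual_density_series(visits, events, des, min_records = 100)
  expect_equal(out$mean_flock_size[out$period == "pre"], 4)
})
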