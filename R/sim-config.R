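#' Simulation configuration for the synthetic colony
#'
#' Bundles and validates every knob of the stochastic colony simulator.
#' Defaults describe a winter feeder experiment: two selective feeders per
#' site recording passive-transponder reads 07:00-17:00, a two-week
#' pre-experimental period followed by a six-week density manipulation in
#' which 20% of the eligible birds (those with at least 100 pre-period
#' reads) are restricted to the low-density feeder.
#'
#' @param n_sites Number of sites, each with two feeders.
#' @param birds_per_site Birds resident at each site.
#' @param days_pre Length of the pre-experimental period in days.
#' @param days_exp Length of the experimental (manipulation) period in days.
#' @param day_start,day_end Daily recording window, seconds since midnight.
#' @param flock_rate Flocking-event arrivals per feeder-hour (Poisson rate).
#' @param flock_size_mean Target mean number of birds per flocking event
#'   when the whole site population is available.
#' @param pair_fraction Proportion of birds in bonded pairs; bonded pairs
#'   get elevated joint-membership odds.
#' @param preference_scale Positive scale applied to pairwise preference
#'   weights inside the logistic recruitment kernel.
#' @param reads_per_member Mean number of extra antenna reads a flock member
#'   emits beyond its first (Poisson mean).
#' @param read_jitter Standard deviation (s) of read times around the event
#'   centre.
#' @param low_fraction Proportion of eligible birds assigned to the
#'   low-density treatment.
#' @param eligibility_min_reads Minimum pre-period reads for a bird to be
#'   eligible for treatment assignment.
#' @param compliance Probability that a low-assigned bird's feeder choice
#'   follows its assignment during the experiment; otherwise it visits the
#'   high-density feeder and is recorded but denied access.
#' @param stray_prob Probability that a high-assigned bird visits the
#'   low-density feeder on a given event during the experiment (recorded,
#'   access denied).
#' @param failure_rate Probability that on a given site-day one of the two
#'   feeders fails to record (emulates SD-card/battery outages).
#' @param discovery_base Baseline per-minute discovery hazard in
#'   patch-discovery trials.
#' @param social_effect Nonnegative multiplier of the social transmission
#'   term in the discovery hazard; 0 switches social transmission off.
#' @param seed Integer master seed; all randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 1, birds_per_site = 12, days_pre = 2,
#'                   days_exp = 3, seed = 1)
sim_config <- function(n_sites = 2,
                       birds_per_site = 30,
                       days_pre = 14,
                       days_exp = 42,
                       day_start = 7 * 3600,
                       day_end = 17 * 3600,
                       flock_rate = 3,
                       flock_size_mean = 5,
                       pair_fraction = 0.4,
                       preference_scale = 4,
                       reads_per_member = 2,
                       read_jitter = 45,
                       low_fraction = 0.20,
                       eligibility_min_reads = 100,
                       compliance = 0.6,
                       stray_prob = 0.05,
                       failure_rate = 0,
                       discovery_base = 0.0027,
                       social_effect = 1,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("sim_config: 'seed' is required", call. = FALSE)
  }
  cfg <- list(
    n_sites = n_sites, birds_per_site = birds_per_site,
    days_pre = days_pre, days_exp = days_exp,
    day_start = day_start, day_end = day_end,
    flock_rate = flock_rate, flock_size_mean = flock_size_mean,
    pair_fraction = pair_fraction, preference_scale = preference_scale,
    reads_per_member = reads_per_member, read_jitter = read_jitter,
    low_fraction = low_fraction,
    eligibility_min_reads = eligibility_min_reads,
    compliance = compliance, stray_prob = stray_prob,
    failure_rate = failure_rate,
    discovery_base = discovery_base, social_effect = social_effect,
    seed = as.integer(seed)
  )

  chk_count <- function(x, nm, min = 1) {
    if (length(cfg[[x]]) != 1 || is.na(cfg[[x]]) || cfg[[x]] < min ||
        cfg[[x]] != round(cfg[[x]])) {
      stop(sprintf("sim_config: '%s' must be an integer >= %d", nm, min),
           call. = FALSE)
    }
  }
  chk_pos <- function(x) {
    if (length(cfg[[x]]) != 1 || is.na(cfg[[x]]) || cfg[[x]] <= 0) {
      stop(sprintf("sim_config: '%s' must be > 0", x), call. = FALSE)
    }
  }
  chk_prop <- function(x) {
    if (length(cfg[[x]]) != 1 || is.na(cfg[[x]]) || cfg[[x]] < 0 ||
        cfg[[x]] > 1) {
      stop(sprintf("sim_config: '%s' must be in [0, 1]", x), call. = FALSE)
    }
  }
  chk_count("n_sites", "n_sites")
  chk_count("birds_per_site", "birds_per_site", min = 2)
  chk_count("days_pre", "days_pre")
  chk_count("days_exp", "days_exp")
  for (f in c("flock_size_mean", "reads_per_member", "read_jitter",
              "preference_scale")) chk_pos(f)
  if (cfg$flock_rate < 0) stop("sim_config: 'flock_rate' must be >= 0",
                               call. = FALSE)
  if (cfg$discovery_base < 0) stop("sim_config: 'discovery_base' must be >= 0",
                                   call. = FALSE)
  if (cfg$social_effect < 0) stop("sim_config: 'social_effect' must be >= 0",
                                  call. = FALSE)
  for (f in c("pair_fraction", "low_fraction", "compliance", "stray_prob",
              "failure_rate")) chk_prop(f)
  if (!(cfg$day_start >= 0 && cfg$day_end <= 86400 &&
        cfg$day_start < cfg$day_end)) {
    stop("sim_config: day window must satisfy 0 <= day_start < day_end <= 86400",
         call. = FALSE)
  }
  chk_count("eligibility_min_reads", "eligibility_min_reads", min = 1)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d site(s) x %d birds, %d pre + %d experimental days\n",
              x$n_sites, x$birds_per_site, x$days_pre, x$days_exp))
  cat(sprintf("  flock rate %.2f/feeder-hour, mean size %.1f, compliance %.2f, seed %d\n",
              x$flock_rate, x$flock_size_mean, x$compliance, x$seed))
  invisible(x)
}

# Derive a reproducible 32-bit substream seed from the master seed and a
# small set of integer keys. Subsets (site, day, feeder) regenerate
# identically in isolation.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in keys) {
    h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}
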