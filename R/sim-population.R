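#' Simulate a colony of tagged birds with pairwise association preferences
#'
#' Creates the bird roster, bonded pairs, and a symmetric preference matrix
#' used by [simulate_visits()] to recruit flock members. Bonded pairs
#' (e.g. past or future breeding partners, which keep foraging together)
#' receive strictly higher preference weights than the non-bonded baseline.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `colony_population`: a list with
#'   `birds` (data.frame: `tag`, `site`), `pair_bonds` (data.frame:
#'   `tag_a`, `tag_b`), and `preference` (symmetric nonnegative matrix,
#'   zero diagonal, zero across sites).
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_sites = 1, birds_per_site = 10,
#'                                       pair_fraction = 1, seed = 7))
#' nrow(pop$pair_bonds)  # 5 bonded pairs
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 101L))

  sites <- sprintf("S%d", seq_len(config$n_sites))
  tags <- unlist(lapply(seq_along(sites), function(i) {
    sprintf("%s_B%02d", sites[i], seq_len(config$birds_per_site))
  }))
  birds <- data.frame(
    tag = tags,
    site = rep(sites, each = config$birds_per_site),
    stringsAsFactors = FALSE
  )

  n <- nrow(birds)
  w <- matrix(0, n, n, dimnames = list(tags, tags))

  bonds <- list()
  for (s in sites) {
    idx <- which(birds$site == s)
    # baseline within-site preferences, weak and symmetric
    base <- matrix(stats::runif(length(idx)^2, 0, 0.2),
                   length(idx), length(idx))
    base <- (base + t(base)) / 2
    diag(base) <- 0
    w[idx, idx] <- base

    n_pairs <- floor(config$pair_fraction * config$birds_per_site / 2)
    if (n_pairs > 0) {
      chosen <- sample(idx, 2 * n_pairs)
      for (p in seq_len(n_pairs)) {
        a <- chosen[2 * p - 1]
        b <- chosen[2 * p]
        wab <- stats::runif(1, 0.6, 1)  # strictly above the 0.2 baseline cap
        w[a, b] <- wab
        w[b, a] <- wab
        bonds[[length(bonds) + 1L]] <- c(tags[min(a, b)], tags[max(a, b)])
      }
    }
  }
  pair_bonds <- if (length(bonds)) {
    data.frame(tag_a = vapply(bonds, `[`, "", 1),
               tag_b = vapply(bonds, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tag_a = character(), tag_b = character(),
               stringsAsFactors = FALSE)
  }

  structure(list(birds = birds, pair_bonds = pair_bonds, preference = w),
            class = "colony_population")
}

#' @export
print.colony_population <- function(x, ...) {
  cat(sprintf("<colony_population> %d birds at %d site(s), %d bonded pair(s)\n",
              nrow(x$birds), length(unique(x$birds$site)), nrow(x$pair_bonds)))
  invisible(x)
}
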