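# Planted-cause recovery benchmark: simulate metacommunities with known
# causes and measure how often the pipeline recovers each cause class.

#' Planted-cause recovery benchmark
#'
#' For each seed, generates a landscape and a planted community
#' ([demo_community()] at benchmark scale), simulates occurrence, runs
#' the pair tests, and attributes the planted pairs. A planted pair
#' counts as detected when it is classified non-random and its site
#' groups are testable; among detected pairs, recovery means:
#' environment-planted pairs with at least one significant covariate,
#' dispersal-planted pairs with a significant coordinate MANOVA, and
#' interaction-planted pairs with final cause `interaction` (nothing else
#' significant). The attribution runs with per-pair Benjamini-Hochberg
#' adjustment across the nine covariate ANOVAs, the benchmark's fixed
#' setting (see the methods vignette).
#'
#' @param seeds Integer vector of replicate seeds.
#' @param n_sites Number of sites per replicate.
#' @param n_env_pairs,n_dispersal_pairs,n_interaction_pairs Planted pairs
#'   per cause.
#' @param n_background Unstructured species.
#' @param interaction_strength Planted conditional log-odds shift.
#' @param alpha Pair-test per-tail level.
#' @param alpha_attr Attribution level.
#' @param p_adjust Attribution adjustment (benchmark default `"BH"`).
#' @return Data.frame with one row per cause: planted, detected and
#'   recovered counts and rates across all seeds.
#' @export
recovery_benchmark <- function(seeds = 1:50, n_sites = 224,
                               n_env_pairs = 8, n_dispersal_pairs = 8,
                               n_interaction_pairs = 8, n_background = 12,
                               interaction_strength = 4,
                               alpha = 0.05, alpha_attr = 0.05,
                               p_adjust = "BH") {
  causes <- c("environment", "dispersal", "interaction")
  tot <- matrix(0L, 3, 3, dimnames = list(causes,
                c("planted", "detected", "recovered")))
  for (s in seeds) {
    sites <- generate_sites(n_sites, seed = s)
    com <- demo_community(
      sites, n_env_pairs = n_env_pairs,
      n_dispersal_pairs = n_dispersal_pairs,
      n_interaction_pairs = n_interaction_pairs,
      n_background = n_background,
      interaction_strength = interaction_strength, seed = s
    )
    sim <- simulate_occurrence(sites, com$species, com$interactions,
                               seed = s)
    occ <- occurrence_matrix(sim$presence)
    pairs <- test_all_pairs(occ, alpha = alpha)
    truth <- sim$truth$pairs
    pk <- paste(pmin(pairs$taxon_a, pairs$taxon_b),
                pmax(pairs$taxon_a, pairs$taxon_b))
    tk <- paste(pmin(truth$species_a, truth$species_b),
                pmax(truth$species_a, truth$species_b))
    planted <- pairs[match(tk, pk), , drop = FALSE]
    det <- planted$classification != "random" & planted$testable
    att <- suppressWarnings(
      attribute_pairs(planted[det, , drop = FALSE], occ, sites,
                      alpha_attr = alpha_attr, p_adjust = p_adjust)
    )
    ak <- paste(pmin(att$taxon_a, att$taxon_b),
                pmax(att$taxon_a, att$taxon_b))
    for (cz in causes) {
      rows <- which(truth$cause == cz)
      tot[cz, "planted"] <- tot[cz, "planted"] + length(rows)
      arows <- att[ak %in% tk[rows] & att$testable, , drop = FALSE]
      tot[cz, "detected"] <- tot[cz, "detected"] + nrow(arows)
      rec <- switch(cz,
        environment = sum(arows$n_explaining > 0),
        dispersal = sum(arows$dispersal),
        interaction = sum(arows$final_cause == "interaction")
      )
      tot[cz, "recovered"] <- tot[cz, "recovered"] + rec
    }
  }
  out <- data.frame(
    cause = causes,
    n_planted = tot[, "planted"],
    n_detected = tot[, "detected"],
    n_recovered = tot[, "recovered"],
    stringsAsFactors = FALSE
  )
  out$detection_rate <- out$n_detected / out$n_planted
  out$recovery_rate <- out$n_recovered / out$n_detected
  rownames(out) <- NULL
  out
}

#' Null false-positive rate of the pair classification
#'
#' Simulates unstructured species (independent Bernoulli occupancies at
#' `plogis(baseline_logit)`) and reports the fraction of testable pairs
#' classified non-random at the given per-tail level.
#'
#' @param n_species,n_sites Community size.
#' @param seed Integer seed.
#' @param alpha Per-tail significance level.
#' @param baseline_logit Occurrence log-odds (0 gives occupancy 1/2).
#' @return List with `fraction_nonrandom`, `n_pairs`.
#' @export
null_pair_rate <- function(n_species = 50, n_sites = 300, seed = 1,
                           alpha = 0.05, baseline_logit = 0) {
  sites <- generate_sites(n_sites, seed = seed)
  species <- species_spec(sprintf("sp%03d", seq_len(n_species)),
                          baseline_logit = baseline_logit)
  sim <- simulate_occurrence(sites, species, seed = seed)
  occ <- occurrence_matrix(sim$presence)
  pairs <- test_all_pairs(occ, alpha = alpha)
  ok <- pairs$testable
  list(
    fraction_nonrandom = mean(pairs$classification[ok] != "random"),
    n_pairs = sum(ok)
  )
}
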