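test_that("site groups implement the allotypic / both-vs-empty definitions", {
  pres <- rbind(
    A = c(1, 1, 1, 0, 0, 0),
    B = c(0, 0, 1, 1, 1, 0)
  )
  colnames(pres) <- paste0("s", 1:6)
  occ <- occurrence_matrix(pres)
  seg <- data.frame(taxon_a = "A", taxon_b = "B",
                    classification = "segregated")
  g <- suppressWarnings(site_groups(seg, occ))
  expect_setequal(g$group1, c("s1", "s2"))
  expect_setequal(g$group2, c("s4", "s5"))
  agg <- data.frame(taxon_a = "A", taxon_b = "B",
                    classification = "aggregated")
  pres2 <- rbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0))
  colnames(pres2) <- paste0("s", 1:4)
  g2 <- suppressWarnings(site_groups(agg, occurrence_matrix(pres2)))
  expect_setequal(g2$group1, c("s1", "s2"))
  expect_setequal(g2$group2, c("s3", "s4"))
  # degenerate group of size 1
  pres3 <- rbind(A = c(1, 0, 0, 0, 0), B = c(0, 1, 1, 1, 1))
  colnames(pres3) <- paste0("s", 1:5)
  expect_warning(g3 <- site_groups(seg, occurrence_matrix(pres3)),
                 "fewer than 2")
  expect_false(g3$testable)
  rnd <- data.frame(taxon_a = "A", taxon_b = "B",
                    classification = "random")
  expect_error(site_groups(rnd, occ), "random pairs")
})

test_that("one-way ANOVA matches hand-computed sums of squares and conventions", {
  res <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(res$F, 1.5, tolerance = 1e-12)   # SSB = 1.5, SSW/df = 1
  expect_equal(res$p, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  flat <- one_way_anova(rep(5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(flat$p, 1)
  sep <- one_way_anova(c(0, 0, 0, 0, 10, 10, 10, 10),
                       rep(c("g1", "g2"), each = 4))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), ">= 2")
})

test_that("two-group MANOVA (Pillai) equals Hotelling's T-squared", {
  x1 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  x2 <- rbind(c(1, 1), c(0, 0.9), c(1.1, 0))
  res <- one_way_manova(rbind(x1, x2), rep(c("a", "b"), each = 3))
  expect_gt(res$p, 0.05)
  expect_equal(res$p, hotelling_p(x1, x2), tolerance = 1e-10)
  set.seed(21)
  y1 <- cbind(rnorm(5, 0, 0.1), rnorm(5, 0, 0.1))
  y2 <- cbind(rnorm(5, 10, 0.1), rnorm(5, 10, 0.1))
  far <- one_way_manova(rbind(y1, y2), rep(c("a", "b"), each = 5))
  expect_lt(far$p, 1e-6)
  expect_equal(far$p, hotelling_p(y1, y2), tolerance = 1e-8)
  same <- one_way_manova(rbind(x1, x1), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("final causes follow the attribution definitions", {
  # 12 sites; A,B share the first six; pH separates the groups exactly
  pres <- rbind(A = rep(c(1, 0), each = 6), B = rep(c(1, 0), each = 6))
  colnames(pres) <- sprintf("s%02d", 1:12)
  occ <- occurrence_matrix(pres)
  sites <- noise_sites(12, seed = 2)
  sites$pH <- rep(c(0, 8), each = 6) + rnorm(12, 0, 0.01)
  pairs <- test_all_pairs(occ, alpha = 0.05)
  att <- attribute_pairs(pairs, occ, sites)
  expect_equal(nrow(att), 1)
  expect_equal(att$final_cause, "environment")
  expect_true(grepl("pH", att$explaining_env_vars))

  # spatial separation only -> dispersal
  sites2 <- noise_sites(12, seed = 3)
  sites2$x <- rep(c(0, 90), each = 6) + runif(12)
  sites2$y <- rep(c(0, 90), each = 6) + runif(12)
  att2 <- attribute_pairs(pairs, occ, sites2)
  expect_equal(att2$final_cause, "dispersal")
  expect_true(att2$dispersal)

  # nothing significant -> potential interaction
  sites3 <- noise_sites(12, seed = 4)
  att3 <- attribute_pairs(pairs, occ, sites3)
  if (att3$n_explaining == 0 && !att3$dispersal)
    expect_equal(att3$final_cause, "interaction")
})

test_that("attribution accounting is conserved on a synthetic run", {
  sites <- generate_sites(120, seed = 11)
  com <- demo_community(sites, n_env_pairs = 3, n_dispersal_pairs = 3,
                        n_interaction_pairs = 3, n_background = 6,
                        seed = 11)
  sim <- simulate_occurrence(sites, com$species, com$interactions, seed = 11)
  occ <- occurrence_matrix(sim$presence)
  pairs <- test_all_pairs(occ)
  att <- suppressWarnings(attribute_pairs(pairs, occ, sites))
  summ <- cause_summary(att, pairs)
  expect_equal(sum(summ$by_cause), summ$n_nonrandom)
  expect_equal(nrow(att), summ$n_nonrandom)
})

test_that("pure-noise environments explain pairs at about the test level", {
  sites <- noise_sites(200, seed = 31)
  pres <- matrix(rbinom(30 * 200, 1, 0.5), 30, 200,
                 dimnames = list(sprintf("t%02d", 1:30), sites$site_id))
  occ <- occurrence_matrix(pres)
  pairs <- test_all_pairs(occ)
  att <- suppressWarnings(attribute_pairs(pairs, occ, sites))
  ps <- unlist(att[paste0("p_", env_variables())])
  rate <- mean(ps < 0.05)
  n <- length(ps)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.02)
})

test_that("variable ranking is a deterministic greedy set cover", {
  # three pairs: pair1 by pH, pair2 by pH and DOC, pair3 by DOC
  vars <- env_variables()
  base <- as.data.frame(setNames(as.list(rep(0.9, length(vars))),
                                 paste0("p_", vars)))
  att <- cbind(
    data.frame(taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "d"),
               classification = "aggregated", stringsAsFactors = FALSE),
    rbind(base, base, base)
  )
  att$p_pH <- c(0.001, 0.001, 0.9)
  att$p_DOC <- c(0.9, 0.001, 0.001)
  att$p_manova <- 0.9
  att$dispersal <- FALSE
  att$n_explaining <- c(1, 2, 1)
  att$testable <- TRUE
  rk <- rank_variables(att, "cooccurrence", alpha_attr = 0.05)
  expect_equal(rk$variable[1], "DOC")  # ties broken by name
  expect_equal(rk$cumulative_prop[1:2], c(2 / 3, 1))
  expect_equal(rk$n_unique[rk$variable == "pH"], 1)
  expect_equal(sum(rk$n_new), 3)
  # single-variable cover
  att2 <- att
  att2$p_DOC <- 0.9
  att2$n_explaining <- c(1, 1, 0)
  rk2 <- rank_variables(att2, "cooccurrence", alpha_attr = 0.05)
  expect_equal(rk2$variable[1], "pH")
  expect_equal(rk2$cumulative_prop[1], rk2$cumulative_prop[9])
  expect_warning(rank_variables(att[0, ], "coexclusion"), "no testable")
})

test_that("the accounting identity combines printed-style inputs", {
  t <- unexplained_tally(c(7017, 2732), c(52143, 25675))
  expect_equal(t$n_unexplained, 9749)
  expect_equal(t$n_total, 77818)
  expect_equal(t$pct, 100 * 9749 / 77818)
})
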