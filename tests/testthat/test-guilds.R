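test_that("chi-square independence matches hand-derived values and conventions", {
  r <- chisq_independence(matrix(c(10, 20, 20, 10), 2))
  expect_equal(r$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_true(all(abs(r$contribution_pct - 25) < 1e-9))
  expect_true(all(r$expected == 15))
  # agreement with the standard implementation (no continuity correction)
  ref <- suppressWarnings(chisq.test(matrix(c(10, 20, 20, 10), 2),
                                     correct = FALSE))
  expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  flat <- chisq_independence(matrix(5, 2, 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  expect_true(all(flat$contribution_pct == 0))
  expect_warning(chisq_independence(rbind(c(3, 4), c(0, 0))), "zero row")
  expect_error(chisq_independence(matrix(0, 2, 2)), "grand total")
})

test_that("contribution percentages always sum to 100 when chi2 > 0", {
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(12, 20), 3, 4)
    r <- chisq_independence(tab)
    if (r$chi2 > 0)
      expect_lt(abs(sum(r$contribution_pct) - 100), 1e-9)
  }
})

test_that("PAM with silhouette selection finds planted clouds", {
  set.seed(7)
  two <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
               matrix(rnorm(20, 5, 0.05), 10, 2))
  res <- pam_cluster(two, k_max = 6)
  expect_equal(res$k, 2)
  expect_equal(length(unique(res$assignments[1:10])), 1)
  expect_gt(res$avg_silhouette, 0.8)
  expect_equal(res$avg_silhouette, silhouette_by_def(two, res$assignments),
               tolerance = 1e-10)
  # swap phase never worsens the build-phase objective
  expect_lte(res$objective[["swap"]], res$objective[["build"]])

  three <- rbind(matrix(rnorm(12, 0, 0.05), 6, 2),
                 matrix(rnorm(12, 5, 0.05), 6, 2),
                 cbind(rnorm(6, 0, 0.05), rnorm(6, 5, 0.05)))
  res3 <- pam_cluster(three, k_max = 5)
  expect_equal(res3$k, 3)
  expect_gt(res3$silhouette_by_k[["3"]], res3$silhouette_by_k[["2"]])

  same <- matrix(1, 5, 2)
  expect_warning(deg <- pam_cluster(same, k_max = 4), "identical")
  expect_equal(deg$k, 2L)
  expect_equal(deg$avg_silhouette, 0)
  expect_warning(pam_cluster(two[1:4, ], k_max = 10), "shrunk")
})

test_that("genus features aggregate pair causes into row-normalized proportions", {
  att <- data.frame(
    taxon_a = c("t1", "t1", "t2"), taxon_b = c("t2", "t3", "t3"),
    classification = "aggregated",
    final_cause = c("environment", "interaction", "environment"),
    stringsAsFactors = FALSE
  )
  taxo <- c(t1 = "Bacteria;P;C;O;F;GenusA;s",
            t2 = "Bacteria;P;C;O;F;GenusA;s",
            t3 = "Bacteria;P;C;O;F;GenusB;s")
  f <- genus_cause_features(att, taxo)
  expect_equal(unname(rowSums(f)), rep(1, nrow(f)))
  # GenusA appears in pairs 1 (env, twice), 2 (int), 3 (env)
  expect_equal(unname(f["GenusA", "environment"]), 3 / 4)
  expect_equal(unname(f["GenusB", "interaction"]), 1 / 2)
})

test_that("Wilcoxon contrasts use exact small-sample p-values", {
  net <- signed_network(data.frame(taxon_a = c("i1", "i2"),
                                   taxon_b = c("i2", "i3"),
                                   weight = c(1, -1)))
  taxa <- data.frame(
    taxon_id = c("i1", "i2", "i3", "o1", "o2", "o3"),
    occupancy = c(1, 2, 3, 4, 5, 6),
    mean_rel_abund = c(4, 5, 6, 1, 2, 3) / 21,
    stringsAsFactors = FALSE
  )
  ct <- interactor_contrast(net, taxa)
  occ_row <- ct[ct$variable == "occupancy", ]
  expect_equal(occ_row$p, 0.1, tolerance = 1e-12)  # 2/C(6,3)
  expect_equal(occ_row$mean_interacting, 2)
  expect_equal(occ_row$mean_noninteracting, 5)
  expect_equal(ct$p[ct$variable == "mean_rel_abund"], 0.1,
               tolerance = 1e-12)
  # empty group
  all_in <- taxa[1:3, ]
  expect_warning(ct2 <- interactor_contrast(net, all_in), "empty")
  expect_true(all(is.na(ct2$p)))
})

test_that("exact Wilcoxon p-values match full enumeration for small groups", {
  set.seed(13)
  for (i in 1:10) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- sample(1:100, nx); y <- sample(setdiff(1:100, x), ny)
    ref <- enum_wilcox_p(x, y)
    got <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("planted low-abundance/high-occupancy interactors reproduce both contrasts", {
  sites <- generate_sites(150, seed = 17)
  # interactors: common but rare in abundance; bystanders: scarcer but abundant
  ids_i <- sprintf("i%02d", 1:10)
  ids_o <- sprintf("o%02d", 1:10)
  sp <- rbind(
    species_spec(ids_i, baseline_logit = 1.5, mean_abundance = 0.2),
    species_spec(ids_o, baseline_logit = -0.5, mean_abundance = 5)
  )
  it <- interaction_spec(ids_i[seq(1, 9, 2)], ids_i[seq(2, 10, 2)],
                         sign = 1, strength = 3)
  sim <- simulate_occurrence(sites, sp, it, seed = 17)
  cnt <- simulate_counts(sim$presence, sp, c(5000, 8000), seed = 17)
  occ <- filter_and_binarize(cnt, 0.1)
  net <- signed_network(data.frame(taxon_a = it$species_a,
                                   taxon_b = it$species_b, weight = 1))
  ct <- interactor_contrast(net, occ$taxa)
  expect_gt(ct$mean_interacting[ct$variable == "occupancy"],
            ct$mean_noninteracting[ct$variable == "occupancy"])
  expect_lt(ct$mean_interacting[ct$variable == "mean_rel_abund"],
            ct$mean_noninteracting[ct$variable == "mean_rel_abund"])
})
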