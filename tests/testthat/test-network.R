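test_that("edge weights are the order-of-magnitude gap to the significance level", {
  att <- data.frame(
    taxon_a = c("a", "c"), taxon_b = c("b", "d"),
    classification = c("aggregated", "segregated"),
    final_cause = "interaction", stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    taxon_a = c("a", "c"), taxon_b = c("b", "d"),
    p_gt = c(1e-5, 0.5), p_lt = c(0.9999, 0.04),
    stringsAsFactors = FALSE
  )
  net <- build_network(att, pairs, alpha = 0.05)
  w <- setNames(net$edges$weight, paste(net$edges$taxon_a, net$edges$taxon_b))
  expect_equal(unname(w["a b"]), log10(0.05) - log10(1e-5),
               tolerance = 1e-10)            # 3.69897
  expect_equal(unname(w["c d"]), -(log10(0.05) - log10(0.04)),
               tolerance = 1e-10)            # -0.09691
  expect_equal(net$edges$edge_type, c("cooccurrence", "coexclusion"))
  # at the boundary p = alpha the pair is not significant: no such edge
  # can arise (final_cause = interaction requires p < alpha); zero
  # weights are rejected by the constructor
  expect_error(signed_network(data.frame(taxon_a = "x", taxon_b = "y",
                                         weight = 0)), "non-zero")
  expect_error(signed_network(data.frame(taxon_a = "x", taxon_b = "x",
                                         weight = 1)), "self-loops")
})

test_that("signed modularity scores the planted two-clique instance correctly", {
  net <- planted_clique_network()
  mem <- planted_clique_membership()
  expect_equal(signed_modularity(net, mem), 0.5, tolerance = 1e-12)
  # one module: positive term 0, negative term 0
  expect_equal(signed_modularity(net, setNames(rep(1, 12), names(mem))), 0)
  # igraph's neg implementation must report the same objective
  set.seed(1)
  g <- as_igraph(net)
  cl <- igraph::cluster_spinglass(g, weights = igraph::E(g)$weight,
                                  implementation = "neg")
  expect_equal(signed_modularity(net, igraph::membership(cl)),
               cl$modularity, tolerance = 1e-9)
})

test_that("every single-node move away from the planted split lowers Q", {
  net <- planted_clique_network()
  mem <- planted_clique_membership()
  q0 <- signed_modularity(net, mem)
  for (v in names(mem)) {
    moved <- mem
    moved[v] <- 3 - moved[v]
    expect_lt(signed_modularity(net, moved), q0)
  }
  # the planted split is the global optimum over all 2-partitions
  best <- -Inf
  for (code in 0:(2^11 - 1)) {
    m <- c(1L, as.integer(intToBits(code)[1:11]) + 1L)
    names(m) <- names(mem)
    q <- signed_modularity(net, m)
    if (q > best) best <- q
  }
  expect_equal(best, q0, tolerance = 1e-12)
})

test_that("spinglass recovers the planted modules across seeds", {
  skip_if_not_installed("mclust")
  net <- planted_clique_network()
  truth <- planted_clique_membership()
  for (s in 1:10) {
    part <- spinglass_partition(net, seed = s, n_restarts = 5)
    expect_equal(ari(part$membership[names(truth)], truth), 1,
                 label = paste("seed", s))
    expect_equal(part$Q, 0.5, tolerance = 1e-12)
  }
  # identical seeds give identical partitions
  expect_identical(spinglass_partition(net, seed = 3)$membership,
                   spinglass_partition(net, seed = 3)$membership)
})

test_that("an all-positive clique forms one module and sign flips dissolve the split", {
  ids <- sprintf("n%d", 1:6)
  el <- t(combn(ids, 2))
  net <- signed_network(data.frame(taxon_a = el[, 1], taxon_b = el[, 2],
                                   weight = 1))
  part <- spinglass_partition(net, seed = 1, n_restarts = 5)
  expect_equal(length(unique(part$membership)), 1)

  flipped <- planted_clique_network()
  flipped$edges$weight <- -flipped$edges$weight
  flipped <- signed_network(flipped$edges)
  mem <- planted_clique_membership()
  expect_equal(signed_modularity(flipped, mem), -0.5, tolerance = 1e-12)
  part_f <- spinglass_partition(flipped, seed = 1, n_restarts = 5)
  expect_false(isTRUE(all.equal(ari(part_f$membership[names(mem)], mem), 1)))
  expect_false(isTRUE(all.equal(part_f$Q, 0.5)))
})

test_that("module metrics match hand-enumerated toy graphs", {
  tri <- signed_network(data.frame(
    taxon_a = c("a", "a", "b"), taxon_b = c("b", "c", "c"), weight = 1))
  part <- list(membership = setNames(rep(1L, 3), c("a", "b", "c")))
  m <- module_metrics(tri, part)
  expect_equal(m$modules$clustering, 1)
  expect_equal(m$modules$diameter, 1)
  expect_equal(m$modules$avg_path_length, 1)

  path4 <- signed_network(data.frame(
    taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "d"), weight = 1))
  part4 <- list(membership = setNames(rep(1L, 4), letters[1:4]))
  m4 <- module_metrics(path4, part4)
  expect_equal(m4$modules$diameter, 3)
  expect_equal(m4$modules$avg_path_length, 5 / 3, tolerance = 1e-12)

  star <- signed_network(data.frame(
    taxon_a = "hub", taxon_b = paste0("leaf", 1:5), weight = 1))
  ps <- list(membership = setNames(rep(1L, 6),
                                   c("hub", paste0("leaf", 1:5))))
  ms <- module_metrics(star, ps)
  hubv <- setNames(ms$nodes$hub_value, ms$nodes$taxon_id)
  expect_equal(unname(hubv["hub"]), max(hubv))
  # weighted diameter uses |weight| distances
  wnet <- signed_network(data.frame(
    taxon_a = c("a", "b"), taxon_b = c("b", "c"), weight = c(2, -3)))
  wm <- module_metrics(wnet, list(membership = setNames(rep(1L, 3),
                                                        c("a", "b", "c"))))
  expect_equal(wm$modules$diameter, 5)
  expect_equal(wm$modules$avg_path_length, 4 / 3, tolerance = 1e-12)
})

test_that("weighted degree conserves edge weight and hubs ignore rescaling", {
  net <- planted_clique_network(w_pos = 1.7, w_neg = 0.6)
  g <- as_igraph(net)
  expect_equal(sum(igraph::strength(g, weights = igraph::E(g)$weight)),
               2 * sum(net$edges$weight), tolerance = 1e-12)
  part <- list(membership = planted_clique_membership())
  m1 <- module_metrics(net, part)
  scaled <- net
  scaled$edges$weight <- scaled$edges$weight * 10
  scaled <- signed_network(scaled$edges)
  m2 <- module_metrics(scaled, part)
  expect_equal(m1$nodes$hub_value, m2$nodes$hub_value, tolerance = 1e-8)
})

test_that("per-site module metrics follow their definitions", {
  net <- signed_network(data.frame(
    taxon_a = c("a", "a", "b"), taxon_b = c("b", "c", "c"),
    weight = c(1, 2, -1)))
  part <- list(membership = setNames(rep(1L, 3), c("a", "b", "c")))
  pres <- rbind(a = c(1, 1, 0), b = c(1, 0, 0), c = c(1, 0, 0))
  colnames(pres) <- paste0("s", 1:3)
  occ <- occurrence_matrix(pres)
  counts <- pres * c(10, 20, 30)
  sm <- per_site_module_metrics(net, part, occ, counts)
  s1 <- sm[sm$site_id == "s1", ]
  expect_equal(s1$richness, 3)
  expect_equal(s1$completeness, 1)
  expect_equal(s1$abundance, 1)
  g <- as_igraph(net)
  wdeg <- igraph::strength(g, weights = igraph::E(g)$weight)
  expect_equal(s1$total_node_weight, sum(wdeg))
  s2 <- sm[sm$site_id == "s2", ]
  expect_equal(s2$richness, 1)
  expect_equal(s2$total_node_weight, unname(wdeg["a"]))
  s3 <- sm[sm$site_id == "s3", ]
  expect_equal(s3$richness, 0)
  expect_equal(s3$abundance, 0)
})
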