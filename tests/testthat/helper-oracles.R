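# Independent oracles and small fixture builders used across the suite.

# Exhaustive null distribution of joint-presence counts: fix species A on
# sites 1..n_a and enumerate all C(N, n_b) placements of species B,
# counting overlaps. Integer counts -> exact rational probabilities.
enum_cooccurrence <- function(N, n_a, n_b) {
  if (n_b == 0) {
    counts <- 1
  } else {
    placements <- combn(N, n_b)
    overlaps <- colSums(placements <= n_a)
    counts <- tabulate(overlaps + 1, nbins = min(n_a, n_b) + 1)
  }
  lo <- max(0, n_a + n_b - N)
  hi <- min(n_a, n_b)
  counts <- counts[(lo:hi) + 1]
  counts / choose(N, n_b)
}

# occurrence_matrix from a list of per-taxon presence vectors
make_occ <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  occurrence_matrix(m)
}

# site table with pure-noise environment (no spatial structure), for
# null-behavior checks of the attribution stage
noise_sites <- function(n, seed) {
  set.seed(seed)
  out <- data.frame(site_id = sprintf("s%02d", seq_len(n)),
                    x = runif(n, 0, 100), y = runif(n, 0, 100),
                    stringsAsFactors = FALSE)
  for (v in env_variables()) out[[v]] <- rnorm(n)
  out
}

# two 6-cliques of positive unit edges joined by 4 negative unit edges;
# the planted split is nodes 1-6 vs 7-12
planted_clique_network <- function(w_pos = 1, w_neg = 1) {
  cl <- function(ids) t(combn(ids, 2))
  pos <- rbind(cl(sprintf("a%d", 1:6)), cl(sprintf("b%d", 1:6)))
  neg <- cbind(sprintf("a%d", 1:4), sprintf("b%d", 1:4))
  edges <- data.frame(
    taxon_a = c(pos[, 1], neg[, 1]),
    taxon_b = c(pos[, 2], neg[, 2]),
    weight = c(rep(w_pos, nrow(pos)), rep(-w_neg, nrow(neg))),
    stringsAsFactors = FALSE
  )
  signed_network(edges)
}

planted_clique_membership <- function() {
  setNames(rep(1:2, each = 6), c(sprintf("a%d", 1:6), sprintf("b%d", 1:6)))
}

# Hotelling two-sample T^2 p-value; with two groups Pillai's MANOVA F
# approximation must agree with this exactly
hotelling_p <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x1)
  d <- colMeans(x1) - colMeans(x2)
  S <- ((n1 - 1) * cov(x1) + (n2 - 1) * cov(x2)) / (n1 + n2 - 2)
  t2 <- (n1 * n2) / (n1 + n2) * drop(t(d) %*% solve(S) %*% d)
  f <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * t2
  pf(f, p, n1 + n2 - p - 1, lower.tail = FALSE)
}

# exact two-sided rank-sum p by full enumeration of group assignments
# (distinct values assumed)
enum_wilcox_p <- function(x, y) {
  all <- c(x, y)
  n <- length(all); m <- length(x)
  r_obs <- sum(rank(all)[seq_len(m)])
  sums <- combn(n, m, function(idx) sum(rank(all)[idx]))
  p_le <- mean(sums <= r_obs)
  p_ge <- mean(sums >= r_obs)
  min(1, 2 * min(p_le, p_ge))
}

# average silhouette width computed from its definition
silhouette_by_def <- function(x, cl) {
  d <- as.matrix(dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- which(cl == cl[i])
    a <- if (length(own) > 1) mean(d[i, setdiff(own, i)]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(d[i, cl == k]), numeric(1)))
    if (length(own) > 1) (b - a) / max(a, b) else 0
  }, numeric(1))
  mean(s)
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
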