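# Downstream guild statistics: chi-square independence with Pearson
# residual contributions, PAM k-medoids clustering with silhouette-chosen
# k, and occupancy/abundance contrasts between interacting and
# non-interacting taxa.

#' Chi-square test of independence with residual contributions
#'
#' Classic r x c chi-square without continuity correction. Rows or
#' columns with zero totals are dropped with a warning. Each cell's
#' contribution is `100 * residual^2 / chi2` (all zero when chi2 = 0);
#' contributions sum to 100.
#'
#' @param table Non-negative count matrix.
#' @return A `contingency_result`: list with `observed`, `expected`,
#'   `chi2`, `df`, `p`, `pearson_residuals`, `contribution_pct`.
#' @examples
#' r <- chisq_independence(matrix(c(10, 20, 20, 10), 2))
#' r$chi2  # 20/3
#' @export
chisq_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(tab) == 0) stop("grand total must be positive", call. = FALSE)
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s)")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  resid <- (tab - expected) / sqrt(expected)
  chi2 <- sum(resid^2)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  contribution <- if (chi2 > 0) 100 * resid^2 / chi2 else resid * 0
  structure(
    list(observed = tab, expected = expected, chi2 = chi2, df = df, p = p,
         pearson_residuals = resid, contribution_pct = contribution),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("chi-square independence: chi2 =", signif(x$chi2, 5), "df =", x$df,
      "p =", signif(x$p, 4), "\n")
  invisible(x)
}

#' PAM k-medoids clustering with silhouette-chosen k
#'
#' Runs [cluster::pam()] (build + swap) for k = 2..`k_max` and keeps the
#' k with the best average silhouette width. Deterministic given the
#' feature matrix. A degenerate input where all rows coincide returns
#' k = 2 with silhouette 0 and a warning.
#'
#' @param features Numeric matrix (e.g. genus x explanatory-category
#'   proportions; rows summing to 1).
#' @param k_max Largest k to consider (shrunk with a warning when there
#'   are too few rows).
#' @param metric Dissimilarity, `"euclidean"` (default) or
#'   `"manhattan"`.
#' @return A `cluster_result`: list with `k`, `medoids`, `assignments`,
#'   `avg_silhouette`, `silhouette_by_k`, `objective`.
#' @export
pam_cluster <- function(features, k_max = 10, metric = "euclidean") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3) stop("need at least 3 rows to cluster", call. = FALSE)
  if (k_max > n - 1) {
    warning("k_max shrunk to ", n - 1, " (need k < n)")
    k_max <- n - 1
  }
  if (max(dist(features)) == 0) {
    warning("all points identical; returning degenerate k = 2 clustering")
    fit <- cluster::pam(features, 2, metric = metric)
    return(structure(
      list(k = 2L, medoids = fit$id.med, assignments = fit$clustering,
           avg_silhouette = 0, silhouette_by_k = c(`2` = 0),
           objective = fit$objective),
      class = "cluster_result"
    ))
  }
  ks <- 2:k_max
  fits <- lapply(ks, function(k) cluster::pam(features, k, metric = metric))
  sil <- vapply(fits, function(f) f$silinfo$avg.width, numeric(1))
  best <- which.max(sil)
  fit <- fits[[best]]
  structure(
    list(k = ks[best], medoids = fit$id.med, assignments = fit$clustering,
         avg_silhouette = sil[best],
         silhouette_by_k = setNames(sil, ks),
         objective = fit$objective),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("PAM clustering: k =", x$k, "average silhouette =",
      round(x$avg_silhouette, 3), "\n")
  invisible(x)
}

#' Per-genus explanatory-category proportions for clustering
#'
#' Builds the feature matrix consumed by [pam_cluster()]: for each genus
#' (extracted from a taxonomy string at the given rank), the proportion
#' of its pairs explained by each cause category. A pair contributes to
#' both members' genera.
#'
#' @param attributions A `pair_attribution` table.
#' @param taxonomy Named character vector taxon_id -> taxonomy string
#'   (semicolon-separated ranks).
#' @param rank 1-based rank index of the genus field (default 6).
#' @param min_pairs Genera with fewer pairs are dropped.
#' @return Matrix genus x cause proportions (rows sum to 1).
#' @export
genus_cause_features <- function(attributions, taxonomy, rank = 6,
                                 min_pairs = 1) {
  genus_of <- function(id) {
    parts <- strsplit(taxonomy[[id]], ";")[[1]]
    if (length(parts) >= rank) trimws(parts[rank]) else NA_character_
  }
  causes <- c("environment", "environment+dispersal", "dispersal",
              "interaction")
  sub <- attributions[attributions$final_cause %in% causes, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sub))) {
    for (id in c(sub$taxon_a[i], sub$taxon_b[i])) {
      gn <- genus_of(id)
      if (is.na(gn)) next
      rows[[length(rows) + 1L]] <- c(genus = gn, cause = sub$final_cause[i])
    }
  }
  if (!length(rows)) stop("no genus-resolvable pairs", call. = FALSE)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  tab <- table(df$genus, factor(df$cause, levels = causes))
  tab <- tab[rowSums(tab) >= min_pairs, , drop = FALSE]
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  prop
}

#' Occupancy and abundance contrast of interacting vs non-interacting taxa
#'
#' Compares the taxa that entered the potential-interaction network
#' against the remaining filtered taxa on occupancy and mean relative
#' abundance, with two-sided Wilcoxon rank-sum tests (exact when the
#' combined group size is at most 25, normal approximation with tie
#' correction otherwise).
#'
#' @param net A [signed_network()].
#' @param taxa Annotation data.frame (`taxon_id`, `occupancy`,
#'   `mean_rel_abund`) covering all filtered taxa, e.g. `occ$taxa`.
#' @return Data.frame with one row per variable: group means, group
#'   sizes and Wilcoxon p-value.
#' @export
interactor_contrast <- function(net, taxa) {
  stopifnot(inherits(net, "signed_network"))
  inter <- taxa$taxon_id %in% net$nodes$taxon_id
  if (!any(inter) || all(inter)) {
    warning("one contrast group is empty")
    return(data.frame(variable = c("occupancy", "mean_rel_abund"),
                      mean_interacting = NA_real_,
                      mean_noninteracting = NA_real_,
                      n_interacting = sum(inter),
                      n_noninteracting = sum(!inter),
                      p = NA_real_))
  }
  one <- function(v) {
    x <- taxa[[v]][inter]
    y <- taxa[[v]][!inter]
    exact <- (length(x) + length(y)) <= 25
    p <- if (identical(sort(x), sort(y)) && length(x) == length(y)) 1 else
      suppressWarnings(wilcox.test(x, y, exact = exact)$p.value)
    data.frame(variable = v, mean_interacting = mean(x),
               mean_noninteracting = mean(y),
               n_interacting = length(x), n_noninteracting = length(y),
               p = p, stringsAsFactors = FALSE)
  }
  out <- rbind(one("occupancy"), one("mean_rel_abund"))
  rownames(out) <- NULL
  out
}
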