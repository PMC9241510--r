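# Attribution of non-random pairs to environment, dispersal or potential
# biotic interaction. For a segregated pair
# the comparison groups are the allotypic sites (only A vs only B); for
# an aggregated pair, sites with both species vs sites with neither.
# Each environmental covariate is tested with a one-way ANOVA over the
# two groups and the site coordinates with a one-way MANOVA (Pillai);
# pairs with no significant test are the potential biotic interactions.

#' Comparison site groups for a non-random pair
#'
#' @param pair One row of a `pair_tests` table (non-random).
#' @param occ The [occurrence_matrix()] the pair was tested on.
#' @return List with `mode` ("segregated"/"aggregated"), `group1`,
#'   `group2` (site-id vectors), and `testable` (both groups of size >= 2).
#' @export
site_groups <- function(pair, occ) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  if (pair$classification == "random")
    stop("random pairs do not enter attribution", call. = FALSE)
  A <- occ$presence[pair$taxon_a, ] == 1L
  B <- occ$presence[pair$taxon_b, ] == 1L
  sites <- colnames(occ$presence)
  if (pair$classification == "segregated") {
    g1 <- sites[A & !B]
    g2 <- sites[B & !A]
  } else {
    g1 <- sites[A & B]
    g2 <- sites[!A & !B]
  }
  testable <- length(g1) >= 2 && length(g2) >= 2
  if (!testable)
    warning("pair ", pair$taxon_a, "/", pair$taxon_b,
            ": a comparison group has fewer than 2 sites")
  list(mode = pair$classification, group1 = g1, group2 = g2,
       testable = testable)
}

#' Two-group one-way ANOVA with degenerate-input conventions
#'
#' Classic equal-variance one-way F test with df (1, n - 2). When the
#' within-group variance is zero in both groups: p = 1 if the means are
#' equal, otherwise F = Inf and p = 0 (perfect separation limit).
#'
#' @param values Numeric response.
#' @param groups Two-level grouping (each level >= 2 members).
#' @return List with `F` and `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) < 2))
    stop("need two groups with >= 2 members each", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  m <- tapply(values, groups, mean)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ssw == 0) {
    if (isTRUE(all.equal(m[[1]], m[[2]]))) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  ht <- oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value))
}

#' Two-group one-way MANOVA of site coordinates
#'
#' Pillai's trace with its standard F approximation; with two groups this
#' is equivalent to Hotelling's T-squared. Identical group centroids give
#' statistic 0 and p = 1; a singular model (e.g. coincident points) is
#' reported as not testable.
#'
#' @param coords Two-column numeric matrix of points.
#' @param groups Two-level grouping (each level >= 3 members).
#' @return List with `statistic` (Pillai), `F`, `p`, and `ok`.
#' @export
one_way_manova <- function(coords, groups) {
  coords <- as.matrix(coords)
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) < 3))
    stop("need two groups with >= 3 members each", call. = FALSE)
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  mu <- apply(coords, 2, function(v) tapply(v, groups, mean))
  if (isTRUE(all.equal(mu[1, ], mu[2, ])))
    return(list(statistic = 0, F = 0, p = 1, ok = TRUE))
  res <- tryCatch({
    fit <- manova(coords ~ groups)
    s <- summary(fit, test = "Pillai")$stats
    list(statistic = unname(s[1, "Pillai"]), F = unname(s[1, "approx F"]),
         p = unname(s[1, "Pr(>F)"]), ok = TRUE)
  }, error = function(e) {
    warning("MANOVA failed (singular input): ", conditionMessage(e))
    list(statistic = NA_real_, F = NA_real_, p = NA_real_, ok = FALSE)
  })
  res
}

#' Attribute non-random pairs to environment, dispersal or interaction
#'
#' For every non-random, testable pair: nine one-way ANOVAs (one per
#' environmental covariate) and one MANOVA of the coordinates over the
#' pair's site groups. Covariates with p below `alpha_attr` form the
#' explaining set; a significant MANOVA sets the dispersal flag. The
#' final cause is `environment`, `dispersal`, `environment+dispersal`, or
#' `interaction` when nothing is significant. Pairs whose groups are too
#' small for all tests (fewer than 3 sites in either group) are reported
#' as `untestable`, never merged into the interaction class.
#'
#' @param pairs A `pair_tests` table (only non-random testable rows are
#'   attributed; others are ignored).
#' @param occ The [occurrence_matrix()].
#' @param sites Site table with coordinates and the covariates of
#'   [env_variables()].
#' @param alpha_attr Significance level of the attribution tests.
#' @param p_adjust `"none"` (default) or `"BH"`: Benjamini-Hochberg
#'   adjustment of the nine covariate p-values within each pair.
#' @return A `pair_attribution` data.frame with per-covariate p-values
#'   (`p_<var>`), `p_manova`, `explaining_env_vars` (comma-separated),
#'   `dispersal`, `final_cause` and `testable`.
#' @export
attribute_pairs <- function(pairs, occ, sites, alpha_attr = 0.05,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(occ, "occurrence_matrix"))
  vars <- env_variables()
  if (!all(vars %in% names(sites)))
    stop("site table lacks environmental covariates: ",
         paste(setdiff(vars, names(sites)), collapse = ", "), call. = FALSE)
  if (anyNA(sites[vars]))
    stop("environmental covariates must be complete", call. = FALSE)
  rownames(sites) <- sites$site_id
  todo <- pairs[pairs$classification != "random" & pairs$testable, ,
                drop = FALSE]
  rows <- vector("list", nrow(todo))
  for (i in seq_len(nrow(todo))) {
    pr <- todo[i, ]
    g <- suppressWarnings(site_groups(pr, occ))
    full <- length(g$group1) >= 3 && length(g$group2) >= 3
    p_env <- setNames(rep(NA_real_, length(vars)), vars)
    p_man <- NA_real_
    if (full) {
      ids <- c(g$group1, g$group2)
      grp <- factor(rep(c("g1", "g2"), c(length(g$group1), length(g$group2))))
      for (v in vars)
        p_env[v] <- one_way_anova(sites[ids, v], grp)$p
      man <- one_way_manova(as.matrix(sites[ids, c("x", "y")]), grp)
      p_man <- man$p
      if (!man$ok) full <- FALSE
    }
    q_env <- if (p_adjust == "BH") p.adjust(p_env, "BH") else p_env
    explaining <- if (full) vars[q_env < alpha_attr] else character()
    dispersal <- isTRUE(full && !is.na(p_man) && p_man < alpha_attr)
    cause <- if (!full) "untestable"
      else if (length(explaining) && dispersal) "environment+dispersal"
      else if (length(explaining)) "environment"
      else if (dispersal) "dispersal"
      else "interaction"
    rows[[i]] <- data.frame(
      taxon_a = pr$taxon_a, taxon_b = pr$taxon_b,
      classification = pr$classification,
      n_group1 = length(g$group1), n_group2 = length(g$group2),
      as.list(setNames(p_env, paste0("p_", vars))),
      p_manova = p_man,
      explaining_env_vars = paste(explaining, collapse = ","),
      n_explaining = length(explaining),
      dispersal = dispersal,
      final_cause = cause,
      testable = full,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon_a = character(), taxon_b = character(),
               classification = character(), final_cause = character(),
               stringsAsFactors = FALSE)
  attr(out, "alpha_attr") <- alpha_attr
  attr(out, "p_adjust") <- p_adjust
  class(out) <- c("pair_attribution", "data.frame")
  out
}

#' Tally attribution causes by edge type
#'
#' Counts non-random pairs by final cause and by edge type (aggregated
#' pairs are co-occurrences, segregated pairs co-exclusions), together
#' with the accounting identity total.
#'
#' @param attributions A `pair_attribution` table.
#' @param pairs The `pair_tests` table it came from.
#' @return List with `by_cause` (cause x edge-type count table),
#'   `n_nonrandom`, `n_unexplained` and `pct_unexplained` (percentage of
#'   all significant pairs left as potential interactions).
#' @export
cause_summary <- function(attributions, pairs) {
  cnt <- pair_counts(pairs)
  causes <- c("environment", "environment+dispersal", "dispersal",
              "interaction", "untestable")
  types <- c(aggregated = "cooccurrence", segregated = "coexclusion")
  tab <- table(factor(attributions$final_cause, levels = causes),
               factor(unname(types[attributions$classification]),
                      levels = unname(types)))
  n_nonrandom <- unname(cnt["aggregated"] + cnt["segregated"])
  n_unexplained <- sum(attributions$final_cause == "interaction")
  list(
    by_cause = tab,
    n_nonrandom = n_nonrandom,
    n_unexplained = n_unexplained,
    pct_unexplained = if (n_nonrandom > 0) 100 * n_unexplained / n_nonrandom
                      else NA_real_
  )
}

#' Accounting identity for unexplained pairs
#'
#' Combines per-edge-type unexplained counts and significant-pair totals
#' into the overall number of potential biotic interactions and its
#' percentage of all significant pairs.
#'
#' @param unexplained Numeric vector of unexplained-pair counts (e.g. one
#'   entry per edge type).
#' @param totals Numeric vector of significant-pair totals.
#' @return List with `n_unexplained`, `n_total` and `pct` (percentage).
#' @export
unexplained_tally <- function(unexplained, totals) {
  n_un <- sum(unexplained)
  n_tot <- sum(totals)
  list(n_unexplained = n_un, n_total = n_tot, pct = 100 * n_un / n_tot)
}

#' Rank environmental variables by uniquely explained links
#'
#' Greedy set cover over the pairs of one edge type: repeatedly pick the
#' covariate explaining the most pairs not covered by previously picked
#' covariates (ties broken by covariate name), and report the cumulative
#' proportion of links covered, alongside each covariate's total and
#' unique (explained-by-it-alone) proportions and the dispersal-only
#' proportion.
#'
#' @param attributions A `pair_attribution` table.
#' @param edge_type `"cooccurrence"` (aggregated pairs) or
#'   `"coexclusion"` (segregated pairs).
#' @param alpha_attr Significance level (defaults to the one stored on
#'   `attributions`).
#' @return A `data.frame` ranked greedily with columns `variable`,
#'   `n_total`, `prop_total`, `n_unique`, `prop_unique`, `n_new`,
#'   `cumulative_prop`; the dispersal-only proportion is attached as
#'   attribute `dispersal_only_prop`.
#' @export
rank_variables <- function(attributions,
                           edge_type = c("cooccurrence", "coexclusion"),
                           alpha_attr = NULL) {
  edge_type <- match.arg(edge_type)
  if (is.null(alpha_attr))
    alpha_attr <- attr(attributions, "alpha_attr") %||% 0.05
  cls <- if (edge_type == "cooccurrence") "aggregated" else "segregated"
  sub <- attributions[attributions$classification == cls &
                        attributions$testable, , drop = FALSE]
  vars <- env_variables()
  if (nrow(sub) == 0) {
    warning("no testable ", edge_type, " pairs to rank")
    return(data.frame(variable = character(), n_total = integer(),
                      prop_total = numeric(), n_unique = integer(),
                      prop_unique = numeric(), n_new = integer(),
                      cumulative_prop = numeric()))
  }
  n_pairs <- nrow(sub)
  expl <- lapply(vars, function(v) which(sub[[paste0("p_", v)]] < alpha_attr))
  names(expl) <- vars
  n_explaining <- rowSums(
    vapply(vars, function(v) sub[[paste0("p_", v)]] < alpha_attr,
           logical(n_pairs))
  )
  disp_only <- sum(sub$dispersal & n_explaining == 0)
  covered <- integer(0)
  order_out <- character(0)
  n_new <- integer(0)
  remaining <- vars
  while (length(remaining)) {
    gain <- vapply(remaining,
                   function(v) length(setdiff(expl[[v]], covered)), integer(1))
    pick <- remaining[order(-gain, remaining)][1]
    covered <- union(covered, expl[[pick]])
    order_out <- c(order_out, pick)
    n_new <- c(n_new, gain[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  out <- data.frame(
    variable = order_out,
    n_total = vapply(order_out, function(v) length(expl[[v]]), integer(1)),
    n_unique = vapply(order_out, function(v)
      sum(n_explaining[expl[[v]]] == 1), integer(1)),
    n_new = n_new,
    stringsAsFactors = FALSE
  )
  out$prop_total <- out$n_total / n_pairs
  out$prop_unique <- out$n_unique / n_pairs
  out$cumulative_prop <- cumsum(out$n_new) / n_pairs
  out <- out[, c("variable", "n_total", "prop_total", "n_unique",
                 "prop_unique", "n_new", "cumulative_prop")]
  rownames(out) <- NULL
  attr(out, "dispersal_only_prop") <- disp_only / n_pairs
  attr(out, "n_pairs") <- n_pairs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
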