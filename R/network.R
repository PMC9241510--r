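# Signed potential-interaction network: nodes are taxa, edges are the
# interaction-class pairs, weighted by the order-of-magnitude difference
# between the pair's tail probability and the significance level,
#   weight = sign * (log10(alpha) - log10(p)),
# positive for co-occurrences (upper tail) and negative for
# co-exclusions (lower tail); weights vanish at the significance
# boundary and grow with evidence.

#' Construct a signed network object
#'
#' @param edges Data.frame with columns `taxon_a`, `taxon_b`, `weight`
#'   (signed, non-zero), and optionally `p`, `edge_type`.
#' @param nodes Optional node annotation data.frame with a `taxon_id`
#'   column (defaults to the taxa appearing in `edges`).
#' @param alpha Significance level recorded for provenance.
#' @return A `signed_network`: list with `nodes`, `edges`, `alpha`.
#' @export
signed_network <- function(edges, nodes = NULL, alpha = 0.05) {
  stopifnot(all(c("taxon_a", "taxon_b", "weight") %in% names(edges)))
  if (any(edges$taxon_a == edges$taxon_b))
    stop("self-loops are not allowed", call. = FALSE)
  if (any(edges$weight == 0))
    stop("edge weights must be non-zero", call. = FALSE)
  key <- paste(pmin(edges$taxon_a, edges$taxon_b),
               pmax(edges$taxon_a, edges$taxon_b))
  if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
  if (!"edge_type" %in% names(edges))
    edges$edge_type <- ifelse(edges$weight > 0, "cooccurrence", "coexclusion")
  ids <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  if (is.null(nodes)) {
    nodes <- data.frame(taxon_id = ids, stringsAsFactors = FALSE)
  } else {
    stopifnot("taxon_id" %in% names(nodes))
    missing <- setdiff(ids, nodes$taxon_id)
    if (length(missing))
      stop("edges reference unannotated nodes: ",
           paste(missing, collapse = ", "), call. = FALSE)
    nodes <- nodes[nodes$taxon_id %in% ids, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("signed network:", nrow(x$nodes), "nodes,",
      sum(x$edges$weight > 0), "positive /", sum(x$edges$weight < 0),
      "negative edges\n")
  invisible(x)
}

#' Convert a signed network to an igraph graph
#'
#' @param net A [signed_network()].
#' @return An undirected [igraph::igraph] with edge attributes `weight`,
#'   `p`, `edge_type` and node annotations.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = net$nodes
  )
}

#' Build the signed network of potential-interaction pairs
#'
#' Takes the attribution table, keeps pairs with `final_cause ==
#' "interaction"`, and weights each edge by
#' `sign * (log10(alpha) - log10(p))` with `p = p_gt` for aggregated
#' pairs (positive sign) and `p = p_lt` for segregated pairs (negative
#' sign). Underflowed p-values are clamped at the smallest positive
#' double with a warning.
#'
#' @param attributions A `pair_attribution` table.
#' @param pairs The `pair_tests` table carrying the tail probabilities.
#' @param alpha Significance level used in the pair tests.
#' @param nodes Optional node annotation data.frame (`taxon_id`, ...),
#'   e.g. `occ$taxa`.
#' @return A [signed_network()].
#' @export
build_network <- function(attributions, pairs, alpha = 0.05, nodes = NULL) {
  keep <- attributions[attributions$final_cause == "interaction", ,
                       drop = FALSE]
  if (nrow(keep) == 0) {
    return(signed_network(
      data.frame(taxon_a = character(), taxon_b = character(),
                 weight = numeric(), p = numeric(),
                 edge_type = character(), stringsAsFactors = FALSE),
      nodes = NULL, alpha = alpha
    ))
  }
  pk <- paste(pairs$taxon_a, pairs$taxon_b)
  idx <- match(paste(keep$taxon_a, keep$taxon_b), pk)
  stopifnot(!anyNA(idx))
  agg <- keep$classification == "aggregated"
  p <- ifelse(agg, pairs$p_gt[idx], pairs$p_lt[idx])
  if (any(p <= 0)) {
    warning("p-value underflow; clamped at .Machine$double.xmin")
    p <- pmax(p, .Machine$double.xmin)
  }
  w <- ifelse(agg, 1, -1) * (log10(alpha) - log10(p))
  edges <- data.frame(
    taxon_a = keep$taxon_a, taxon_b = keep$taxon_b,
    weight = w, p = p,
    edge_type = ifelse(agg, "cooccurrence", "coexclusion"),
    stringsAsFactors = FALSE
  )
  signed_network(edges, nodes = nodes, alpha = alpha)
}

#' Signed modularity of a partition
#'
#' Quality function for networks with positive and negative edges
#' (Gomez-Jensen-Arenas form): the classic modularity of the positive
#' subgraph minus that of the negative subgraph, combined with weights
#' proportional to the total positive and negative strength. Positive
#' edges inside modules and negative edges between modules increase Q.
#'
#' @param net A [signed_network()] or igraph graph with a `weight` edge
#'   attribute.
#' @param membership Module assignment, named by node or in vertex order.
#' @param gamma_pos,gamma_neg Resolution parameters of the positive and
#'   negative terms.
#' @return The signed modularity Q.
#' @export
signed_modularity <- function(net, membership, gamma_pos = 1, gamma_neg = 1) {
  g <- if (inherits(net, "signed_network")) as_igraph(net) else net
  nm <- igraph::V(g)$name
  if (!is.null(names(membership)) && !is.null(nm))
    membership <- membership[nm]
  membership <- as.integer(factor(membership))
  w <- igraph::E(g)$weight
  el <- igraph::as_edgelist(g, names = FALSE)
  same <- membership[el[, 1]] == membership[el[, 2]]
  part <- function(wpart, gamma) {
    tot <- sum(wpart)
    if (tot == 0) return(0)
    k <- igraph::strength(g, weights = wpart)
    kc <- tapply(k, membership, sum)
    sum(wpart[same]) / tot - gamma * sum((kc / (2 * tot))^2)
  }
  wp <- pmax(w, 0)
  wn <- pmax(-w, 0)
  qp <- part(wp, gamma_pos)
  qn <- part(wn, gamma_neg)
  twp <- sum(wp); twn <- sum(wn)
  if (twp + twn == 0) return(0)
  (twp * qp - twn * qn) / (twp + twn)
}

#' Partition a signed network with the spinglass algorithm
#'
#' Runs [igraph::cluster_spinglass()] with the negative-edge
#' implementation (absolute weights as coupling strengths, sign giving
#' the ferro/antiferromagnetic direction) independently on each connected
#' component, with multiple seeded annealing restarts, keeping the
#' membership with the best [signed_modularity()]. Isolated nodes form
#' singleton modules.
#'
#' @param net A [signed_network()].
#' @param seed Integer seed (reproducible).
#' @param gamma_pos,gamma_neg Resolution parameters.
#' @param n_restarts Annealing restarts per component.
#' @param spins Maximum number of spins (upper bound on modules per
#'   component).
#' @return A `module_partition`: list with `membership` (named integer),
#'   `Q`, `seed`.
#' @export
spinglass_partition <- function(net, seed = 1, gamma_pos = 1, gamma_neg = 1,
                                n_restarts = 25, spins = 25) {
  stopifnot(inherits(net, "signed_network"))
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  membership <- setNames(rep(NA_integer_, n), igraph::V(g)$name)
  if (n == 0)
    return(structure(list(membership = membership, Q = NA_real_, seed = seed),
                     class = "module_partition"))
  set.seed(seed)
  comp <- igraph::components(g)
  next_id <- 0L
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vids)
    if (igraph::vcount(sub) == 1L || igraph::ecount(sub) == 0L) {
      membership[igraph::V(sub)$name] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    best <- NULL
    best_q <- -Inf
    for (r in seq_len(n_restarts)) {
      cl <- tryCatch(
        igraph::cluster_spinglass(
          sub, weights = igraph::E(sub)$weight,
          spins = min(spins, igraph::vcount(sub)),
          implementation = "neg",
          gamma = gamma_pos, gamma.minus = gamma_neg
        ),
        error = function(e) NULL
      )
      if (is.null(cl)) next
      mem <- igraph::membership(cl)
      q <- signed_modularity(sub, mem, gamma_pos, gamma_neg)
      if (q > best_q) {
        best_q <- q
        best <- mem
      }
    }
    if (is.null(best))
      best <- setNames(rep(1L, igraph::vcount(sub)), igraph::V(sub)$name)
    membership[names(best)] <- next_id + as.integer(factor(best))
    next_id <- next_id + length(unique(best))
  }
  Q <- signed_modularity(g, membership, gamma_pos, gamma_neg)
  structure(list(membership = membership, Q = Q, seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module partition:", length(unique(x$membership)), "modules, Q =",
      round(x$Q, 4), "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Structural metrics of network modules and nodes
#'
#' Per module (induced subgraph): node count, diameter on the
#' absolute-weight distances, average shortest-path length in hops
#' (unweighted), clustering coefficient (mean local transitivity,
#' degree-<2 nodes excluded), and the mean and SD of member hub values.
#' Per node: weighted degree (sum of signed incident weights) and hub
#' value (principal-eigenvector hub score on absolute weights, computed
#' on the full network, max-normalized). Node pairs disconnected within
#' a module are excluded from the path statistics and counted.
#'
#' @param net A [signed_network()].
#' @param part A `module_partition` from [spinglass_partition()].
#' @param weighted_diameter Use `|weight|` as distances for the diameter
#'   (default) or hop counts.
#' @param weighted_path_length Use `|weight|` distances for the average
#'   path length (default hops).
#' @return A `network_metrics`: list with `modules` and `nodes`
#'   data.frames.
#' @export
module_metrics <- function(net, part, weighted_diameter = TRUE,
                           weighted_path_length = FALSE) {
  stopifnot(inherits(net, "signed_network"))
  g <- as_igraph(net)
  mem <- part$membership[igraph::V(g)$name]
  hub <- if (igraph::ecount(g) > 0)
    igraph::hits_scores(g, weights = abs(igraph::E(g)$weight))$hub
  else setNames(rep(NA_real_, igraph::vcount(g)), igraph::V(g)$name)
  wdeg <- igraph::strength(g, weights = igraph::E(g)$weight)
  nodes <- data.frame(
    taxon_id = igraph::V(g)$name,
    module = unname(mem),
    weighted_degree = unname(wdeg),
    hub_value = unname(hub),
    stringsAsFactors = FALSE
  )
  mods <- sort(unique(mem))
  rows <- lapply(mods, function(m) {
    vids <- which(mem == m)
    sub <- igraph::induced_subgraph(g, vids)
    nv <- igraph::vcount(sub)
    if (nv == 0)
      return(data.frame(module = m, n_nodes = 0, diameter = NA_real_,
                        clustering = NA_real_, avg_path_length = NA_real_,
                        mean_hub = NA_real_, sd_hub = NA_real_,
                        n_unreachable_pairs = NA_integer_))
    aw <- abs(igraph::E(sub)$weight)
    diam <- if (igraph::ecount(sub) == 0) NA_real_ else
      igraph::diameter(sub, weights = if (weighted_diameter) aw else NA,
                       unconnected = TRUE)
    apl <- if (igraph::ecount(sub) == 0) NA_real_ else
      igraph::mean_distance(sub,
                            weights = if (weighted_path_length) aw else NA,
                            unconnected = TRUE)
    loc <- suppressWarnings(igraph::transitivity(sub, type = "local"))
    clus <- if (all(is.nan(loc))) NA_real_ else mean(loc, na.rm = TRUE)
    dmat <- igraph::distances(sub, weights = NA)
    unreach <- sum(is.infinite(dmat[upper.tri(dmat)]))
    data.frame(
      module = m, n_nodes = nv, diameter = diam, clustering = clus,
      avg_path_length = apl,
      mean_hub = mean(hub[vids]), sd_hub = if (nv > 1) sd(hub[vids]) else 0,
      n_unreachable_pairs = unreach
    )
  })
  modules <- do.call(rbind, rows)
  tot_unreach <- sum(modules$n_unreachable_pairs, na.rm = TRUE)
  if (tot_unreach > 0)
    message(tot_unreach,
            " within-module node pair(s) unconnected; excluded from path statistics")
  structure(list(modules = modules, nodes = nodes),
            class = "network_metrics")
}

#' Per-site module composition metrics
#'
#' For every site and module: richness (module nodes present at the
#' site), completeness (richness over module size), abundance (summed
#' relative abundance of the present module nodes, from `counts`), and
#' total node weight (summed weighted degree of the present nodes).
#'
#' @param net A [signed_network()].
#' @param part A `module_partition`.
#' @param occ An [occurrence_matrix()] resolving the node ids.
#' @param counts Optional count matrix for the abundance component.
#' @return Long data.frame: `site_id`, `module`, `richness`,
#'   `completeness`, `abundance`, `total_node_weight`.
#' @export
per_site_module_metrics <- function(net, part, occ, counts = NULL) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  nodes <- intersect(names(part$membership), rownames(occ$presence))
  if (length(nodes) == 0)
    stop("no network node resolvable in the occurrence matrix", call. = FALSE)
  g <- as_igraph(net)
  wdeg <- igraph::strength(g, weights = igraph::E(g)$weight)
  rel <- if (!is.null(counts)) {
    cs <- pmax(colSums(counts), 1)
    sweep(counts, 2, cs, "/")
  } else NULL
  mem <- part$membership[nodes]
  mods <- sort(unique(mem))
  sites <- colnames(occ$presence)
  out <- expand.grid(site_id = sites, module = mods,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$richness <- 0L
  out$completeness <- 0
  out$abundance <- 0
  out$total_node_weight <- 0
  for (k in seq_len(nrow(out))) {
    mnodes <- nodes[mem == out$module[k]]
    pres <- occ$presence[mnodes, out$site_id[k]] == 1L
    here <- mnodes[pres]
    out$richness[k] <- length(here)
    out$completeness[k] <- length(here) / length(mnodes)
    if (!is.null(rel) && length(here))
      out$abundance[k] <- sum(rel[here, out$site_id[k]])
    if (length(here))
      out$total_node_weight[k] <- sum(wdeg[here])
  }
  out
}
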