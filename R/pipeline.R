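# End-to-end pipeline: preprocess -> pair tests -> attribution ->
# variable ranking -> signed network -> spinglass modules -> metrics ->
# guild statistics, driven by a single config with one root seed, and
# writing every artifact plus a JSON manifest.

#' Default pipeline configuration (synthetic demo)
#'
#' @param out_dir Output directory.
#' @param seed Root seed; all stage seeds are derived from it.
#' @param n_sites Number of synthetic sites.
#' @param ... Overrides for any top-level config entry.
#' @return Config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("guildnet_run_"), seed = 1,
                        n_sites = 224, ...) {
  cfg <- list(
    mode = "synthetic",
    seed = seed,
    out_dir = out_dir,
    synthetic = list(
      n_sites = n_sites,
      n_env_pairs = 25, n_dispersal_pairs = 15, n_interaction_pairs = 20,
      n_background = 30, interaction_strength = 4,
      depth_range = c(6000, 15000)
    ),
    rarefy_depth = 5000,
    min_occurrence_fraction = 0.10,
    alpha = 0.05,
    alpha_attr = 0.05,
    min_expected = 1,
    p_adjust_pairs = "none",
    p_adjust_attr = "none",
    gamma_pos = 1, gamma_neg = 1,
    n_restarts = 25, spins = 25,
    weighted_diameter = TRUE,
    weighted_path_length = FALSE
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

.validate_config <- function(cfg) {
  need01 <- c("alpha", "alpha_attr", "min_occurrence_fraction")
  for (nm in need01) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      stop("config: ", nm, " must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(cfg$rarefy_depth) || cfg$rarefy_depth < 1)
    stop("config: rarefy_depth must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config: seed must be a single integer", call. = FALSE)
  if (!cfg$mode %in% c("synthetic", "files"))
    stop("config: mode must be 'synthetic' or 'files'", call. = FALSE)
  if (cfg$mode == "files") {
    for (nm in c("counts_file", "sites_file"))
      if (is.null(cfg[[nm]]) || !file.exists(cfg[[nm]]))
        stop("config: ", nm, " missing or not found", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a taxa-by-site count table
#'
#' Tab-separated with taxon ids in the first column and site ids in the
#' header.
#'
#' @param path File path.
#' @return Integer matrix.
#' @export
read_count_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  m
}

#' Read a site metadata table
#'
#' Tab-separated with columns `site_id`, `x`, `y` and the covariates of
#' [env_variables()].
#'
#' @param path File path.
#' @return Site data.frame.
#' @export
read_site_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("site_id", "x", "y", env_variables())
  if (!all(need %in% names(df)))
    stop("site table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}

.write_tsv <- function(x, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    x <- data.frame(setNames(list(rownames(x)), rownames_col),
                    as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes every stage from a config list (or YAML/JSON file path):
#' input simulation or loading, rarefaction, occupancy filtering, pair
#' tests, attribution, variable ranking, signed-network construction,
#' spinglass partitioning, module/node and per-site metrics, and the
#' interactor contrast. All randomness is funneled through derived
#' stage seeds so a rerun with the same config is bit-identical. Every
#' artifact is written to `out_dir` as a tab-separated table (plus
#' GraphML for the network) and indexed with md5 checksums in
#' `manifest.json`.
#'
#' @param config Config list (see [demo_config()]) or path to a
#'   YAML/JSON config file.
#' @return The manifest, invisibly as an R list.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- .validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- new.env(parent = emptyenv())
  art$files <- character(0)
  emit <- function(...) art$files <- c(art$files, ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[guildnet] %-12s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  seed_of <- function(k) (as.integer(cfg$seed) * 101L + k) %% 2147483647L

  inputs <- stage("inputs", {
    if (cfg$mode == "synthetic") {
      sy <- cfg$synthetic
      sites <- generate_sites(sy$n_sites, seed = seed_of(1L))
      com <- demo_community(
        sites, n_env_pairs = sy$n_env_pairs,
        n_dispersal_pairs = sy$n_dispersal_pairs,
        n_interaction_pairs = sy$n_interaction_pairs,
        n_background = sy$n_background,
        interaction_strength = sy$interaction_strength,
        seed = seed_of(2L)
      )
      sim <- simulate_occurrence(sites, com$species, com$interactions,
                                 seed = seed_of(3L))
      counts <- simulate_counts(sim$presence, com$species,
                                depth_range = sy$depth_range,
                                seed = seed_of(4L))
      emit(
        .write_tsv(sites, file.path(cfg$out_dir, "sites.tsv")),
        .write_tsv(counts, file.path(cfg$out_dir, "counts.tsv"), "taxon_id"),
        .write_tsv(com$species,
                   file.path(cfg$out_dir, "species_spec.tsv")),
        .write_tsv(sim$truth$pairs,
                   file.path(cfg$out_dir, "truth_pairs.tsv")))
      list(sites = sites, counts = counts, truth = sim$truth)
    } else {
      list(sites = read_site_table(cfg$sites_file),
           counts = read_count_table(cfg$counts_file), truth = NULL)
    }
  })

  occ <- stage("preprocess", {
    rar <- rarefy(inputs$counts, depth = cfg$rarefy_depth,
                  seed = seed_of(5L))
    occ <- filter_and_binarize(rar, cfg$min_occurrence_fraction)
    emit(
      .write_tsv(occ$presence, file.path(cfg$out_dir, "occurrence.tsv"),
                 "taxon_id"),
      .write_tsv(occ$taxa, file.path(cfg$out_dir, "taxa.tsv")))
    occ
  })
  # the site table must match the retained (rarefaction-surviving) sites
  inputs$sites <- inputs$sites[
    match(colnames(occ$presence), inputs$sites$site_id), , drop = FALSE]

  pairs <- stage("pairs", {
    p <- test_all_pairs(occ, alpha = cfg$alpha,
                        min_expected = cfg$min_expected,
                        p_adjust = cfg$p_adjust_pairs)
    emit(
      .write_tsv(p, file.path(cfg$out_dir, "pair_tests.tsv")))
    p
  })

  attributions <- stage("attribute", {
    a <- suppressWarnings(
      attribute_pairs(pairs, occ, inputs$sites,
                      alpha_attr = cfg$alpha_attr,
                      p_adjust = cfg$p_adjust_attr))
    emit(
      .write_tsv(a, file.path(cfg$out_dir, "attributions.tsv")))
    a
  })

  ranking <- stage("rank", {
    rk <- lapply(c("cooccurrence", "coexclusion"), function(et) {
      r <- suppressWarnings(rank_variables(attributions, et))
      emit(.write_tsv(
        r, file.path(cfg$out_dir, paste0("ranking_", et, ".tsv"))))
      r
    })
    names(rk) <- c("cooccurrence", "coexclusion")
    rk
  })

  net <- stage("network", {
    nt <- build_network(attributions, pairs, alpha = cfg$alpha,
                        nodes = occ$taxa)
    emit(
      .write_tsv(nt$edges, file.path(cfg$out_dir, "edges.tsv")))
    if (nrow(nt$edges) > 0) {
      gml <- file.path(cfg$out_dir, "network.graphml")
      igraph::write_graph(as_igraph(nt), gml, format = "graphml")
      emit(gml)
    }
    nt
  })

  part <- stage("partition", {
    if (nrow(net$edges) == 0) NULL else {
      pt <- spinglass_partition(net, seed = seed_of(6L),
                                gamma_pos = cfg$gamma_pos,
                                gamma_neg = cfg$gamma_neg,
                                n_restarts = cfg$n_restarts,
                                spins = cfg$spins)
      emit(.write_tsv(
        data.frame(taxon_id = names(pt$membership),
                   module = unname(pt$membership)),
        file.path(cfg$out_dir, "modules.tsv")))
      pt
    }
  })

  metrics <- stage("metrics", {
    if (is.null(part)) NULL else {
      m <- suppressMessages(module_metrics(
        net, part, weighted_diameter = cfg$weighted_diameter,
        weighted_path_length = cfg$weighted_path_length))
      sm <- per_site_module_metrics(net, part, occ, inputs$counts)
      emit(
        .write_tsv(m$modules, file.path(cfg$out_dir, "module_metrics.tsv")),
        .write_tsv(m$nodes, file.path(cfg$out_dir, "node_metrics.tsv")),
        .write_tsv(sm, file.path(cfg$out_dir, "site_module_metrics.tsv")))
      m
    }
  })

  stats <- stage("stats", {
    ct <- suppressWarnings(interactor_contrast(net, occ$taxa))
    emit(
      .write_tsv(ct, file.path(cfg$out_dir, "interactor_contrast.tsv")))
    ct
  })

  summ <- cause_summary(attributions, pairs)
  manifest <- list(
    package = "guildnet",
    version = as.character(packageVersion("guildnet")),
    config = cfg,
    n_sites = ncol(occ$presence),
    n_taxa = nrow(occ$presence),
    pair_counts = as.list(pair_counts(pairs)),
    cause_counts = as.list(setNames(
      as.integer(rowSums(summ$by_cause)), rownames(summ$by_cause))),
    n_nonrandom = summ$n_nonrandom,
    n_unexplained = summ$n_unexplained,
    pct_unexplained = summ$pct_unexplained,
    modularity_Q = if (is.null(part)) NA else part$Q,
    n_modules = if (is.null(part)) 0L
                else length(unique(part$membership)),
    dispersal_only_prop = lapply(ranking, attr, "dispersal_only_prop"),
    files = as.list(tools::md5sum(sort(art$files)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
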