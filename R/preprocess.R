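# Preprocessing: rarefaction to a common depth and occupancy filtering of
# the count table into the presence/absence matrix the pair tests consume.

#' Rarefy a count table to a common sequencing depth
#'
#' Randomly subsamples each site (column) to exactly `depth` reads without
#' replacement (via [vegan::rrarefy()]). Sites whose total is below the
#' depth are dropped with a warning.
#'
#' @param counts Integer taxa x site matrix.
#' @param depth Target depth per site (>= 1).
#' @param seed Integer seed.
#' @return Integer matrix with every retained column summing to `depth`.
#' @export
rarefy <- function(counts, depth = 5000, seed = 1) {
  if (!is.numeric(depth) || depth < 1)
    stop("depth must be >= 1", call. = FALSE)
  depth <- as.integer(depth)
  tot <- colSums(counts)
  shallow <- tot < depth
  if (all(shallow))
    stop("all sites are below the rarefaction depth", call. = FALSE)
  if (any(shallow))
    warning(sum(shallow), " site(s) below depth ", depth, " dropped: ",
            paste(colnames(counts)[shallow], collapse = ", "))
  kept <- counts[, !shallow, drop = FALSE]
  set.seed(seed)
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(kept), depth)),
    # vegan flags data whose smallest nonzero count exceeds 1 as
    # "probably not counts"; simulated multinomial counts trip this
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(kept)
  out
}

#' Occurrence-filter and binarize a count table
#'
#' Converts counts to presence/absence and removes taxa observed at fewer
#' than `ceiling(min_occurrence_fraction * n_sites)` sites (a taxon exactly
#' at the threshold is retained). Each retained taxon is annotated with
#' its occupancy and its mean relative abundance, computed on the
#' proportions of the supplied (pre-binarization) counts.
#'
#' @param counts Integer taxa x site matrix.
#' @param min_occurrence_fraction Occupancy threshold as a fraction of
#'   sites, in (0, 1).
#' @return An `occurrence_matrix`: list with `presence` (binary matrix),
#'   `taxa` (data.frame `taxon_id`, `occupancy`, `mean_rel_abund`),
#'   `n_sites` and `threshold`.
#' @examples
#' counts <- matrix(rpois(60, 3), 6, 10,
#'                  dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
#' occ <- filter_and_binarize(counts, 0.2)
#' occ$taxa
#' @export
filter_and_binarize <- function(counts, min_occurrence_fraction = 0.10) {
  f <- min_occurrence_fraction
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("min_occurrence_fraction must be in (0, 1)", call. = FALSE)
  n_sites <- ncol(counts)
  threshold <- ceiling(f * n_sites)
  cs <- colSums(counts)
  rel <- sweep(counts, 2, pmax(cs, 1), "/")
  mra <- rowMeans(rel)
  presence <- (counts > 0) * 1L
  occupancy <- rowSums(presence)
  keep <- occupancy >= threshold
  if (!any(keep))
    stop("no taxon reaches the occupancy threshold of ", threshold,
         " sites", call. = FALSE)
  occurrence_matrix(presence[keep, , drop = FALSE],
                    mean_rel_abund = mra[keep],
                    threshold = threshold)
}

#' Construct an occurrence matrix object
#'
#' Low-level constructor used by [filter_and_binarize()] and by the
#' synthetic harness when a binary matrix is available directly.
#'
#' @param presence Binary taxa x site matrix with dimnames.
#' @param mean_rel_abund Optional per-taxon mean relative abundance
#'   annotation (named or in row order).
#' @param threshold Occupancy threshold recorded for provenance.
#' @return An `occurrence_matrix` object.
#' @export
occurrence_matrix <- function(presence, mean_rel_abund = NULL,
                              threshold = NA_integer_) {
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence matrix needs dimnames", call. = FALSE)
  if (!all(presence %in% c(0L, 1L)))
    stop("presence must be binary", call. = FALSE)
  if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence)))
    stop("duplicate taxon or site ids", call. = FALSE)
  taxa <- data.frame(
    taxon_id = rownames(presence),
    occupancy = rowSums(presence),
    mean_rel_abund = if (is.null(mean_rel_abund)) NA_real_
                     else unname(mean_rel_abund),
    stringsAsFactors = FALSE
  )
  structure(
    list(presence = presence, taxa = taxa, n_sites = ncol(presence),
         threshold = threshold),
    class = "occurrence_matrix"
  )
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("occurrence matrix:", nrow(x$presence), "taxa x", x$n_sites,
      "sites; occupancy threshold", x$threshold, "\n")
  invisible(x)
}
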