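# Synthetic metacommunity generator: sites with spatially structured
# environments, species with Gaussian niches and dispersal kernels, and
# planted pairwise facilitation/exclusion. Serves as the ground-truth
# harness for the pair-classification and attribution stages.

# Environmental covariates of an alpine lake district, with the unit
# ranges the generated fields are rescaled into.
.env_meta <- data.frame(
  var  = c("pH", "DOC", "NO3", "TP", "SRP", "DRSi", "SO4", "RWT", "altitude"),
  unit = c("unitless", "mg/L", "uM", "ug/L", "ug/L", "uM", "uM", "days", "m"),
  lo   = c(4.5, 0.3, 0.1, 1, 0.5, 1, 5, 5, 1600),
  hi   = c(9.5, 6.0, 40, 30, 10, 100, 150, 2000, 3000),
  stringsAsFactors = FALSE
)

#' Names of the environmental covariates carried by a site table
#'
#' @return Character vector of the nine covariate names (pH, DOC, NO3, TP,
#'   SRP, DRSi, SO4, RWT, altitude).
#' @export
env_variables <- function() .env_meta$var

#' Generate a spatially structured site table
#'
#' Draws site coordinates uniformly in a square landscape and generates
#' nine environmental covariates as smooth spatial fields: each covariate
#' is a mixture of a small number of shared latent fields (linear trend
#' plus Gaussian-kernel-smoothed noise) and a covariate-specific smooth
#' field, then rescaled linearly into its declared unit range. Sharing
#' latent fields makes covariates mutually correlated and partially
#' confounded with space, as in real lake districts.
#'
#' @param n_sites Number of sites (>= 10).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param bandwidth Gaussian smoothing bandwidth in coordinate units
#'   (landscape is 100 x 100).
#' @param n_latent Number of shared latent fields.
#' @return A `data.frame` with columns `site_id`, `x`, `y` and the nine
#'   covariates of [env_variables()].
#' @examples
#' sites <- generate_sites(24, seed = 1)
#' range(sites$pH)
#' @export
generate_sites <- function(n_sites = 224, seed = 1, bandwidth = 15, n_latent = 3) {
  if (!is.numeric(n_sites) || n_sites < 10)
    stop("n_sites must be at least 10", call. = FALSE)
  n_sites <- as.integer(n_sites)
  set.seed(seed)
  x <- runif(n_sites, 0, 100)
  y <- runif(n_sites, 0, 100)
  d2 <- as.matrix(dist(cbind(x, y)))^2
  W <- exp(-d2 / (2 * bandwidth^2))
  W <- W / rowSums(W)
  smooth_field <- function() {
    z <- as.vector(W %*% rnorm(n_sites))
    as.vector(scale(z))
  }
  trend_field <- function() {
    th <- runif(1, 0, 2 * pi)
    as.vector(scale(cos(th) * x + sin(th) * y))
  }
  latents <- vapply(
    seq_len(n_latent),
    function(k) as.vector(scale(trend_field() + smooth_field())),
    numeric(n_sites)
  )
  env <- vapply(seq_len(nrow(.env_meta)), function(v) {
    k1 <- ((v - 1L) %% n_latent) + 1L
    k2 <- (k1 %% n_latent) + 1L
    f <- 0.8 * latents[, k1] + 0.3 * latents[, k2] + 0.5 * smooth_field()
    lo <- .env_meta$lo[v]
    hi <- .env_meta$hi[v]
    lo + (f - min(f)) / (max(f) - min(f)) * (hi - lo)
  }, numeric(n_sites))
  colnames(env) <- .env_meta$var
  out <- data.frame(
    site_id = sprintf("L%03d", seq_len(n_sites)),
    x = x, y = y, env,
    stringsAsFactors = FALSE
  )
  class(out) <- c("site_table", "data.frame")
  out
}

#' Build a species specification table
#'
#' Each row describes one species of the generative occurrence model:
#' occurrence probability at a site is
#' `plogis(baseline_logit + niche + dispersal)` where the niche term is a
#' Gaussian bump `niche_height * exp(-(e - niche_center)^2 / (2 niche_width^2))`
#' in the covariate `niche_var`, and the dispersal term is a soft penalty
#' `-dispersal_decay * max(0, (d / dispersal_radius)^2 - 1)` on the
#' distance `d` to the dispersal center (zero inside the radius).
#'
#' @param species_id Character ids (unique).
#' @param baseline_logit Log-odds of occurrence with no effects.
#' @param niche_var Name of an environmental covariate, or `NA` for none.
#' @param niche_center,niche_width,niche_height Gaussian niche parameters
#'   in covariate units; `niche_width > 0` where `niche_var` is set.
#' @param disp_x,disp_y Dispersal center coordinates, or `NA` for none.
#' @param dispersal_radius,dispersal_decay Soft dispersal kernel: radius in
#'   coordinate units (> 0 where a center is set) and log-odds decay rate.
#' @param mean_abundance Expected relative abundance when present (> 0).
#' @return A `data.frame` with one row per species.
#' @export
species_spec <- function(species_id,
                         baseline_logit = 0,
                         niche_var = NA_character_,
                         niche_center = NA_real_,
                         niche_width = NA_real_,
                         niche_height = 4,
                         disp_x = NA_real_,
                         disp_y = NA_real_,
                         dispersal_radius = NA_real_,
                         dispersal_decay = 4,
                         mean_abundance = 1) {
  sp <- data.frame(
    species_id = as.character(species_id),
    baseline_logit = baseline_logit,
    niche_var = as.character(niche_var),
    niche_center = niche_center,
    niche_width = niche_width,
    niche_height = niche_height,
    disp_x = disp_x, disp_y = disp_y,
    dispersal_radius = dispersal_radius,
    dispersal_decay = dispersal_decay,
    mean_abundance = mean_abundance,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sp$species_id))
    stop("species ids must be unique", call. = FALSE)
  has_niche <- !is.na(sp$niche_var)
  if (any(has_niche & (is.na(sp$niche_width) | sp$niche_width <= 0)))
    stop("niche_width must be > 0 where niche_var is set", call. = FALSE)
  has_disp <- !is.na(sp$disp_x)
  if (any(has_disp & (is.na(sp$dispersal_radius) | sp$dispersal_radius <= 0)))
    stop("dispersal_radius must be > 0 where a dispersal center is set",
         call. = FALSE)
  if (any(sp$mean_abundance <= 0))
    stop("mean_abundance must be > 0", call. = FALSE)
  sp
}

#' Build an interaction specification table
#'
#' @param species_a,species_b Character ids of the pair members (distinct).
#' @param sign `+1` for facilitation, `-1` for exclusion.
#' @param strength Non-negative log-odds shift applied to `species_b` at
#'   sites where `species_a` is present; 0 means independence.
#' @return A `data.frame` with one row per directed planted interaction.
#' @export
interaction_spec <- function(species_a, species_b, sign = 1, strength = 0) {
  it <- data.frame(
    species_a = as.character(species_a),
    species_b = as.character(species_b),
    sign = as.numeric(sign), strength = as.numeric(strength),
    stringsAsFactors = FALSE
  )
  if (any(it$species_a == it$species_b))
    stop("interaction pair members must be distinct", call. = FALSE)
  if (any(!it$sign %in% c(-1, 1)))
    stop("sign must be +1 or -1", call. = FALSE)
  if (any(it$strength < 0))
    stop("strength must be >= 0", call. = FALSE)
  it
}

.occurrence_logits <- function(sites, species) {
  n <- nrow(sites)
  L <- matrix(rep(species$baseline_logit, each = n),
              nrow = nrow(species), ncol = n, byrow = TRUE)
  for (i in seq_len(nrow(species))) {
    if (!is.na(species$niche_var[i])) {
      v <- species$niche_var[i]
      if (!v %in% names(sites))
        stop("unknown niche_var: ", v, call. = FALSE)
      e <- sites[[v]]
      L[i, ] <- L[i, ] + species$niche_height[i] *
        exp(-(e - species$niche_center[i])^2 / (2 * species$niche_width[i]^2))
    }
    if (!is.na(species$disp_x[i])) {
      d <- sqrt((sites$x - species$disp_x[i])^2 +
                (sites$y - species$disp_y[i])^2)
      L[i, ] <- L[i, ] - species$dispersal_decay[i] *
        pmax(0, (d / species$dispersal_radius[i])^2 - 1)
    }
  }
  dimnames(L) <- list(species$species_id, sites$site_id)
  L
}

# Ground-truth cause labels for planted pairs, with priority
# interaction > dispersal > environment when causes overlap.
.planted_truth <- function(species, interactions, seed) {
  lab <- list()
  key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  add <- function(a, b, cause) {
    k <- key(a, b)
    if (is.null(lab[[k]])) lab[[k]] <<- c(sort(c(a, b)), cause)
  }
  if (!is.null(interactions) && nrow(interactions) > 0)
    for (i in seq_len(nrow(interactions)))
      add(interactions$species_a[i], interactions$species_b[i], "interaction")
  disp <- which(!is.na(species$disp_x))
  if (length(disp) > 1) {
    for (a in disp) for (b in disp) {
      if (a < b) {
        dd <- sqrt((species$disp_x[a] - species$disp_x[b])^2 +
                   (species$disp_y[a] - species$disp_y[b])^2)
        if (dd <= 1e-6)
          add(species$species_id[a], species$species_id[b], "dispersal")
      }
    }
  }
  nich <- which(!is.na(species$niche_var))
  if (length(nich) > 1) {
    for (a in nich) for (b in nich) {
      if (a < b && species$niche_var[a] == species$niche_var[b]) {
        overlap <- abs(species$niche_center[a] - species$niche_center[b]) <=
          species$niche_width[a] + species$niche_width[b]
        if (overlap)
          add(species$species_id[a], species$species_id[b], "environment")
      }
    }
  }
  pairs <- if (length(lab)) {
    do.call(rbind, lapply(unname(lab), function(z)
      data.frame(species_a = z[1], species_b = z[2], cause = z[3],
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(species_a = character(), species_b = character(),
               cause = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(pairs = pairs, species = species, interactions = interactions,
         seed = seed),
    class = "synthetic_truth"
  )
}

#' Simulate species occurrence over a site table
#'
#' Samples each species independently from its logistic occurrence model
#' (see [species_spec()]), then applies planted interactions by sequential
#' conditional sampling: for each interaction row, the second member is
#' resampled with its log-odds shifted by `sign * strength` at sites where
#' the first member is present. Ground-truth cause labels are recorded for
#' every planted pair: interaction pairs, pairs sharing a dispersal
#' center, and pairs with overlapping Gaussian niches in the same
#' covariate (priority interaction > dispersal > environment).
#'
#' @param sites A site table from [generate_sites()].
#' @param species A species table from [species_spec()].
#' @param interactions Optional interaction table from [interaction_spec()].
#' @param seed Integer seed.
#' @return A list with `presence` (binary species x site matrix) and
#'   `truth` (a `synthetic_truth` with the planted pair labels and specs).
#' @export
simulate_occurrence <- function(sites, species, interactions = NULL, seed = 1) {
  if (!is.null(interactions) && nrow(interactions) > 0) {
    unknown <- setdiff(
      unique(c(interactions$species_a, interactions$species_b)),
      species$species_id
    )
    if (length(unknown))
      stop("interaction references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  L <- .occurrence_logits(sites, species)
  n <- ncol(L)
  set.seed(seed)
  pres <- matrix(rbinom(length(L), 1L, plogis(L)),
                 nrow = nrow(L), dimnames = dimnames(L))
  if (!is.null(interactions) && nrow(interactions) > 0) {
    for (i in seq_len(nrow(interactions))) {
      a <- interactions$species_a[i]
      b <- interactions$species_b[i]
      shift <- interactions$sign[i] * interactions$strength[i] * pres[a, ]
      pres[b, ] <- rbinom(n, 1L, plogis(L[b, ] + shift))
    }
  }
  list(presence = pres, truth = .planted_truth(species, interactions, seed))
}

#' Simulate a sequencing count table from an occurrence matrix
#'
#' Per site, a sequencing depth is drawn uniformly from `depth_range` and
#' counts for the species present there are drawn from a multinomial with
#' probabilities proportional to `mean_abundance` times lognormal noise.
#' Counts are exactly zero where the species is absent.
#'
#' @param presence Binary species x site matrix.
#' @param species Species table ([species_spec()]) carrying
#'   `mean_abundance`.
#' @param depth_range Length-2 positive integer range of per-site depths.
#' @param seed Integer seed.
#' @param noise_sdlog Lognormal sd of per-site abundance noise.
#' @return Integer count matrix with the dimnames of `presence`.
#' @export
simulate_counts <- function(presence, species, depth_range = c(6000, 15000),
                            seed = 1, noise_sdlog = 0.5) {
  if (any(depth_range < 1)) stop("depths must be positive", call. = FALSE)
  ab <- setNames(species$mean_abundance, species$species_id)[rownames(presence)]
  if (anyNA(ab)) stop("species table missing ids of the presence matrix",
                      call. = FALSE)
  set.seed(seed)
  counts <- matrix(0L, nrow(presence), ncol(presence),
                   dimnames = dimnames(presence))
  for (j in seq_len(ncol(presence))) {
    present <- which(presence[, j] == 1L)
    depth <- depth_range[1] +
      sample.int(depth_range[2] - depth_range[1] + 1L, 1L) - 1L
    if (length(present) == 0L) {
      warning("site ", colnames(presence)[j],
              " has no species present; all-zero column emitted")
      next
    }
    p <- ab[present] * rlnorm(length(present), 0, noise_sdlog)
    counts[present, j] <- rmultinom(1, depth, p)[, 1]
  }
  counts
}

#' Assemble a demo community with planted causes
#'
#' Builds a species and interaction specification in which pairs of
#' species are planted with a known cause: environment pairs share a
#' Gaussian niche on one covariate (centers taken from observed site
#' values), dispersal pairs share a dispersal center (taken from site
#' coordinates), and interaction pairs carry a conditional log-odds shift
#' (half facilitation, half exclusion). Background species have no
#' structure. Defaults produce 150 species mirroring the scale of an
#' alpine-lakes survey.
#'
#' @param sites Site table used to anchor niche centers and dispersal
#'   centers at realistic values.
#' @param n_env_pairs,n_dispersal_pairs,n_interaction_pairs Number of
#'   planted pairs per cause (two species each).
#' @param n_background Number of unstructured species.
#' @param interaction_strength Log-odds shift of the planted interactions.
#' @param seed Integer seed for the spec draw (independent of occurrence
#'   sampling).
#' @return List with `species` and `interactions` tables.
#' @export
demo_community <- function(sites, n_env_pairs = 25, n_dispersal_pairs = 15,
                           n_interaction_pairs = 20, n_background = 30,
                           interaction_strength = 4, seed = 1) {
  set.seed(seed)
  sp <- list()
  it <- list()
  idx <- 0L
  nid <- function(prefix) {
    idx <<- idx + 1L
    sprintf("%s%03d", prefix, idx)
  }
  vars <- env_variables()
  for (k in seq_len(n_env_pairs)) {
    v <- vars[((k - 1L) %% length(vars)) + 1L]
    center <- sample(sites[[v]], 1)
    width <- 0.15 * diff(range(sites[[v]]))
    ids <- c(nid("env"), nid("env"))
    sp[[length(sp) + 1L]] <- species_spec(
      ids, baseline_logit = -2, niche_var = v,
      niche_center = center + c(-0.2, 0.2) * width, niche_width = width,
      niche_height = 4.5
    )
  }
  for (k in seq_len(n_dispersal_pairs)) {
    j <- sample(nrow(sites), 1)
    ids <- c(nid("dsp"), nid("dsp"))
    sp[[length(sp) + 1L]] <- species_spec(
      ids, baseline_logit = 1,
      disp_x = sites$x[j], disp_y = sites$y[j],
      dispersal_radius = 20, dispersal_decay = 4
    )
  }
  for (k in seq_len(n_interaction_pairs)) {
    sgn <- if (k <= ceiling(n_interaction_pairs / 2)) 1 else -1
    ids <- c(nid("int"), nid("int"))
    sp[[length(sp) + 1L]] <- species_spec(ids, baseline_logit = 0)
    it[[length(it) + 1L]] <- interaction_spec(
      ids[1], ids[2], sign = sgn, strength = interaction_strength
    )
  }
  if (n_background > 0)
    sp[[length(sp) + 1L]] <- species_spec(
      vapply(seq_len(n_background), function(i) nid("bkg"), character(1)),
      baseline_logit = 0
    )
  species <- do.call(rbind, sp)
  # lognormal abundance spread, independent of planted causes
  species$mean_abundance <- rlnorm(nrow(species), 0, 1)
  interactions <- if (length(it)) do.call(rbind, it) else NULL
  list(species = species, interactions = interactions)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic truth:", nrow(x$pairs), "planted pairs (",
      paste(sprintf("%s=%d", names(table(x$pairs$cause)),
                    as.integer(table(x$pairs$cause))), collapse = ", "),
      "), seed", x$seed, "\n")
  invisible(x)
}
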