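#' Describe a synthetic sampling design
#'
#' The default design emulates a coast-to-basin transect: 4 stations x 3
#' depth layers x 7 replicates = 84 samples, with a temperature-like
#' gradient that warms offshore at the surface and cools offshore at depth.
#'
#' @param n_stations,n_layers,n_replicates_per_cell design dimensions; the
#'   product is the number of samples.
#' @param station_coords matrix/data.frame with `latitude`, `longitude`
#'   rows per station (decimal degrees).
#' @param env_gradient numeric `n_stations x n_layers` matrix of
#'   temperature-like values per design cell.
#' @param env_noise_sd within-cell spread of the variable (same units).
#' @param read_depth reads per sample (> 0).
#' @param seed integer seed recorded in the design.
#' @return a list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_stations = 4, n_layers = 3,
                             n_replicates_per_cell = 7,
                             station_coords = NULL, env_gradient = NULL,
                             env_noise_sd = 0.3, read_depth = 5000,
                             seed = 1) {
  if (read_depth <= 0) stop_invalid("read_depth must be > 0")
  if (n_stations < 1 || n_layers < 1 || n_layers > 3 ||
      n_replicates_per_cell < 1)
    stop_invalid("design dimensions must be positive (<= 3 layers)")
  if (is.null(station_coords)) {
    # transect from coastal to basin stations, ~500 km span
    lat <- seq(22.2, 18.2, length.out = n_stations)
    lon <- seq(114.6, 116.0, length.out = n_stations)
    station_coords <- data.frame(latitude = lat, longitude = lon)
  }
  if (is.null(env_gradient)) {
    # rows: stations (coast -> basin); cols: surface, DCM, bottom
    base <- cbind(surface = seq(27.5, 30.0, length.out = n_stations),
                  DCM = seq(25.0, 22.0, length.out = n_stations),
                  bottom = seq(22.0, 17.0, length.out = n_stations))
    env_gradient <- base[, seq_len(n_layers), drop = FALSE]
  }
  env_gradient <- as.matrix(env_gradient)
  if (!all(dim(env_gradient) == c(n_stations, n_layers)))
    stop_invalid("env_gradient must be n_stations x n_layers")
  structure(list(n_stations = n_stations, n_layers = n_layers,
                 n_replicates_per_cell = n_replicates_per_cell,
                 station_coords = as.data.frame(station_coords),
                 env_gradient = env_gradient, env_noise_sd = env_noise_sd,
                 read_depth = as.integer(read_depth), seed = seed),
            class = "synthetic_design")
}

#' Describe an assembly scenario (the ground truth of a simulation)
#'
#' The four processes quantified downstream are realized by three knobs:
#' a Gaussian environmental filter of width `1/sqrt(2*selection_strength)`
#' acting on trait-environment mismatch (selection), an exponential
#' distance kernel mixing station source pools (dispersal limitation when
#' narrow, homogenizing dispersal when wide), and a Dirichlet resampling
#' step whose concentration `migration_rate_m * read_depth` injects
#' demographic drift (drift dominates as `m` shrinks or when `drift_only`).
#'
#' @param selection_strength >= 0; 0 disables environmental filtering.
#' @param dispersal_kernel_scale > 0 km; `Inf` mixes all stations fully.
#' @param migration_rate_m in (0, 1].
#' @param drift_only if `TRUE`, every sample resamples the metacommunity.
#' @param pool_noise_sd sd of the log-normal station-pool perturbation that
#'   differentiates station source pools before kernel mixing.
#' @return a list of class `assembly_scenario`.
#' @export
assembly_scenario <- function(selection_strength = 0,
                              dispersal_kernel_scale = Inf,
                              migration_rate_m = 1,
                              drift_only = FALSE,
                              pool_noise_sd = 1) {
  if (!is.numeric(selection_strength) || selection_strength < 0 ||
      is.na(selection_strength))
    stop_invalid("selection_strength must be >= 0")
  if (!is.numeric(dispersal_kernel_scale) || dispersal_kernel_scale <= 0)
    stop_invalid("dispersal_kernel_scale must be > 0")
  if (!is.numeric(migration_rate_m) || migration_rate_m <= 0 ||
      migration_rate_m > 1)
    stop_invalid("migration_rate_m must be in (0, 1]")
  structure(list(selection_strength = selection_strength,
                 dispersal_kernel_scale = dispersal_kernel_scale,
                 migration_rate_m = migration_rate_m,
                 drift_only = isTRUE(drift_only),
                 pool_noise_sd = pool_noise_sd),
            class = "assembly_scenario")
}

#' Simulate sample metadata for a design
#'
#' One row per sample with station, habitat class (first half of the
#' stations is nearshore), depth layer, coordinates, depth and
#' environmental covariates.  The temperature-like variable equals the
#' design's `env_gradient` cell value plus Gaussian noise.
#'
#' @param design a [synthetic_design].
#' @param seed optional seed (defaults to the design's).
#' @return metadata data.frame, one row per sample.
#' @export
simulate_metadata <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  layers <- LAYER_LEVELS[seq_len(design$n_layers)]
  grid <- expand.grid(replicate = seq_len(design$n_replicates_per_cell),
                      layer = layers,
                      station = seq_len(design$n_stations),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  layer_idx <- match(grid$layer, layers)
  depth_by_layer <- c(surface = 5, DCM = 50, bottom = 120)
  with_seed(seed, {
    temp <- design$env_gradient[cbind(grid$station, layer_idx)] +
      stats::rnorm(n, 0, design$env_noise_sd)
    md <- data.frame(
      sample_id = sprintf("St%d_%s_R%d", grid$station, grid$layer,
                          grid$replicate),
      station = paste0("St", grid$station),
      habitat_class = ifelse(grid$station <= design$n_stations / 2,
                             "nearshore", "offshore"),
      layer = grid$layer,
      latitude = design$station_coords$latitude[grid$station],
      longitude = design$station_coords$longitude[grid$station],
      depth_m = unname(depth_by_layer[grid$layer]),
      temperature = temp,
      salinity = 33.5 + 0.2 * grid$station + stats::rnorm(n, 0, 0.05),
      dissolved_oxygen = 7.5 - 0.02 * unname(depth_by_layer[grid$layer]) +
        stats::rnorm(n, 0, 0.1),
      bacterial_abundance = exp(13.5 - 0.25 * grid$station +
                                  stats::rnorm(n, 0, 0.2)),
      stringsAsFactors = FALSE)
    validate_metadata(md)
    md
  })
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Draw a log-normal metacommunity abundance profile
#'
#' @param n_taxa number of OTUs.
#' @param meanlog,sdlog log-normal parameters; the default sd of 1.5 gives
#'   realistic steep rank-abundance curves.
#' @param seed optional seed.
#' @return proportions summing to 1.
#' @export
simulate_metacommunity <- function(n_taxa, meanlog = 0, sdlog = 1.5,
                                   seed = NULL) {
  with_seed(seed, {
    w <- stats::rlnorm(n_taxa, meanlog, sdlog)
    w / sum(w)
  })
}

#' Assemble synthetic communities under a known scenario
#'
#' Per sample, OTU sampling weights are
#' `station pool x exp(-selection_strength * (trait - env)^2)`, where the
#' station pools are log-normally perturbed copies of the metacommunity
#' mixed across stations (within each depth layer) with kernel
#' `exp(-distance_km / dispersal_kernel_scale)`.  The composition is then
#' Dirichlet-resampled with concentration `m * read_depth` (drift) and
#' `read_depth` reads are drawn multinomially.
#'
#' @param tree `phylo` whose tips cover the OTU pool.
#' @param traits named per-tip niche optimum (same scale as `env`).
#' @param metadata data.frame from [simulate_metadata] (needs `station`,
#'   `layer`, `latitude`, `longitude`, `temperature`).
#' @param scenario an [assembly_scenario].
#' @param read_depth reads per sample.
#' @param metacommunity optional proportions per tip; defaults to a
#'   log-normal draw.
#' @param seed optional seed.
#' @return an [otu_table] (samples x OTUs).
#' @export
assemble_communities <- function(tree, traits, metadata, scenario,
                                 read_depth = 5000, metacommunity = NULL,
                                 seed = NULL) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  tips <- tree$tip.label
  if (!all(tips %in% names(traits)))
    stop_invalid("traits must be named for every tree tip")
  traits <- traits[tips]
  validate_metadata(metadata)
  n_taxa <- length(tips)
  n_samp <- nrow(metadata)
  with_seed(seed, {
    if (is.null(metacommunity)) metacommunity <- simulate_metacommunity(n_taxa)
    if (length(metacommunity) != n_taxa)
      stop_invalid("metacommunity length must match tree tips")
    meta <- metacommunity / sum(metacommunity)

    stations <- unique(metadata$station)
    layers <- unique(metadata$layer)
    coords <- metadata[match(stations, metadata$station),
                       c("latitude", "longitude")]
    sd_km <- geographic_distance(
      data.frame(sample_id = stations, coords))
    kern <- exp(-sd_km / scenario$dispersal_kernel_scale)
    if (any(!is.finite(kern))) kern[!is.finite(kern)] <- 1

    # station x layer source pools: perturbed metacommunity, kernel-mixed
    # across stations within each layer (layers are never mixed)
    pools <- array(0, dim = c(length(stations), length(layers), n_taxa))
    for (li in seq_along(layers)) {
      raw <- matrix(0, length(stations), n_taxa)
      for (si in seq_along(stations))
        raw[si, ] <- meta * exp(stats::rnorm(n_taxa, 0,
                                             scenario$pool_noise_sd))
      raw <- raw / rowSums(raw)
      mixed <- (kern / rowSums(kern)) %*% raw
      pools[, li, ] <- mixed / rowSums(mixed)
    }

    counts <- matrix(0, n_samp, n_taxa,
                     dimnames = list(metadata$sample_id, tips))
    conc <- scenario$migration_rate_m * read_depth
    for (i in seq_len(n_samp)) {
      if (scenario$drift_only) {
        w <- meta
      } else {
        si <- match(metadata$station[i], stations)
        li <- match(metadata$layer[i], layers)
        w <- pools[si, li, ]
        if (scenario$selection_strength > 0) {
          env <- metadata$temperature[i]
          w <- w * exp(-scenario$selection_strength * (traits - env)^2)
        }
        if (sum(w) == 0) w <- meta
        w <- w / sum(w)
      }
      comp <- rdirichlet1(conc * w)
      counts[i, ] <- stats::rmultinom(1, read_depth, comp)[, 1L]
    }
    otu_table(counts)
  })
}

#' Simulate samples from the Sloan neutral model
#'
#' Each sample's composition is drawn from a Dirichlet distribution with
#' concentration `Nm * source_proportions` (the marginal of every OTU is
#' the Beta distribution the neutral fit assumes) and reads are drawn
#' multinomially.
#'
#' @param Nm metacommunity size x migration rate (> 0).
#' @param source_proportions metacommunity relative abundances (sum to 1).
#' @param n_samples,read_depth sampling effort.
#' @param seed optional seed.
#' @return an [otu_table].
#' @export
simulate_neutral_metacommunity <- function(Nm, source_proportions, n_samples,
                                           read_depth, seed = NULL) {
  if (!is.numeric(Nm) || Nm <= 0) stop_invalid("Nm must be > 0")
  p <- source_proportions
  if (abs(sum(p) - 1) > 1e-8) stop_invalid("source proportions must sum to 1")
  with_seed(seed, {
    counts <- matrix(0, n_samples, length(p))
    for (i in seq_len(n_samples)) {
      comp <- rdirichlet1(Nm * p)
      counts[i, ] <- stats::rmultinom(1, read_depth, comp)[, 1L]
    }
    nm <- names(p)
    if (is.null(nm)) nm <- paste0("OTU", seq_along(p))
    otu_table(counts, paste0("S", seq_len(n_samples)), nm)
  })
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Convenience wrapper tying together tree, Brownian niche traits,
#' metadata and community assembly under one scenario.
#'
#' @param design a [synthetic_design].
#' @param scenario an [assembly_scenario].
#' @param n_taxa OTU pool size.
#' @param sigma2 Brownian rate for niche traits; traits are rescaled to the
#'   span of the design's environmental gradient so the filter can act.
#' @param seed master seed; all stages derive from it.
#' @return list with `otu_table`, `tree`, `traits`, `metadata`, `truth`.
#' @export
simulate_dataset <- function(design = synthetic_design(),
                             scenario = assembly_scenario(),
                             n_taxa = 200, sigma2 = 1, seed = design$seed) {
  tree <- simulate_tree(n_taxa, seed = derive_seed(seed, 1))
  traits <- evolve_traits(tree, sigma2, seed = derive_seed(seed, 2))
  rng <- range(design$env_gradient)
  if (diff(range(traits)) > 0) {
    traits <- (traits - min(traits)) / diff(range(traits))
    traits <- rng[1] + traits * diff(rng)
  } else {
    traits <- traits * 0 + mean(rng)
  }
  metadata <- simulate_metadata(design, seed = derive_seed(seed, 3))
  table <- assemble_communities(tree, traits, metadata, scenario,
                                read_depth = design$read_depth,
                                seed = derive_seed(seed, 4))
  list(otu_table = table, tree = tree, traits = traits, metadata = metadata,
       truth = scenario, design = design)
}

#' Write a synthetic dataset to plain-text files
#'
#' @param dataset result of [simulate_dataset].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(dataset$otu_table, file.path(dir, "otu_table.tsv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(
    data.frame(otu_id = names(dataset$traits), trait = dataset$traits),
    file.path(dir, "traits.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(unclass(dataset$truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
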