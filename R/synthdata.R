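# Seeded synthetic-data generator.
#
# Emulates the statistical structure the analysis assumes: ~39 strains in
# four genospecies clusters of uneven frequency (26/8/2/3), three
# housekeeping loci of lengths 1045/390/307 bp, sampling sites along a
# noisy SW-NE transect with two geographically restricted clusters at the
# south-western end, one cluster confined to high-elevation sites
# (> 2400 m), isolation by distance within the dominant cluster, and
# balanced RCBD greenhouse trait data with strain random effects.

#' Simulation configuration
#'
#' Defaults are the study conditions the generator emulates: 39 strains in
#' clusters of 26/8/2/3, locus lengths 1045/390/307 bp, a ~400 km SW-NE
#' transect, an elevation-restricted cluster above 2400 m, and a
#' 3-replicate randomized complete block greenhouse trial.
#'
#' @param n_strains Number of query strains (default 39).
#' @param cluster_frequencies Strains per genospecies cluster; must sum to
#'   `n_strains` (default `c(26, 8, 2, 3)`).
#' @param locus_lengths Named lengths (bp) of the housekeeping loci
#'   (default 16S 1045, atpD 390, recA 307; concatenated 1742).
#' @param within_cluster_divergence Expected substitutions/site separating
#'   a strain from its cluster ancestor (default 0.005).
#' @param between_cluster_divergence Expected substitutions/site separating
#'   a cluster ancestor from the root (default 0.03).
#' @param base_freqs Root base composition (default GC-rich, as in
#'   rhizobial housekeeping genes).
#' @param kappa Transition/transversion rate ratio of the substitution
#'   kernel (default 2).
#' @param transect_length_km Length of the sampling transect (default 400).
#' @param n_sites Number of sampling sites (default 16).
#' @param ibd_strength Fraction of each strain's mutations placed on the
#'   geographic gradient (0 = exchangeable null, 1 = fully gradient);
#'   default 0.8.
#' @param clonal_rate Probability that a strain repeats its site founder's
#'   haplotype exactly (local clonality; default 0.5).
#' @param elevation_threshold_m Elevation rule threshold (default 2400):
#'   the `elevation_cluster` occurs only at sites above it.
#' @param elevation_cluster Index of the elevation-restricted cluster
#'   (default 4).
#' @param spatial_structure If `TRUE` (default) clusters 2-3 are restricted
#'   to the SW end of the transect and the elevation rule applies; set
#'   `FALSE` for a spatially exchangeable null.
#' @param gap_rate Per-site probability of replacing a base with a gap in
#'   each query sequence (default 0; used to exercise pairwise deletion).
#' @param n_replicates Greenhouse replicates (blocks; default 3).
#' @param trait_model List: `mu` (trait means: nodule_number,
#'   nodule_dw_mg, shoot_dw_g, root_dw_g), `beta` (per-trait loading of the
#'   latent strain effectiveness, relative scale), `cv_rep` (replicate/block
#'   coefficient of variation), `cv_e` (residual CV), `sigma_strain`
#'   (SD of the latent strain effect), `control_deficit` (relative biomass
#'   deficit of the uninoculated control).
#' @param seed Integer seed; sub-generators use `seed + 1..3`.
#' @return Object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_strains = 39,
                              cluster_frequencies = c(26, 8, 2, 3),
                              locus_lengths = c(`16S_rRNA` = 1045,
                                                atpD = 390, recA = 307),
                              within_cluster_divergence = 0.005,
                              between_cluster_divergence = 0.03,
                              base_freqs = c(A = 0.19, C = 0.31,
                                             G = 0.31, T = 0.19),
                              kappa = 2,
                              transect_length_km = 400,
                              n_sites = 16,
                              ibd_strength = 0.8,
                              clonal_rate = 0.5,
                              elevation_threshold_m = 2400,
                              elevation_cluster = 4,
                              spatial_structure = TRUE,
                              gap_rate = 0,
                              n_replicates = 3,
                              trait_model = list(),
                              seed = NULL) {
  if (sum(cluster_frequencies) != n_strains) {
    stop_rg("cluster_frequencies must sum to n_strains",
            class = "rhizogeo_input_error")
  }
  if (any(cluster_frequencies < 1)) {
    stop_rg("each cluster needs at least one strain",
            class = "rhizogeo_input_error")
  }
  if (any(locus_lengths < 1)) {
    stop_rg("locus lengths must be >= 1", class = "rhizogeo_input_error")
  }
  stopifnot(within_cluster_divergence >= 0, within_cluster_divergence < 1,
            between_cluster_divergence >= 0, between_cluster_divergence < 1,
            ibd_strength >= 0, ibd_strength <= 1,
            clonal_rate >= 0, clonal_rate <= 1,
            abs(sum(base_freqs) - 1) < 1e-8)
  tm <- utils::modifyList(list(
    mu = c(nodule_number = 25, nodule_dw_mg = 40,
           shoot_dw_g = 1.2, root_dw_g = 0.9),
    beta = c(nodule_number = 0.25, nodule_dw_mg = 0.30,
             shoot_dw_g = 0.10, root_dw_g = 0.08),
    cv_rep = 0.05, cv_e = 0.20, sigma_strain = 1, control_deficit = 0.15),
    trait_model)
  structure(list(n_strains = n_strains,
                 n_clusters = length(cluster_frequencies),
                 cluster_frequencies = cluster_frequencies,
                 locus_lengths = locus_lengths,
                 within_cluster_divergence = within_cluster_divergence,
                 between_cluster_divergence = between_cluster_divergence,
                 base_freqs = base_freqs, kappa = kappa,
                 transect_length_km = transect_length_km,
                 n_sites = n_sites, ibd_strength = ibd_strength,
                 clonal_rate = clonal_rate,
                 elevation_threshold_m = elevation_threshold_m,
                 elevation_cluster = elevation_cluster,
                 spatial_structure = spatial_structure,
                 gap_rate = gap_rate, n_replicates = n_replicates,
                 trait_model = tm, seed = seed),
            class = "sim_config")
}

strain_names <- function(cfg) {
  sprintf("S%02d", seq_len(cfg$n_strains))
}

cluster_labels <- function(cfg) {
  as.character(utils::as.roman(seq_len(cfg$n_clusters)))
}

# Substitute a base: transition with probability kappa/(kappa + 2), else
# one of the two transversions uniformly. Codes 1..4 = A, C, G, T.
TRANSITION_PARTNER <- c(3L, 4L, 1L, 2L)
TRANSVERSIONS <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

mutate_bases <- function(bases, kappa) {
  n <- length(bases)
  if (!n) return(bases)
  is_ts <- stats::runif(n) < kappa / (kappa + 2)
  out <- bases
  out[is_ts] <- TRANSITION_PARTNER[bases[is_ts]]
  if (any(!is_ts)) {
    tv <- which(!is_ts)
    pick <- 1L + (stats::runif(length(tv)) < 0.5)
    out[tv] <- vapply(seq_along(tv), function(i)
      TRANSVERSIONS[[bases[tv[i]]]][pick[i]], integer(1))
  }
  out
}

#' Simulate sampling geography along a SW-NE transect
#'
#' Sites are placed along a noisy linear transect of
#' `cfg$transect_length_km` starting in south-western Ethiopia. With
#' `spatial_structure = TRUE` (the study condition), clusters 2-3 are
#' restricted to the south-western fifth of the transect (cluster 3 to a
#' single site), the elevation cluster occurs only at two sites above the
#' elevation threshold, and the dominant cluster is spread over the
#' remaining range. With `spatial_structure = FALSE` all strains are
#' placed uniformly over sites (exchangeable null).
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (default derived from `cfg$seed`).
#' @return data.frame with columns strain, cluster, site, transect_km,
#'   latitude, longitude, elevation_m.
#' @export
simulate_geography <- function(cfg, seed = if (is.null(cfg$seed)) NULL
                               else cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    K <- cfg$n_clusters
    cluster <- rep(seq_len(K), cfg$cluster_frequencies)
    n_sites <- cfg$n_sites
    # at least 3 sites in the SW fifth so restricted clusters have homes
    pos <- sort(c(stats::runif(3, 0, 0.2),
                  stats::runif(n_sites - 3, 0, 1))) * cfg$transect_length_km
    elev <- stats::runif(n_sites, 1500, 2300)
    high_sites <- integer(0)
    if (cfg$spatial_structure && cfg$elevation_cluster <= K) {
      candidates <- which(pos > 0.5 * cfg$transect_length_km)
      high_sites <- sample(candidates, 2)
      elev[high_sites] <- stats::runif(2, cfg$elevation_threshold_m + 50,
                                       cfg$elevation_threshold_m + 250)
    }
    sw_sites <- which(pos <= 0.2 * cfg$transect_length_km)
    general <- setdiff(seq_len(n_sites), high_sites)
    site <- integer(cfg$n_strains)
    for (k in seq_len(K)) {
      idx <- which(cluster == k)
      site[idx] <- if (!cfg$spatial_structure) {
        sample(n_sites, length(idx), replace = TRUE)
      } else if (k == cfg$elevation_cluster && length(high_sites)) {
        sample(high_sites, length(idx), replace = TRUE)
      } else if (k == 3L && K >= 3L) {
        rep(sample(sw_sites, 1), length(idx))
      } else if (k == 2L && K >= 2L) {
        sample(sw_sites, length(idx), replace = TRUE)
      } else {
        sample(general, length(idx), replace = TRUE)
      }
    }
    # project transect km to coordinates: origin in SW Ethiopia, bearing NE
    lat0 <- 6.8; lon0 <- 37.2
    lateral <- stats::rnorm(n_sites, 0, 3)  # km, perpendicular jitter
    north <- pos * cos(pi / 4) + lateral * cos(3 * pi / 4)
    east <- pos * sin(pi / 4) + lateral * sin(3 * pi / 4)
    lat <- lat0 + north / 111.195
    lon <- lon0 + east / (111.195 * cos(lat0 * pi / 180))
    data.frame(strain = strain_names(cfg), cluster = cluster, site = site,
               transect_km = pos[site], latitude = lat[site],
               longitude = lon[site], elevation_m = elev[site],
               stringsAsFactors = FALSE)
  })
}

#' Simulate multilocus sequences with cluster and gradient structure
#'
#' Each cluster descends from an ancestral sequence mutated from a global
#' root at the between-cluster rate; strains carry exactly
#' `round(within_cluster_divergence * L)` substitutions relative to their
#' cluster ancestor. A fraction `ibd_strength` of those substitutions is
#' drawn from a cluster-specific pool of candidate positions in a
#' contiguous block whose offset slides with the strain's transect
#' position, so that nearby strains share mutations and genetic distance
#' grows with geographic distance; the remainder are private random
#' substitutions. When `geography` is `NULL` all mutations are private
#' (no gradient). Strains at a shared site repeat their site founder's
#' haplotype with probability `clonal_rate`.
#'
#' @param cfg A [simulation_config()].
#' @param geography Optional data.frame from [simulate_geography()].
#' @param seed Integer seed (default derived from `cfg$seed`).
#' @return List: `mla` (a `multilocus_alignment` of the query strains),
#'   `ref_alignment` (a [locus_alignment()] of one clean ancestor sequence
#'   per cluster, aligned to the same columns), `ref_labels` (named
#'   genospecies labels for the references).
#' @export
simulate_sequences <- function(cfg, geography = NULL,
                               seed = if (is.null(cfg$seed)) NULL
                               else cfg$seed + 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- sum(cfg$locus_lengths)
  with_seed(seed, {
    root <- sample.int(4L, L, replace = TRUE, prob = cfg$base_freqs)
    K <- cfg$n_clusters
    cluster <- rep(seq_len(K), cfg$cluster_frequencies)
    ancestors <- lapply(seq_len(K), function(k) {
      anc <- root
      hit <- which(stats::runif(L) < cfg$between_cluster_divergence)
      anc[hit] <- mutate_bases(anc[hit], cfg$kappa)
      anc
    })
    m <- round(cfg$within_cluster_divergence * L)
    seqs <- matrix(0L, cfg$n_strains, L)
    for (k in seq_len(K)) {
      idx <- which(cluster == k)
      use_grad <- !is.null(geography) && cfg$ibd_strength > 0 && m > 0
      m_grad <- if (use_grad) round(cfg$ibd_strength * m) else 0L
      m_priv <- m - m_grad
      pool <- if (m_grad > 0) sample.int(L, min(L, 2L * m)) else integer(0)
      tpos <- if (use_grad) {
        tk <- geography$transect_km[idx]
        if (length(idx) > 1L && stats::sd(tk) > 0) {
          (rank(tk, ties.method = "first") - 1) / (length(idx) - 1)
        } else rep(0, length(idx))
      } else rep(0, length(idx))
      for (i in seq_along(idx)) {
        s <- ancestors[[k]]
        hit <- integer(0)
        if (m_grad > 0) {
          off <- round(tpos[i] * (length(pool) - m_grad))
          hit <- pool[(off + 1):(off + m_grad)]
        }
        if (m_priv > 0) {
          hit <- c(hit, sample(setdiff(seq_len(L), pool), m_priv))
        }
        s[hit] <- mutate_bases(s[hit], cfg$kappa)
        seqs[idx[i], ] <- s
      }
    }
    # local clonality: repeat the site founder's haplotype
    if (!is.null(geography) && cfg$clonal_rate > 0) {
      for (k in seq_len(K)) {
        for (st in unique(geography$site[cluster == k])) {
          members <- which(cluster == k & geography$site == st)
          if (length(members) > 1L) {
            for (i in members[-1]) {
              if (stats::runif(1) < cfg$clonal_rate) {
                seqs[i, ] <- seqs[members[1], ]
              }
            }
          }
        }
      }
    }
    chars <- matrix(UNAMBIGUOUS[seqs], nrow(seqs), L)
    if (cfg$gap_rate > 0) {
      gaps <- matrix(stats::runif(length(chars)) < cfg$gap_rate,
                     nrow(chars), ncol(chars))
      chars[gaps] <- "-"
    }
    rownames(chars) <- strain_names(cfg)
    bounds <- cumsum(c(0, cfg$locus_lengths))
    loci <- lapply(seq_along(cfg$locus_lengths), function(j) {
      locus_alignment(chars[, (bounds[j] + 1):bounds[j + 1], drop = FALSE],
                      names(cfg$locus_lengths)[j])
    })
    ref_chars <- matrix(UNAMBIGUOUS[do.call(rbind, ancestors)], K, L)
    rownames(ref_chars) <- sprintf("REF_%s", cluster_labels(cfg))
    ref_aln <- locus_alignment(ref_chars, "reference_panel")
    list(mla = concatenate_loci(loci),
         ref_alignment = ref_aln,
         ref_labels = stats::setNames(cluster_labels(cfg),
                                      rownames(ref_chars)))
  })
}

#' Simulate a balanced greenhouse trait table
#'
#' One latent effectiveness per strain (N(0, sigma_strain^2)) drives all
#' four correlated traits through trait-specific loadings:
#' `y = mu_t * (1 + beta_t * a_i + b_j + e_ij)` with replicate (block)
#' effects `b_j ~ N(0, cv_rep^2)` and residuals `e ~ N(0, cv_e^2)`.
#' The uninoculated control has latent effectiveness 0, zero nodulation,
#' and biomass reduced by `control_deficit`. Values are truncated at zero
#' and nodule counts rounded.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (default derived from `cfg$seed`).
#' @param latent_override Optional named vector forcing the latent effect
#'   of specific strains (e.g. `c(S05 = 5)` plants a +5 SD strain).
#' @return List: `traits` (a `trait_table` data.frame incl. the
#'   `"control"` rows), `latent` (true strain effects).
#' @export
simulate_traits <- function(cfg, seed = if (is.null(cfg$seed)) NULL
                            else cfg$seed + 3L,
                            latent_override = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  tm <- cfg$trait_model
  with_seed(seed, {
    ids <- strain_names(cfg)
    a <- stats::rnorm(length(ids), 0, tm$sigma_strain)
    names(a) <- ids
    if (!is.null(latent_override)) {
      a[names(latent_override)] <- latent_override
    }
    all_ids <- c(ids, "control")
    r <- cfg$n_replicates
    traits <- names(tm$mu)
    rows <- expand.grid(strain = all_ids, replicate = seq_len(r),
                        stringsAsFactors = FALSE)
    b <- matrix(stats::rnorm(r * length(traits), 0, tm$cv_rep), r,
                length(traits), dimnames = list(NULL, traits))
    out <- rows
    for (tr in traits) {
      lat <- ifelse(rows$strain == "control", 0, a[rows$strain])
      y <- tm$mu[tr] * (1 + tm$beta[tr] * lat + b[rows$replicate, tr] +
                          stats::rnorm(nrow(rows), 0, tm$cv_e))
      if (tr %in% c("nodule_number", "nodule_dw_mg")) {
        y[rows$strain == "control"] <- 0
      } else {
        ctl <- rows$strain == "control"
        y[ctl] <- y[ctl] * (1 - tm$control_deficit)
      }
      y <- pmax(y, 0)
      if (tr == "nodule_number") y <- round(y)
      out[[tr]] <- unname(y)
    }
    class(out) <- c("trait_table", "data.frame")
    list(traits = out, latent = a)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Chains [simulate_geography()], [simulate_sequences()] and
#' [simulate_traits()] under sub-seeds derived from `cfg$seed`, and
#' assembles a truth record sufficient to score recovery of every
#' estimated quantity. Identical seeds yield identical datasets.
#'
#' @param cfg A [simulation_config()] (use its `seed` for reproducibility).
#' @return Object of class `synthetic_dataset`: `config`, `metadata`,
#'   `mla`, `ref_alignment`, `ref_labels`, `traits`, `truth`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  geo <- simulate_geography(cfg)
  sq <- simulate_sequences(cfg, geography = geo)
  tr <- simulate_traits(cfg)
  truth <- list(cluster = stats::setNames(cluster_labels(cfg)[geo$cluster],
                                          geo$strain),
                latent_effect = tr$latent,
                parameters = unclass(cfg)[c(
                  "within_cluster_divergence", "between_cluster_divergence",
                  "ibd_strength", "clonal_rate", "elevation_threshold_m",
                  "spatial_structure")],
                seed = cfg$seed)
  structure(list(config = cfg, metadata = geo, mla = sq$mla,
                 ref_alignment = sq$ref_alignment,
                 ref_labels = sq$ref_labels, traits = tr$traits,
                 truth = truth),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk in pipeline input formats
#'
#' Per-locus FASTA, reference FASTA + label TSV, metadata CSV, trait CSV
#' and a JSON truth record.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(ds$mla$loci)) {
    write_fasta_alignment(ds$mla$loci[[nm]],
                          file.path(dir, paste0(nm, ".fasta")))
  }
  write_fasta_alignment(ds$ref_alignment, file.path(dir, "references.fasta"))
  utils::write.table(data.frame(reference = names(ds$ref_labels),
                                genospecies = unname(ds$ref_labels)),
                     file.path(dir, "reference_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(ds$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  truth <- ds$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
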