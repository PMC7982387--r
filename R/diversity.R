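# Diversity at the species (index), haplotype and nucleotide levels, plus
# the bootstrap comparison of an observed sample against a reference
# population.

check_counts <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) {
    stop_rg("all counts are zero", class = "rhizogeo_input_error")
  }
  if (any(counts < 0)) {
    stop_rg("negative counts", class = "rhizogeo_input_error")
  }
  counts
}

#' Shannon diversity index (natural log)
#'
#' @param counts Non-negative category counts (e.g. strains per
#'   genospecies); zero categories are ignored.
#' @return H = -sum p_i log p_i.
#' @export
#'
#' @examples
#' shannon_index(c(26, 8, 2, 3))
shannon_index <- function(counts) {
  counts <- check_counts(counts)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Gini-Simpson diversity index
#'
#' @inheritParams shannon_index
#' @return D = 1 - sum p_i^2.
#' @export
simpson_index <- function(counts) {
  counts <- check_counts(counts)
  unname(vegan::diversity(counts, index = "simpson"))
}

#' Mean pairwise distance within a subset of strains
#'
#' Arithmetic mean of the off-diagonal distances among the given strains;
#' the per-source "nucleotide" and "haplotype" diversity entries of the
#' report are this statistic applied to the corresponding matrices.
#'
#' @param dm A [dist_matrix()].
#' @param subset Strain ids (default: all strains in `dm`); at least 2.
#' @return Mean off-diagonal distance.
#' @export
mean_pairwise_distance <- function(dm, subset = rownames(dm)) {
  if (length(subset) < 2L) {
    stop_rg("subset must contain at least 2 strains",
            class = "rhizogeo_input_error")
  }
  sub <- dist_subset(dm, subset)
  mean(lower_vec(unclass(sub)))
}

#' Bootstrap comparison of diversity indices against a reference population
#'
#' Draws `B` samples of size `n_draw` with replacement from the reference
#' labels, computes Shannon and Simpson indices for each, and reports
#' permutation-style p-values with the +1 correction. The default is the
#' lower tail (is the observed sample *less* diverse than the reference?);
#' a two-sided alternative is available.
#'
#' @param observed_labels Category labels of the observed sample.
#' @param reference_labels Category labels of the reference population.
#' @param n_draw Resample size (default 39).
#' @param B Number of resamples (default 10000).
#' @param seed Optional integer seed; recorded in the output.
#' @param alternative `"less"` (default) or `"two.sided"`.
#' @return Object of class `bootstrap_comparison`: observed `H` and `D`,
#'   the resampled values, `p_H`, `p_D`, `n_draw`, `B`, `seed`.
#' @export
bootstrap_diversity_comparison <- function(observed_labels, reference_labels,
                                           n_draw = 39, B = 10000,
                                           seed = NULL,
                                           alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(reference_labels)) {
    stop_rg("reference population is empty", class = "rhizogeo_input_error")
  }
  if (n_draw < 1L || B < 1L) {
    stop_rg("n_draw and B must be >= 1", class = "rhizogeo_input_error")
  }
  obs_counts <- as.integer(table(observed_labels))
  H_obs <- shannon_index(obs_counts)
  D_obs <- simpson_index(obs_counts)
  ref <- match(reference_labels, unique(reference_labels))
  K <- max(ref)
  draws <- with_seed(seed,
    matrix(sample(ref, n_draw * B, replace = TRUE), nrow = B))
  H_boot <- numeric(B)
  D_boot <- numeric(B)
  for (b in seq_len(B)) {
    cts <- tabulate(draws[b, ], nbins = K)
    p <- cts[cts > 0] / n_draw
    H_boot[b] <- -sum(p * log(p))
    D_boot[b] <- 1 - sum(p^2)
  }
  p_tail <- function(boot, obs) {
    lower <- (1 + sum(boot <= obs)) / (B + 1)
    if (alternative == "less") return(lower)
    upper <- (1 + sum(boot >= obs)) / (B + 1)
    min(1, 2 * min(lower, upper))
  }
  structure(list(H_observed = H_obs, D_observed = D_obs,
                 H_boot = H_boot, D_boot = D_boot,
                 p_H = p_tail(H_boot, H_obs), p_D = p_tail(D_boot, D_obs),
                 n_draw = n_draw, B = B, seed = seed,
                 alternative = alternative),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat("<bootstrap_comparison> B=", x$B, ", n_draw=", x$n_draw,
      ", tail=", x$alternative, "\n", sep = "")
  cat(sprintf("  Shannon: observed %.4f, p = %.4g\n", x$H_observed, x$p_H))
  cat(sprintf("  Simpson: observed %.4f, p = %.4g\n", x$D_observed, x$p_D))
  invisible(x)
}

#' Per-source diversity report
#'
#' One row per source of strains: sample size, mean pairwise nucleotide and
#' haplotype distance, and Shannon/Simpson indices of the genospecies
#' composition.
#'
#' @param sources Named list mapping a source label to a vector of strain
#'   ids.
#' @param nucleotide_dm Nucleotide-level [dist_matrix()].
#' @param haplotype_dm Haplotype-level [dist_matrix()].
#' @param genospecies Named character vector strain -> genospecies label.
#' @return data.frame with columns source, n, nucleotides, haplotypes,
#'   shannon, simpson.
#' @export
diversity_report <- function(sources, nucleotide_dm, haplotype_dm,
                             genospecies) {
  rows <- lapply(names(sources), function(src) {
    ids <- sources[[src]]
    counts <- as.integer(table(genospecies[ids]))
    data.frame(source = src, n = length(ids),
               nucleotides = mean_pairwise_distance(nucleotide_dm, ids),
               haplotypes = mean_pairwise_distance(haplotype_dm, ids),
               shannon = shannon_index(counts),
               simpson = simpson_index(counts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
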