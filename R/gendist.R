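# Pairwise genetic, geographic and scalar distance matrices.
#
# Nucleotide-level distances use pairwise deletion by default: a site
# enters the comparison of a pair only when both sequences carry an
# unambiguous base (A/C/G/T) there. Complete deletion (drop any column with
# a gap/ambiguity anywhere) is available via `deletion = "complete"`.

# Shared counting machinery: number of comparable sites, matches, and
# transition counts for every pair, via indicator cross-products.
pair_counts <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  code <- encode_acgt(aln$seqs)
  if (deletion == "complete") {
    keep <- colSums(is.na(code)) == 0L
    code <- code[, keep, drop = FALSE]
  }
  if (ncol(code) == 0L) {
    stop_rg("no comparable columns remain after deletion",
            class = "rhizogeo_undefined_distance_error")
  }
  ok <- !is.na(code)
  storage.mode(ok) <- "double"
  ind <- base_indicators(code)
  comp <- tcrossprod(ok)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  # transition site counts: A<->G (purine), C<->T (pyrimidine)
  ag <- tcrossprod(ind[[1]], ind[[3]])
  ag <- ag + t(ag)
  ct <- tcrossprod(ind[[2]], ind[[4]])
  ct <- ct + t(ct)
  freqs <- tabulate(code[ok > 0], nbins = 4L)
  freqs <- freqs / sum(freqs)
  names(freqs) <- UNAMBIGUOUS
  list(comp = comp, matches = matches, ag = ag, ct = ct, freqs = freqs,
       labels = rownames(aln$seqs))
}

check_comparable <- function(pc) {
  bad <- which(pc$comp == 0 & upper.tri(pc$comp), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_rg("no comparable sites for pair(s): ",
            paste(pc$labels[bad[1, 1]], pc$labels[bad[1, 2]], sep = " / "),
            class = "rhizogeo_undefined_distance_error")
  }
}

#' p-distance matrix (pairwise proportion of differing sites)
#'
#' For each pair of strains, the proportion of differing sites among the
#' columns where both sequences have an unambiguous base.
#'
#' @param aln A [locus_alignment()] (single locus or concatenated).
#' @param deletion `"pairwise"` (default) or `"complete"` site deletion.
#' @return A [dist_matrix()] with `level = "nucleotide"`.
#' @export
#'
#' @examples
#' aln <- locus_alignment(c(a = "ACGTAA", b = "ACGTCC"), "toy")
#' p_distance_matrix(aln)   # 2/6
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (n_strains(aln) < 2L) {
    stop_rg("need at least 2 strains", class = "rhizogeo_input_error")
  }
  pc <- pair_counts(aln, deletion)
  check_comparable(pc)
  d <- (pc$comp - pc$matches) / pc$comp
  diag(d) <- 0
  dist_matrix(d, pc$labels, "nucleotide")
}

#' Tamura-Nei (1993) distance matrix
#'
#' Closed-form TN93 distance computed per pair from the purine-transition
#' proportion P1, pyrimidine-transition proportion P2 and transversion
#' proportion Q, with base frequencies pooled over the whole alignment
#' (more stable than per-pair estimates at these sample sizes). An optional
#' gamma rate-heterogeneity correction with user-supplied shape is
#' available; the default is the plain TN93 distance.
#'
#' Pairs whose corrective logarithms have non-positive arguments
#' (saturation) are returned as `NA` and listed in the
#' `"undefined_pairs"` attribute with a warning.
#'
#' @param aln A [locus_alignment()].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @param gamma_shape Optional gamma shape alpha for among-site rate
#'   variation; `NULL` (default) applies no rate correction.
#' @return A [dist_matrix()] with `level = "nucleotide_tn93"`.
#' @export
tn93_distance_matrix <- function(aln, deletion = c("pairwise", "complete"),
                                 gamma_shape = NULL) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (n_strains(aln) < 2L) {
    stop_rg("need at least 2 strains", class = "rhizogeo_input_error")
  }
  pc <- pair_counts(aln, deletion)
  check_comparable(pc)
  f <- pc$freqs
  if (any(f[c("A", "G")] == 0) || any(f[c("C", "T")] == 0)) {
    stop_rg("base frequencies not estimable (a base is absent)",
            class = "rhizogeo_input_error")
  }
  gA <- f["A"]; gC <- f["C"]; gG <- f["G"]; gT <- f["T"]
  gR <- gA + gG; gY <- gC + gT
  P1 <- pc$ag / pc$comp
  P2 <- pc$ct / pc$comp
  Q <- (pc$comp - pc$matches - pc$ag - pc$ct) / pc$comp
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  bad <- (w1 <= 0) | (w2 <= 0) | (w3 <= 0)
  w1[bad] <- w2[bad] <- w3[bad] <- NA_real_
  if (is.null(gamma_shape)) {
    d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  } else {
    a <- gamma_shape
    stopifnot(is.numeric(a), a > 0)
    d <- a * (k1 * (w1^(-1 / a) - 1) + k2 * (w2^(-1 / a) - 1) +
                k3 * (w3^(-1 / a) - 1))
  }
  diag(d) <- 0
  if (any(bad[upper.tri(bad)])) {
    idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
    pairs <- paste(pc$labels[idx[, 1]], pc$labels[idx[, 2]], sep = "/")
    warning("TN93 saturation: distance undefined for pair(s) ",
            paste(pairs, collapse = ", "))
  }
  out <- dist_matrix(d, pc$labels, "nucleotide_tn93")
  attr(out, "undefined_pairs") <- if (any(bad[upper.tri(bad)])) {
    idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
    cbind(pc$labels[idx[, 1]], pc$labels[idx[, 2]])
  } else NULL
  attr(out, "base_freqs") <- f
  out
}

#' Call per-locus haplotypes
#'
#' Within each locus, strains with byte-identical sequences (after
#' uppercasing; gaps count as characters) share one haplotype. Labels are
#' dense integers in order of first appearance.
#'
#' @param mla A `multilocus_alignment` from [concatenate_loci()].
#' @return Object of class `haplotype_table`: list with `haplotypes`
#'   (named list, per locus a named integer vector strain -> label) and
#'   `n_haplotypes` per locus.
#' @export
call_haplotypes <- function(mla) {
  stopifnot(inherits(mla, "multilocus_alignment"))
  haps <- lapply(mla$loci, function(a) {
    s <- apply(a$seqs, 1, paste, collapse = "")
    h <- match(s, unique(s))
    names(h) <- rownames(a$seqs)
    h
  })
  structure(list(haplotypes = haps,
                 n_haplotypes = vapply(haps, function(h) length(unique(h)),
                                       integer(1))),
            class = "haplotype_table")
}

#' Allele-sharing distance across loci
#'
#' `d(i, j)` is the fraction of loci at which strains i and j carry
#' different haplotypes; values lie on the grid 0, 1/L, ..., 1.
#'
#' @param ht A `haplotype_table` from [call_haplotypes()].
#' @return A [dist_matrix()] with `level = "haplotype"`.
#' @export
allele_sharing_distance <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  haps <- ht$haplotypes
  if (!length(haps)) {
    stop_rg("haplotype table has no loci", class = "rhizogeo_input_error")
  }
  ids <- names(haps[[1]])
  for (h in haps) {
    if (!identical(names(h), ids)) {
      stop_rg("strain sets differ across loci in haplotype table",
              class = "rhizogeo_missing_strain_error")
    }
  }
  L <- length(haps)
  d <- Reduce(`+`, lapply(haps, function(h) outer(h, h, `!=`) * 1)) / L
  dist_matrix(d, ids, "haplotype")
}

#' Binary genospecies distance
#'
#' 0 when two strains carry the same genospecies label, 1 otherwise.
#'
#' @param labels Named character vector strain -> genospecies, or a
#'   `genospecies_assignment` data.frame from [assign_genospecies()] (in
#'   which case `"unassigned"` strains are rejected).
#' @return A [dist_matrix()] with `level = "species"`.
#' @export
species_distance_matrix <- function(labels) {
  if (inherits(labels, "genospecies_assignment")) {
    labels <- stats::setNames(labels$genospecies, labels$strain)
  }
  if (is.null(names(labels))) {
    stop_rg("labels must be named by strain", class = "rhizogeo_input_error")
  }
  bad <- names(labels)[is.na(labels) | labels == "unassigned"]
  if (length(bad)) {
    stop_rg("unlabelled strains: ", paste(bad, collapse = ", "),
            class = "rhizogeo_input_error")
  }
  d <- outer(labels, labels, `!=`) * 1
  dist_matrix(d, names(labels), "species")
}

#' Great-circle geographic distance matrix
#'
#' Haversine distance in kilometres on a sphere of IUGG mean radius
#' 6371.0088 km.
#'
#' @param meta data.frame with columns `strain`, `latitude`, `longitude`
#'   (decimal degrees).
#' @return A [dist_matrix()] with `level = "geographic_km"`.
#' @export
geographic_distance_matrix <- function(meta) {
  req <- c("strain", "latitude", "longitude")
  if (!all(req %in% names(meta))) {
    stop_rg("metadata must have columns ", paste(req, collapse = ", "),
            class = "rhizogeo_input_error")
  }
  miss <- meta$strain[!is.finite(meta$latitude) | !is.finite(meta$longitude)]
  if (length(miss)) {
    stop_rg("missing coordinates for: ", paste(miss, collapse = ", "),
            class = "rhizogeo_input_error")
  }
  if (any(abs(meta$latitude) > 90) || any(abs(meta$longitude) > 180)) {
    stop_rg("coordinates out of range", class = "rhizogeo_input_error")
  }
  pts <- cbind(meta$longitude, meta$latitude)
  d <- geosphere::distm(pts, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371.0088))
  dist_matrix(d, meta$strain, "geographic_km")
}

#' Absolute-difference distance matrix for a per-strain scalar
#'
#' Used for elevation (m) and shoot-dry-weight matrices in the Mantel
#' analyses.
#'
#' @param values Named numeric vector, one finite value per strain.
#' @param level `"elevation_m"` (default) or `"trait"`.
#' @return A [dist_matrix()].
#' @export
scalar_distance_matrix <- function(values, level = c("elevation_m", "trait")) {
  level <- match.arg(level)
  if (is.null(names(values))) {
    stop_rg("values must be named by strain", class = "rhizogeo_input_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_rg("missing value for: ",
            paste(names(values)[!is.finite(values)], collapse = ", "),
            class = "rhizogeo_input_error")
  }
  d <- abs(outer(values, values, `-`))
  dist_matrix(d, names(values), level)
}
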