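#' Assign strains to genospecies by similarity to a reference panel
#'
#' Each query strain receives the genospecies label of its nearest
#' reference by average nucleotide identity (ANI = 1 - p-distance over the
#' columns where both sequences are unambiguous) on the shared alignment,
#' provided that similarity reaches `min_similarity`; otherwise the strain
#' is reported as `"unassigned"`. Ties are broken by the first reference in
#' input order, with a warning.
#'
#' The default threshold of 0.95 reflects typical within-genospecies ANI
#' floors in housekeeping-gene MLSA of *Mesorhizobium*.
#'
#' @param queries A [locus_alignment()] (typically the concatenated
#'   housekeeping alignment) of query strains, aligned to the same columns
#'   as `refs`.
#' @param refs A [locus_alignment()] of reference strains.
#' @param ref_labels Named character vector mapping reference ids to
#'   genospecies labels.
#' @param min_similarity Minimum ANI for assignment (fraction, default 0.95).
#' @return data.frame of class `genospecies_assignment` with columns
#'   `strain`, `genospecies`, `nearest_ref`, `similarity`.
#' @export
assign_genospecies <- function(queries, refs, ref_labels,
                               min_similarity = 0.95) {
  stopifnot(inherits(queries, "locus_alignment"),
            inherits(refs, "locus_alignment"))
  if (n_strains(refs) < 1L) {
    stop_rg("no reference strains", class = "rhizogeo_input_error")
  }
  if (alignment_length(queries) != alignment_length(refs)) {
    stop_rg("queries and references are not aligned to the same columns",
            class = "rhizogeo_input_error")
  }
  if (is.null(names(ref_labels)) ||
      !all(strain_ids(refs) %in% names(ref_labels))) {
    stop_rg("every reference needs a genospecies label",
            class = "rhizogeo_input_error")
  }
  cq <- encode_acgt(queries$seqs)
  cr <- encode_acgt(refs$seqs)
  okq <- !is.na(cq); storage.mode(okq) <- "double"
  okr <- !is.na(cr); storage.mode(okr) <- "double"
  comp <- okq %*% t(okr)
  matches <- matrix(0, nrow(cq), nrow(cr))
  for (b in 1:4) {
    iq <- (cq == b); iq[is.na(iq)] <- FALSE; storage.mode(iq) <- "double"
    ir <- (cr == b); ir[is.na(ir)] <- FALSE; storage.mode(ir) <- "double"
    matches <- matches + iq %*% t(ir)
  }
  if (any(comp == 0)) {
    stop_rg("query/reference pair with no comparable sites",
            class = "rhizogeo_undefined_distance_error")
  }
  sim <- matches / comp
  best <- integer(nrow(sim))
  for (i in seq_len(nrow(sim))) {
    m <- max(sim[i, ])
    hits <- which(sim[i, ] >= m - 1e-12)
    if (length(hits) > 1L) {
      warning("ANI tie for strain ", strain_ids(queries)[i],
              "; keeping first reference in input order (",
              strain_ids(refs)[hits[1]], ")")
    }
    best[i] <- hits[1]
  }
  best_sim <- sim[cbind(seq_len(nrow(sim)), best)]
  assigned <- best_sim >= min_similarity
  out <- data.frame(
    strain = strain_ids(queries),
    genospecies = ifelse(assigned,
                         unname(ref_labels[strain_ids(refs)[best]]),
                         "unassigned"),
    nearest_ref = strain_ids(refs)[best],
    similarity = best_sim,
    stringsAsFactors = FALSE)
  class(out) <- c("genospecies_assignment", "data.frame")
  out
}

#' Chi-squared test of composition differences between samples
#'
#' Pearson chi-squared test on a samples x genospecies contingency table,
#' without continuity correction. A warning (not an error) is issued when
#' any expected count falls below 5.
#'
#' @param table Matrix or table of non-negative counts with at least two
#'   rows (samples) and two columns (genospecies/clades).
#' @return List with `statistic`, `df`, `p.value` and the `expected` counts.
#' @export
composition_chisq <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_rg("need at least 2 samples and 2 categories",
            class = "rhizogeo_input_error")
  }
  if (any(m < 0) || any(m != round(m))) {
    stop_rg("counts must be non-negative integers",
            class = "rhizogeo_input_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_rg("zero row or column in contingency table",
            class = "rhizogeo_input_error")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(res$expected < 5)) {
    warning("expected count < 5 in ", sum(res$expected < 5),
            " cell(s); chi-squared approximation may be poor")
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, expected = res$expected)
}

#' Write a genospecies assignment as TSV
#'
#' @param assign A `genospecies_assignment` from [assign_genospecies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment_tsv <- function(assign, path) {
  utils::write.table(assign, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
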