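#' Labelled symmetric distance matrix
#'
#' Thin wrapper around a base matrix that enforces the invariants every
#' distance matrix in the pipeline must satisfy: symmetry, a zero diagonal,
#' non-negative values and unique labels. `NA` entries are permitted only
#' to flag pairs whose distance is undefined (e.g. TN93 saturation).
#'
#' @param values Square numeric matrix.
#' @param labels Strain ids (defaults to rownames of `values`).
#' @param level One of `"nucleotide"`, `"nucleotide_tn93"`, `"haplotype"`,
#'   `"species"`, `"geographic_km"`, `"elevation_m"`, `"trait"`.
#' @return A matrix of class `dist_matrix` with attribute `level`.
#' @export
dist_matrix <- function(values, labels = rownames(values), level) {
  level <- match.arg(level, c("nucleotide", "nucleotide_tn93", "haplotype",
                              "species", "geographic_km", "elevation_m",
                              "trait"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop_rg("distance matrix must be square", class = "rhizogeo_input_error")
  }
  if (is.null(labels)) {
    stop_rg("distance matrix needs strain labels", class = "rhizogeo_input_error")
  }
  if (anyDuplicated(labels)) {
    stop_rg("duplicate labels in distance matrix", class = "rhizogeo_input_error")
  }
  dimnames(values) <- list(labels, labels)
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop_rg("distance matrix is not symmetric", class = "rhizogeo_input_error")
  }
  if (any(abs(diag(values)) > 1e-12, na.rm = TRUE)) {
    stop_rg("distance matrix diagonal must be zero", class = "rhizogeo_input_error")
  }
  if (any(values < -1e-12, na.rm = TRUE)) {
    stop_rg("negative distances", class = "rhizogeo_input_error")
  }
  diag(values) <- 0
  values[values < 0] <- 0
  structure(values, class = c("dist_matrix", "matrix", "array"), level = level)
}

#' @rdname dist_matrix
#' @param x A `dist_matrix`.
#' @export
dist_level <- function(x) attr(x, "level")

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix> level=", attr(x, "level"), ", ", nrow(x), " strains\n",
      sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# Strict lower-triangle vector, the vectorization used by Mantel statistics.
lower_vec <- function(m) m[lower.tri(m)]

#' Subset a distance matrix to a set of strains
#'
#' @param dm A [dist_matrix()].
#' @param ids Strain ids to keep (order preserved as given).
#' @return A `dist_matrix` over `ids`.
#' @export
dist_subset <- function(dm, ids) {
  missing <- setdiff(ids, rownames(dm))
  if (length(missing)) {
    stop_rg("strains absent from distance matrix: ",
            paste(missing, collapse = ", "), class = "rhizogeo_input_error")
  }
  dist_matrix(unclass(dm)[ids, ids, drop = FALSE], ids, attr(dm, "level"))
}

#' Write a distance matrix as square TSV
#'
#' @param dm A [dist_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(strain = rownames(dm), unclass(dm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in lower-triangle PHYLIP style
#'
#' @param dm A [dist_matrix()].
#' @param path Output path.
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(dm, path, digits = 6) {
  n <- nrow(dm)
  lines <- character(n + 1L)
  lines[1] <- as.character(n)
  for (i in seq_len(n)) {
    row <- if (i == 1L) "" else
      paste(formatC(unclass(dm)[i, seq_len(i - 1L)], digits = digits,
                    format = "g"), collapse = "\t")
    lines[i + 1L] <- paste0(rownames(dm)[i],
                            if (nzchar(row)) "\t" else "", row)
  }
  writeLines(lines, path)
  invisible(path)
}
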