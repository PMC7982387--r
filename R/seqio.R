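#' Construct a single-locus alignment
#'
#' A `locus_alignment` holds equal-length, uppercase nucleotide sequences for
#' a set of uniquely identified strains. Sequences may contain IUPAC
#' ambiguity codes and the gap character `-`; anything else is rejected.
#'
#' @param sequences Named character vector of aligned sequences (one string
#'   per strain; names are strain ids), or a character matrix with one row
#'   per strain and one column per alignment position.
#' @param locus_name Label for the locus (e.g. `"recA"`).
#'
#' @return An object of class `locus_alignment`: a list with elements
#'   `locus`, `seqs` (character matrix, strains x positions), and implied
#'   accessors `n_strains()`/`alignment_length()`.
#' @export
#'
#' @examples
#' aln <- locus_alignment(c(s1 = "ACGT", s2 = "ACGA"), "toy")
#' alignment_length(aln)
locus_alignment <- function(sequences, locus_name = "locus") {
  if (is.matrix(sequences)) {
    m <- sequences
    if (is.null(rownames(m))) {
      stop_rg("sequence matrix must have strain ids as rownames",
              class = "rhizogeo_input_error")
    }
  } else {
    if (is.null(names(sequences)) || anyNA(names(sequences)) ||
        any(names(sequences) == "")) {
      stop_rg("sequences must be named by strain id",
              class = "rhizogeo_input_error")
    }
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      stop_rg("unequal sequence lengths (", paste(unique(lens), collapse = ", "),
              "): input is not an alignment", class = "rhizogeo_alignment_error")
    }
    m <- do.call(rbind, strsplit(toupper(unname(sequences)), "", fixed = TRUE))
    rownames(m) <- names(sequences)
  }
  m[] <- toupper(m)
  if (anyDuplicated(rownames(m))) {
    stop_rg("duplicate strain ids: ",
            paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
            class = "rhizogeo_input_error")
  }
  if (ncol(m) < 1L) {
    stop_rg("alignment has zero columns", class = "rhizogeo_alignment_error")
  }
  bad <- setdiff(unique(as.vector(m)), IUPAC_CHARS)
  if (length(bad)) {
    stop_rg("non-IUPAC characters in alignment: ",
            paste(bad, collapse = " "), class = "rhizogeo_input_error")
  }
  structure(list(locus = locus_name, seqs = m), class = "locus_alignment")
}

#' @rdname locus_alignment
#' @param x A `locus_alignment`.
#' @export
alignment_length <- function(x) ncol(x$seqs)

#' @rdname locus_alignment
#' @export
n_strains <- function(x) nrow(x$seqs)

#' @rdname locus_alignment
#' @export
strain_ids <- function(x) rownames(x$seqs)

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus, ": ", n_strains(x), " strains x ",
      alignment_length(x), " bp\n", sep = "")
  invisible(x)
}

#' Read a pre-aligned FASTA file as a locus alignment
#'
#' The description line up to the first whitespace is taken as the strain id.
#' Sequences are uppercased; ragged (unequal-length) records, duplicate ids
#' and non-IUPAC characters are rejected.
#'
#' @param path Path to a FASTA file with at least two records.
#' @param locus_name Label for the locus; defaults to the file name stem.
#' @return A [locus_alignment()].
#' @export
read_fasta_alignment <- function(path, locus_name = NULL) {
  if (!file.exists(path)) {
    stop_rg("file not found: ", path, class = "rhizogeo_input_error")
  }
  if (is.null(locus_name)) {
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  }
  recs <- ape::read.FASTA(path)
  if (length(recs) < 2L) {
    stop_rg("FASTA must contain at least 2 records: ", path,
            class = "rhizogeo_input_error")
  }
  seqs <- vapply(as.character(recs), paste, character(1), collapse = "")
  names(seqs) <- sub("\\s.*$", "", names(recs))
  locus_alignment(seqs, locus_name)
}

#' Write a locus alignment as FASTA
#'
#' @param aln A [locus_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$seqs, 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Concatenate per-locus alignments into a multilocus alignment
#'
#' All loci must contain the identical strain set; a strain present in only
#' some loci is an error rather than a silent intersection, so any
#' subsetting is an explicit caller decision. Strain order is canonicalized
#' by sorting ids, and columns are joined in the given locus order.
#'
#' @param loci List of [locus_alignment()] objects sharing one strain set.
#' @return An object of class `multilocus_alignment`: list with `loci` (the
#'   reordered per-locus alignments) and `concatenated` (a single
#'   `locus_alignment` whose length is the sum of the locus lengths).
#' @export
concatenate_loci <- function(loci) {
  if (!length(loci)) {
    stop_rg("no loci supplied", class = "rhizogeo_input_error")
  }
  if (!all(vapply(loci, inherits, logical(1), "locus_alignment"))) {
    stop_rg("all elements must be locus_alignment objects",
            class = "rhizogeo_input_error")
  }
  ids <- lapply(loci, strain_ids)
  common <- sort(ids[[1]])
  for (k in seq_along(loci)) {
    if (!setequal(ids[[k]], ids[[1]]) || length(ids[[k]]) != length(ids[[1]])) {
      missing <- c(setdiff(ids[[1]], ids[[k]]), setdiff(ids[[k]], ids[[1]]))
      stop_rg("strain sets differ between loci '", loci[[1]]$locus, "' and '",
              loci[[k]]$locus, "'; offending strains: ",
              paste(missing, collapse = ", "),
              class = "rhizogeo_missing_strain_error")
    }
  }
  loci <- lapply(loci, function(a) {
    a$seqs <- a$seqs[common, , drop = FALSE]
    a
  })
  names(loci) <- vapply(loci, `[[`, character(1), "locus")
  conc <- locus_alignment(do.call(cbind, lapply(loci, `[[`, "seqs")),
                          paste(names(loci), collapse = "+"))
  structure(list(loci = loci, concatenated = conc),
            class = "multilocus_alignment")
}

#' @export
print.multilocus_alignment <- function(x, ...) {
  cat("<multilocus_alignment> ", length(x$loci), " loci (",
      paste(names(x$loci), collapse = ", "), "), ",
      n_strains(x$concatenated), " strains, ",
      alignment_length(x$concatenated), " bp concatenated\n", sep = "")
  invisible(x)
}

#' Classify alignment columns into conserved/variable/PI/singleton sites
#'
#' Columns containing any gap or ambiguity code are excluded from the
#' conserved/variable tallies and counted in `excluded`. Among the fully
#' unambiguous columns: one observed state is conserved; a variable column
#' is parsimony-informative when at least two states each occur in at least
#' two sequences, otherwise it is a singleton site. By construction
#' `variable = parsimony_informative + singletons` and
#' `conserved + variable + excluded = length`.
#'
#' @param aln A [locus_alignment()].
#' @return Object of class `site_classification` with counts `conserved`,
#'   `variable`, `parsimony_informative`, `singletons`, `excluded`, plus
#'   `locus`, `n_sequences` and `length`.
#' @export
#'
#' @examples
#' aln <- locus_alignment(
#'   c(a = "ACGTAA", b = "ACGTAC", c = "ACGTCC", d = "ACGACC"), "toy")
#' classify_sites(aln)
classify_sites <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  m <- aln$seqs
  amb <- !(m %in% UNAMBIGUOUS)
  dim(amb) <- dim(m)
  excluded_col <- colSums(amb) > 0L
  conserved <- variable <- pi_sites <- singletons <- 0L
  for (j in which(!excluded_col)) {
    counts <- tabulate(match(m[, j], UNAMBIGUOUS), nbins = 4L)
    k <- sum(counts > 0L)
    if (k == 1L) {
      conserved <- conserved + 1L
    } else {
      variable <- variable + 1L
      if (sum(counts >= 2L) >= 2L) {
        pi_sites <- pi_sites + 1L
      } else {
        singletons <- singletons + 1L
      }
    }
  }
  structure(list(locus = aln$locus,
                 n_sequences = n_strains(aln),
                 length = alignment_length(aln),
                 conserved = conserved,
                 variable = variable,
                 parsimony_informative = pi_sites,
                 singletons = singletons,
                 excluded = sum(excluded_col)),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("<site_classification> ", x$locus, " (", x$n_sequences, " seqs, ",
      x$length, " bp)\n", sep = "")
  cat(sprintf("  conserved %d | variable %d (PI %d + singleton %d) | excluded %d\n",
              x$conserved, x$variable, x$parsimony_informative,
              x$singletons, x$excluded))
  invisible(x)
}

#' Tabulate site statistics for several alignments
#'
#' @param alignments List of [locus_alignment()] objects (typically the
#'   per-locus alignments plus the concatenation).
#' @return data.frame with one row per alignment: locus, n_sequences,
#'   length, conserved, variable, parsimony_informative, singletons,
#'   excluded.
#' @export
site_stats_table <- function(alignments) {
  rows <- lapply(alignments, function(a) {
    cl <- classify_sites(a)
    data.frame(locus = cl$locus, n_sequences = cl$n_sequences,
               length = cl$length, conserved = cl$conserved,
               variable = cl$variable,
               parsimony_informative = cl$parsimony_informative,
               singletons = cl$singletons, excluded = cl$excluded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a site-statistics table as TSV
#'
#' @param stats data.frame from [site_stats_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
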