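# Internal helpers shared across modules.

# IUPAC nucleotide alphabet accepted in alignments; '-' is the gap character.
IUPAC_CHARS <- c("A", "C", "G", "T",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "-")

UNAMBIGUOUS <- c("A", "C", "G", "T")

#' @keywords internal
#' @noRd
stop_rg <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "rhizogeo_error")))
}

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's RNG afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Encode a character alignment matrix as integers 1..4 (A,C,G,T), NA for
# gaps and ambiguity codes.
encode_acgt <- function(m) {
  out <- match(m, UNAMBIGUOUS)
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

# One 0/1 indicator matrix per unambiguous base.
base_indicators <- function(code) {
  lapply(1:4, function(b) {
    I <- (code == b)
    I[is.na(I)] <- FALSE
    storage.mode(I) <- "double"
    I
  })
}
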