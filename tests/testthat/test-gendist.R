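# Distance matrices: p-distance, TN93, haplotypes, species, geography.

test_that("p-distance matches hand counts, with pairwise deletion", {
  aln <- locus_alignment(c(a = "ACGTAA", b = "ACGTAA"), "same")
  expect_equal(unname(p_distance_matrix(aln)["a", "b"]), 0)

  aln <- locus_alignment(c(a = "ACGTAA", b = "ACGTCC"), "two")
  expect_equal(unname(p_distance_matrix(aln)["a", "b"]), 2 / 6)

  aln <- locus_alignment(c(a = "AC-TAA", b = "ACGTAC"), "gap")
  expect_equal(unname(p_distance_matrix(aln)["a", "b"]), 1 / 5)

  # complete deletion drops the gapped column for every pair
  aln <- locus_alignment(c(a = "AC-TAA", b = "ACGTAC", c = "ACGTAA"), "gap3")
  d <- p_distance_matrix(aln, deletion = "complete")
  expect_equal(unname(d["b", "c"]), 1 / 5)
})

test_that("a pair with no comparable columns is an error naming the pair", {
  aln <- locus_alignment(c(a = "AA--", b = "--TT", c = "AATT"), "disjoint")
  expect_error(p_distance_matrix(aln), "a / b",
               class = "rhizogeo_undefined_distance_error")
})

test_that("p-distance and TN93 match independently coded oracles on random pairs", {
  set.seed(91)
  for (i in 1:100) {
    aln <- rand_alignment(2, 500, sub_rate = runif(1, 0.01, 0.15),
                          gap_rate = runif(1, 0, 0.03))
    a <- aln$seqs[1, ]; b <- aln$seqs[2, ]
    expect_equal(unname(p_distance_matrix(aln)[1, 2]),
                 oracle_p_distance(a, b), tolerance = 1e-12)
    tn <- suppressWarnings(tn93_distance_matrix(aln))
    freqs <- attr(tn, "base_freqs")
    expect_equal(unname(tn[1, 2]), oracle_tn93(a, b, freqs),
                 tolerance = 1e-12)
  }
})

test_that("TN93 reduces to Kimura-2-parameter under equal frequencies and equal transition rates", {
  # frequency-preserving construction: swap equal numbers of A<->G,
  # C<->T, and balanced transversion pairs
  base <- rep(c("A", "C", "G", "T"), each = 100)
  mut <- base
  k <- 15  # A<->G swaps
  mut[1:k] <- "G"; mut[201:(200 + k)] <- "A"
  mut[101:(100 + k)] <- "T"; mut[301:(300 + k)] <- "C"
  q <- 10  # balanced transversions A<->C
  mut[(k + 1):(k + q)] <- "C"; mut[(100 + k + 1):(100 + k + q)] <- "A"
  aln <- locus_alignment(rbind(s1 = base, s2 = mut), "k80")
  f <- attr(tn93_distance_matrix(aln), "base_freqs")
  expect_equal(unname(f), rep(0.25, 4))
  P <- 4 * k / 400   # total transition proportion: 2k A<->G plus 2k C<->T
  Q <- 2 * q / 400
  expect_equal(unname(tn93_distance_matrix(aln)[1, 2]), oracle_k80(P, Q),
               tolerance = 1e-10)
})

test_that("TN93 agrees with ape's implementation on a clean alignment", {
  set.seed(5)
  aln <- rand_alignment(12, 700, sub_rate = 0.05)
  tn <- tn93_distance_matrix(aln)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(aln$seqs)),
                                 model = "TN93", pairwise.deletion = TRUE))
  expect_equal(unclass(tn), ref[rownames(tn), colnames(tn)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("saturated pairs are flagged undefined with a warning", {
  base <- rep(c("A", "C", "G", "T"), each = 25)
  flip <- c(A = "C", C = "A", G = "T", T = "G")[base]  # all transversions
  aln <- locus_alignment(rbind(s1 = base, s2 = unname(flip)), "sat")
  expect_warning(tn <- tn93_distance_matrix(aln), "saturation")
  expect_true(is.na(tn["s1", "s2"]))
  expect_equal(nrow(attr(tn, "undefined_pairs")), 1)
})

test_that("p-distance never exceeds the TN93 distance", {
  set.seed(14)
  for (i in 1:20) {
    aln <- rand_alignment(6, 400, sub_rate = runif(1, 0.01, 0.1))
    p <- p_distance_matrix(aln)
    tn <- suppressWarnings(tn93_distance_matrix(aln))
    ok <- !is.na(unclass(tn))
    expect_true(all(unclass(p)[ok] <= unclass(tn)[ok] + 1e-12))
  }
})

test_that("haplotype calling collapses identical sequences per locus", {
  a <- locus_alignment(c(x = "AAAA", y = "AAAA", z = "AAAA"), "l1")
  b <- locus_alignment(c(x = "CCCC", y = "CCCC", z = "CCGG"), "l2")
  ht <- call_haplotypes(concatenate_loci(list(a, b)))
  expect_equal(unname(ht$n_haplotypes), c(1L, 2L))
  expect_equal(unname(ht$haplotypes$l2), c(1L, 1L, 2L))

  # gaps are characters: a gapped copy is a distinct haplotype
  g <- locus_alignment(c(x = "AC-T", y = "ACGT"), "g")
  expect_equal(call_haplotypes(concatenate_loci(list(g)))$n_haplotypes[["g"]], 2L)
})

test_that("allele-sharing distance averages haplotype mismatch across loci", {
  mk <- function(nm, s) locus_alignment(s, nm)
  loci <- list(
    mk("l1", c(x = "AA", y = "AA", z = "AA")),   # share
    mk("l2", c(x = "CC", y = "CC", z = "CG")),   # z differs
    mk("l3", c(x = "GG", y = "GT", z = "GG")))   # y differs
  d <- allele_sharing_distance(call_haplotypes(concatenate_loci(loci)))
  expect_equal(unname(d["x", "y"]), 1 / 3)
  expect_equal(unname(d["x", "z"]), 1 / 3)
  expect_equal(unname(d["y", "z"]), 2 / 3)
  expect_equal(dist_level(d), "haplotype")

  # single locus: 0/1 indicators
  d1 <- allele_sharing_distance(call_haplotypes(concatenate_loci(loci[2])))
  expect_true(all(unclass(d1) %in% c(0, 1)))
})

test_that("allele-sharing values lie on the grid {0, 1/L, ..., 1}", {
  set.seed(77)
  loci <- lapply(1:4, function(k)
    rand_alignment(10, 20, sub_rate = 0.2, locus = paste0("L", k)))
  ids <- strain_ids(loci[[1]])
  loci <- lapply(loci, function(a) { rownames(a$seqs) <- ids; a })
  d <- allele_sharing_distance(call_haplotypes(concatenate_loci(loci)))
  expect_true(all(abs(unclass(d) * 4 - round(unclass(d) * 4)) < 1e-12))
})

test_that("species distance is the 0/1 cluster indicator with the expected mean", {
  expect_true(all(unclass(species_distance_matrix(
    c(a = "I", b = "I", c = "I"))) == 0))

  d <- species_distance_matrix(c(a = "I", b = "I", c = "II"))
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 1)

  # four clusters 26/8/2/3: mean off-diagonal from the combinatorial count
  labels <- setNames(rep(c("I", "II", "III", "IV"), c(26, 8, 2, 3)),
                     sprintf("s%02d", 1:39))
  d <- species_distance_matrix(labels)
  same <- sum(c(26, 8, 2, 3) * (c(26, 8, 2, 3) - 1))
  expect_equal(mean(lower_vec(unclass(d))), 1 - same / (39 * 38),
               tolerance = 1e-12)
  expect_equal(mean(lower_vec(unclass(d))), 0.51822, tolerance = 1e-4)

  expect_error(species_distance_matrix(c(a = "I", b = NA)),
               class = "rhizogeo_input_error")
})

test_that("geographic distance matches haversine closed forms", {
  meta <- data.frame(strain = c("o", "n", "anti"),
                     latitude = c(0, 1, 0), longitude = c(0, 0, 180))
  d <- geographic_distance_matrix(meta)
  expect_equal(unname(d["o", "o"]), 0)
  expect_equal(unname(d["o", "n"]), 6371.0088 * pi / 180, tolerance = 1e-6)
  expect_equal(unname(d["o", "anti"]), pi * 6371.0088, tolerance = 1e-6)

  expect_error(geographic_distance_matrix(
    data.frame(strain = "x", latitude = NA, longitude = 3)),
    class = "rhizogeo_input_error")
  expect_error(geographic_distance_matrix(
    data.frame(strain = c("x", "y"), latitude = c(95, 0),
               longitude = c(0, 0))),
    class = "rhizogeo_input_error")
})

test_that("scalar distances are absolute differences", {
  expect_true(all(unclass(scalar_distance_matrix(
    c(a = 2, b = 2, c = 2))) == 0))
  d <- scalar_distance_matrix(c(a = 1800, b = 2400))
  expect_equal(unname(d["a", "b"]), 600)
  d <- scalar_distance_matrix(c(a = 1, b = 2, c = 4), level = "trait")
  expect_equal(sort(lower_vec(unclass(d))), c(1, 2, 3))
  expect_error(scalar_distance_matrix(c(a = 1, b = NA)),
               class = "rhizogeo_input_error")
})

test_that("geographic and scalar matrices satisfy the triangle inequality", {
  set.seed(44)
  for (i in 1:20) {
    meta <- data.frame(strain = sprintf("p%d", 1:8),
                       latitude = runif(8, -60, 60),
                       longitude = runif(8, -170, 170))
    d <- unclass(geographic_distance_matrix(meta))
    s <- unclass(scalar_distance_matrix(
      setNames(rnorm(8), meta$strain), "trait"))
    for (m in list(d, s)) {
      for (a in 1:8) for (b in 1:8) {
        expect_true(all(m[a, b] <= m[a, ] + m[, b] + 1e-9))
      }
    }
  }
})

test_that("every constructed matrix is symmetric with zero diagonal", {
  set.seed(3)
  aln <- rand_alignment(6, 200, sub_rate = 0.05)
  mats <- list(p_distance_matrix(aln),
               suppressWarnings(tn93_distance_matrix(aln)),
               scalar_distance_matrix(setNames(rnorm(4), letters[1:4]),
                                      "trait"))
  for (m in mats) {
    expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
    expect_true(all(diag(unclass(m)) == 0))
  }
})

test_that("distance matrices round-trip through the TSV writer", {
  set.seed(8)
  d <- rand_euclid_dm(5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(d, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(d), ignore_attr = TRUE,
               tolerance = 1e-12)
  path2 <- withr::local_tempfile(fileext = ".phy")
  write_distance_phylip(d, path2)
  expect_equal(readLines(path2)[1], "5")
})
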