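# Mantel tests, PCoA, coordinate regression, sliding-window decay.

test_that("Mantel r equals the independently computed triangle correlation", {
  set.seed(12)
  X <- rand_euclid_dm(4)
  Y <- rand_euclid_dm(4)
  m <- mantel_test(X, Y, n_perm = 99, seed = 1)
  expect_equal(m$r, oracle_pearson(lower_vec(unclass(X)),
                                   lower_vec(unclass(Y))),
               tolerance = 1e-12)
})

test_that("self-comparison gives r = 1 at the permutation p floor", {
  set.seed(13)
  X <- rand_euclid_dm(8)
  m <- mantel_test(X, X, n_perm = 199, seed = 3)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 200)
})

test_that("Mantel agrees with vegan and respects label checks", {
  set.seed(19)
  X <- rand_euclid_dm(10)
  Y <- rand_euclid_dm(10)
  m <- mantel_test(X, Y, n_perm = 99, seed = 2)
  vg <- vegan::mantel(as.dist(unclass(X)), as.dist(unclass(Y)),
                      permutations = 99)
  expect_equal(m$r, unname(vg$statistic), tolerance = 1e-12)

  Ybad <- dist_matrix(unclass(Y), sprintf("w%02d", 1:10), "trait")
  expect_error(mantel_test(X, Ybad), class = "rhizogeo_input_error")
  Z <- dist_matrix(matrix(1, 5, 5) - diag(5), letters[1:5], "trait")
  expect_error(mantel_test(Z, dist_subset(X, rownames(X)[1:5])),
               class = "rhizogeo_input_error")
})

test_that("Mantel r is invariant under a common relabeling of X and Y", {
  set.seed(23)
  X <- rand_euclid_dm(9)
  Y <- rand_euclid_dm(9)
  p <- sample(9)
  Xp <- dist_matrix(unclass(X)[p, p], rownames(X)[p], "trait")
  Yp <- dist_matrix(unclass(Y)[p, p], rownames(Y)[p], "trait")
  expect_equal(mantel_test(X, Y, n_perm = 9, seed = 1)$r,
               mantel_test(Xp, Yp, n_perm = 9, seed = 1)$r,
               tolerance = 1e-12)
})

test_that("partial Mantel reduces to simple Mantel for an orthogonal covariate", {
  set.seed(29)
  X <- rand_euclid_dm(12)
  Y <- rand_euclid_dm(12)
  x <- lower_vec(unclass(X)); y <- lower_vec(unclass(Y))
  # residualize a random triangle against [1, x, y]: exactly orthogonal
  z0 <- rnorm(length(x))
  z <- stats::resid(lm(z0 ~ x + y))
  z <- z - min(z)   # shift preserves correlations, keeps distances >= 0
  Zm <- matrix(0, 12, 12)
  Zm[lower.tri(Zm)] <- z
  Zm <- Zm + t(Zm)
  Z <- dist_matrix(Zm, rownames(X), "trait")
  pm <- partial_mantel_test(X, Y, Z, n_perm = 49, seed = 5)
  m <- mantel_test(X, Y, n_perm = 49, seed = 5)
  expect_equal(pm$r, m$r, tolerance = 1e-10)
})

test_that("a covariate identical to Y is rejected as degenerate", {
  set.seed(31)
  X <- rand_euclid_dm(8)
  Y <- rand_euclid_dm(8)
  expect_error(partial_mantel_test(X, Y, Y),
               class = "rhizogeo_input_error")
})

test_that("conditioning on the confounder shrinks the correlation", {
  set.seed(37)
  ratio <- replicate(100, {
    pts <- matrix(rnorm(10), 10, 1)
    Z <- as.matrix(dist(pts))
    X <- as.matrix(dist(pts + rnorm(10, sd = 0.4)))
    Y <- as.matrix(dist(pts + rnorm(10, sd = 0.4)))
    lab <- sprintf("v%02d", 1:10)
    Xd <- dist_matrix(X, lab, "trait")
    Yd <- dist_matrix(Y, lab, "trait")
    Zd <- dist_matrix(Z, lab, "trait")
    c(abs(partial_mantel_test(Xd, Yd, Zd, n_perm = 1, seed = 1)$r),
      abs(mantel_test(Xd, Yd, n_perm = 1, seed = 1)$r))
  })
  expect_lt(mean(ratio[1, ]), mean(ratio[2, ]))
})

test_that("PCoA reconstructs Euclidean-embeddable distances", {
  # collinear points 0-1-2: one positive axis, exact reconstruction
  D <- dist_matrix(as.matrix(dist(c(0, 1, 2))), c("p0", "p1", "p2"),
                   "trait")
  pc <- principal_coordinates(D)
  expect_equal(ncol(pc$coordinates), 1)
  expect_equal(as.matrix(dist(pc$coordinates)), unclass(D),
               ignore_attr = TRUE, tolerance = 1e-10)

  set.seed(41)
  pts <- matrix(rnorm(24), 12, 2)
  D <- dist_matrix(as.matrix(dist(pts)), sprintf("r%02d", 1:12), "trait")
  pc <- principal_coordinates(D)
  expect_equal(ncol(pc$coordinates), 2)
  expect_equal(as.matrix(dist(pc$coordinates[, 1:2])), unclass(D),
               ignore_attr = TRUE, tolerance = 1e-8)
  # eigenvalues nonincreasing; positive mass equals coordinate variance
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  expect_equal(sum(pc$eigenvalues[pc$eigenvalues > 0]),
               sum(scale(pc$coordinates, scale = FALSE)^2),
               tolerance = 1e-8)
})

test_that("PCoA agrees with cmdscale and reports negative eigenvalues", {
  set.seed(43)
  D <- rand_euclid_dm(9, dim = 3)
  pc <- principal_coordinates(D)
  ref <- cmdscale(as.dist(unclass(D)), k = 3, eig = TRUE)
  expect_equal(abs(pc$coordinates[, 1:3]), abs(ref$points),
               ignore_attr = TRUE, tolerance = 1e-8)

  # a regular simplex: all off-diagonal distances equal, all axes equal
  n <- 5
  D <- dist_matrix(matrix(1, n, n) - diag(n), letters[1:n], "trait")
  pc <- principal_coordinates(D)
  expect_equal(max(pc$eigenvalues[1:(n - 1)]) -
                 min(pc$eigenvalues[1:(n - 1)]), 0, tolerance = 1e-10)

  # non-Euclidean input: negative eigenvalues get reported
  m <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 2.8,
                1, 1, 2.8, 0), 4)
  D <- dist_matrix(m, letters[1:4], "trait")
  pc <- principal_coordinates(D)
  expect_gt(pc$n_negative, 0)
  expect_warning(principal_coordinates(D, n_axes = 4), "truncating")
})

test_that("coordinate regression recovers exact dependence and rejects collinearity", {
  set.seed(47)
  geo <- rand_euclid_dm(15)
  geo_pc <- principal_coordinates(geo)
  gen_pc <- geo_pc
  gen_pc$coordinates <- geo_pc$coordinates[, 1, drop = FALSE]
  colnames(gen_pc$coordinates) <- "Axis1"
  alt <- setNames(rnorm(15, 2000, 100), rownames(geo))
  tab <- suppressWarnings(
    pcoa_regression(gen_pc, geo_pc, alt, n_genetic_axes = 1))
  expect_equal(tab$r_squared[1], 1, tolerance = 1e-10)
  # geo1 absorbs the entire sum of squares; altitude explains nothing
  expect_lt(tab$sum_sq[tab$term == "altitude"],
            1e-12 * tab$sum_sq[tab$term == "geo1"])

  # collinear predictors: altitude an exact linear function of geo1
  alt_bad <- setNames(3 * geo_pc$coordinates[, 1] + 5, rownames(geo))
  expect_error(pcoa_regression(gen_pc, geo_pc, alt_bad),
               class = "rhizogeo_input_error")
})

test_that("the altitude association is driven by the elevation-restricted cluster", {
  # presence/absence contrast: the altitude term is detectable with the
  # high-elevation genospecies in the sample and disappears once those
  # strains are removed
  res <- vapply(1:100, function(s) {
    ds <- simulate_dataset(simulation_config(seed = 1000 + s))
    meta <- ds$metadata[order(ds$metadata$strain), ]
    nt <- p_distance_matrix(ds$mla$concatenated)
    alt_p <- function(ids) {
      m <- meta[meta$strain %in% ids, ]
      gen_pc <- principal_coordinates(dist_subset(nt, m$strain))
      geo_pc <- principal_coordinates(geographic_distance_matrix(m))
      alt <- setNames(m$elevation_m, m$strain)
      tab <- pcoa_regression(gen_pc, geo_pc, alt)
      min(tab$p_value[tab$term == "altitude"])
    }
    keep <- names(ds$truth$cluster)[ds$truth$cluster != "IV"]
    c(with_iv = alt_p(meta$strain), without_iv = alt_p(keep))
  }, numeric(2))
  expect_gt(mean(res["with_iv", ] < 0.01), 0.5)
  expect_lt(mean(res["without_iv", ] < 0.01), 0.15)
  expect_lt(median(res["with_iv", ]), median(res["without_iv", ]))
})

test_that("sliding windows cover the distance range and keep empty windows", {
  # two tight groups 100 km apart: middle windows are empty, not dropped
  meta <- data.frame(strain = sprintf("s%d", 1:6),
                     latitude = c(0, 0.01, 0.02, 0.9, 0.91, 0.92),
                     longitude = 0)
  geo <- geographic_distance_matrix(meta)
  set.seed(3)
  gen <- rand_euclid_dm(6, labels = meta$strain)
  hap <- rand_euclid_dm(6, labels = meta$strain)
  prof <- sliding_window_decay(gen, hap, geo, seed = 9)
  expect_true(any(prof$n_pairs == 0))
  expect_true(all(is.na(prof$nt_distance[prof$n_pairs == 0])))
  expect_true(all(diff(prof$midpoint) > 0))
  # every window's count matches a direct recount of eligible pairs
  gd <- lower_vec(unclass(geo))
  for (i in seq_len(nrow(prof))) {
    expect_equal(prof$n_pairs[i],
                 sum(gd >= prof$window_low[i] & gd < prof$window_high[i]))
  }
})

test_that("co-located strains yield a single window with a matching baseline", {
  meta <- data.frame(strain = sprintf("s%d", 1:5), latitude = 1,
                     longitude = 30)
  geo <- geographic_distance_matrix(meta)
  set.seed(6)
  gen <- rand_euclid_dm(5, labels = meta$strain)
  hap <- rand_euclid_dm(5, labels = meta$strain)
  prof <- sliding_window_decay(gen, hap, geo, seed = 2)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$window_low, 0)
  expect_equal(prof$n_pairs, 10)
  expect_false(is.na(prof$baseline_nt))
})

test_that("window profiles are bit-reproducible under a fixed seed", {
  ds <- simulate_dataset(simulation_config(seed = 33))
  meta <- ds$metadata[order(ds$metadata$strain), ]
  geo <- geographic_distance_matrix(meta)
  nt <- p_distance_matrix(ds$mla$concatenated)
  hap <- allele_sharing_distance(call_haplotypes(ds$mla))
  a <- sliding_window_decay(nt, hap, geo, seed = 17)
  b <- sliding_window_decay(nt, hap, geo, seed = 17)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # exhaustive mode averages all within-window pairs deterministically
  e1 <- sliding_window_decay(nt, hap, geo, seed = 1, exhaustive = TRUE)
  e2 <- sliding_window_decay(nt, hap, geo, seed = 99, exhaustive = TRUE)
  expect_identical(e1$nt_distance, e2$nt_distance)
})
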