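# Permutation-based spatial inference: Mantel and partial Mantel tests,
# principal coordinates, coordinate-on-coordinate regression, and the
# sliding-window distance-decay resampler.

check_conformable <- function(...) {
  mats <- list(...)
  labs <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(rownames(m), labs)) {
      stop_rg("distance matrices have mismatched labels",
              class = "rhizogeo_input_error")
    }
  }
  labs
}

triangle_or_stop <- function(m, what) {
  v <- lower_vec(unclass(m))
  if (anyNA(v)) {
    stop_rg(what, " matrix contains undefined distances",
            class = "rhizogeo_input_error")
  }
  if (stats::sd(v) == 0) {
    stop_rg(what, " matrix has zero variance in its lower triangle",
            class = "rhizogeo_input_error")
  }
  v
}

perm_pvalue <- function(r_obs, r_perm, tail) {
  n_perm <- length(r_perm)
  switch(tail,
         two.sided = (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-14)) / (n_perm + 1),
         greater = (1 + sum(r_perm >= r_obs - 1e-14)) / (n_perm + 1),
         less = (1 + sum(r_perm <= r_obs + 1e-14)) / (n_perm + 1))
}

#' Mantel permutation test
#'
#' Pearson correlation of the strict lower triangles of two conformable
#' distance matrices, with significance from simultaneous row/column
#' permutations of `X`. Two-sided by default.
#'
#' @param X,Y [dist_matrix()] objects (or plain labelled symmetric
#'   matrices) with identical labels in identical order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @param tail `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Object of class `mantel_result` with `r`, `p`, `n_perm`,
#'   `tail`, `partial = FALSE`.
#' @export
mantel_test <- function(X, Y, n_perm = 9999, seed = NULL,
                        tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  check_conformable(X, Y)
  x <- triangle_or_stop(X, "X")
  y <- triangle_or_stop(Y, "Y")
  r_obs <- stats::cor(x, y)
  n <- nrow(X)
  Xm <- unclass(X)
  lt <- lower.tri(Xm)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(Xm[p, p][lt], y)
    }, numeric(1))
  })
  structure(list(r = r_obs, p = perm_pvalue(r_obs, r_perm, tail),
                 n_perm = n_perm, tail = tail, partial = FALSE,
                 covariate = NULL, seed = seed),
            class = "mantel_result")
}

partial_r <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Partial Mantel permutation test
#'
#' First-order partial correlation of the triangles of `X` and `Y` given a
#' covariate matrix `Z`, with significance obtained by permuting the rows
#' and columns of `X` and recomputing the partial statistic for each
#' permutation (Smouse-Long-Sokal scheme).
#'
#' @inheritParams mantel_test
#' @param Z Covariate [dist_matrix()].
#' @param covariate Label for the covariate, recorded in the result.
#' @return Object of class `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel_test <- function(X, Y, Z, n_perm = 9999, seed = NULL,
                                tail = c("two.sided", "greater", "less"),
                                covariate = "Z") {
  tail <- match.arg(tail)
  check_conformable(X, Y, Z)
  x <- triangle_or_stop(X, "X")
  y <- triangle_or_stop(Y, "Y")
  z <- triangle_or_stop(Z, "Z")
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop_rg("degenerate partial correlation: covariate collinear with X or Y",
            class = "rhizogeo_input_error")
  }
  r_obs <- partial_r(rxy, rxz, ryz)
  n <- nrow(X)
  Xm <- unclass(X)
  lt <- lower.tri(Xm)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      xp <- Xm[p, p][lt]
      partial_r(stats::cor(xp, y), stats::cor(xp, z), ryz)
    }, numeric(1))
  })
  structure(list(r = r_obs, p = perm_pvalue(r_obs, r_perm, tail),
                 n_perm = n_perm, tail = tail, partial = TRUE,
                 covariate = covariate, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  lab <- if (x$partial) paste0("partial Mantel (cov: ", x$covariate, ")")
         else "Mantel"
  cat(sprintf("<%s> r = %.4f, p = %.4g (%d permutations, %s)\n",
              lab, x$r, x$p, x$n_perm, x$tail))
  invisible(x)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition. Axes
#' with positive eigenvalues are retained and scaled by the square root of
#' their eigenvalue; negative eigenvalues are reported, not corrected.
#'
#' @param D A [dist_matrix()] (or labelled symmetric matrix), n >= 3.
#' @param n_axes Number of axes to return (default: all positive axes).
#'   Requests beyond the number of positive eigenvalues are truncated with
#'   a warning.
#' @return Object of class `pcoa_result`: `coordinates` (strains x axes),
#'   `eigenvalues` (all, nonincreasing), `prop_variance` (per positive
#'   axis, relative to the positive total), `n_negative`, `negative_sum`.
#' @export
principal_coordinates <- function(D, n_axes = NULL) {
  Dm <- unclass(as.matrix(D))
  n <- nrow(Dm)
  if (n < 3L) {
    stop_rg("need at least 3 strains for PCoA", class = "rhizogeo_input_error")
  }
  if (anyNA(Dm)) {
    stop_rg("distance matrix contains undefined entries",
            class = "rhizogeo_input_error")
  }
  A <- -0.5 * Dm^2
  G <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (is.null(n_axes)) n_axes <- length(pos)
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive axes available; truncating")
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  dimnames(coords) <- list(rownames(Dm), paste0("Axis", seq_len(n_axes)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 prop_variance = e$values[pos] / sum(e$values[pos]),
                 n_negative = sum(e$values < -tol),
                 negative_sum = sum(e$values[e$values < -tol])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result> ", nrow(x$coordinates), " strains, ",
      ncol(x$coordinates), " positive axes (", x$n_negative,
      " negative eigenvalues)\n", sep = "")
  cat("  prop. variance:",
      paste(sprintf("%.3f", utils::head(x$prop_variance, 5)), collapse = " "),
      "\n")
  invisible(x)
}

#' Regress genetic principal coordinates on geographic coordinates and altitude
#'
#' Each genetic coordinate is regressed by ordinary least squares on the
#' leading geographic principal coordinates (default 2, standing in for
#' latitude/longitude along a transect) and, optionally, altitude.
#' Per-term F statistics and p-values come from the sequential ANOVA of
#' each fit; the full-model R-squared is reported per genetic axis.
#'
#' @param genetic A `pcoa_result` for the genetic distance matrix.
#' @param geographic A `pcoa_result` for the geographic distance matrix.
#' @param altitude Optional named numeric vector of elevations (m).
#' @param n_genetic_axes Number of genetic axes to analyse (default 3:
#'   with four genospecies clusters the between-cluster structure spans
#'   three axes, and associations can appear beyond the leading one).
#' @param n_geo_axes Number of geographic axes used as predictors
#'   (default 2).
#' @return data.frame with columns genetic_axis, term, df, sum_sq,
#'   f_value, p_value, r_squared.
#' @export
pcoa_regression <- function(genetic, geographic, altitude = NULL,
                            n_genetic_axes = 3, n_geo_axes = 2) {
  gcoord <- genetic$coordinates
  geo <- geographic$coordinates
  if (!identical(rownames(gcoord), rownames(geo))) {
    stop_rg("genetic and geographic coordinates must share strains in order",
            class = "rhizogeo_input_error")
  }
  n_genetic_axes <- min(n_genetic_axes, ncol(gcoord))
  n_geo_axes <- min(n_geo_axes, ncol(geo))
  df <- as.data.frame(geo[, seq_len(n_geo_axes), drop = FALSE])
  names(df) <- paste0("geo", seq_len(n_geo_axes))
  terms <- names(df)
  if (!is.null(altitude)) {
    if (!all(rownames(gcoord) %in% names(altitude))) {
      stop_rg("altitude missing for some strains",
              class = "rhizogeo_input_error")
    }
    df$altitude <- altitude[rownames(gcoord)]
    terms <- c(terms, "altitude")
  }
  X <- stats::model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) {
    stop_rg("rank-deficient design (collinear predictors)",
            class = "rhizogeo_input_error")
  }
  out <- list()
  for (a in seq_len(n_genetic_axes)) {
    df$.y <- gcoord[, a]
    fit <- stats::lm(stats::reformulate(terms, ".y"), data = df)
    an <- stats::anova(fit)
    r2 <- summary(fit)$r.squared
    out[[a]] <- data.frame(genetic_axis = paste0("Axis", a),
                           term = rownames(an)[rownames(an) != "Residuals"],
                           df = an$Df[rownames(an) != "Residuals"],
                           sum_sq = an$`Sum Sq`[rownames(an) != "Residuals"],
                           f_value = an$`F value`[rownames(an) != "Residuals"],
                           p_value = an$`Pr(>F)`[rownames(an) != "Residuals"],
                           r_squared = r2,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Sliding-window genetic distance decay
#'
#' Windows of `width_km` are moved along the range of geographic distances
#' at `step_km` intervals. For each window holding at least one strain
#' pair, one pair is sampled uniformly and its nucleotide and haplotype
#' distances recorded (the study design assumes few haplotypes dominate
#' within a window of this width). A baseline of the same number of pairs
#' sampled uniformly from all pairs, irrespective of distance, is drawn for
#' comparison. Windows with no eligible pair are kept as empty (NA) rows.
#'
#' @param genetic Nucleotide-level [dist_matrix()].
#' @param haplotype Haplotype-level [dist_matrix()].
#' @param geo Geographic [dist_matrix()] in km.
#' @param width_km Window width (default 40).
#' @param step_km Step between window starts (default 10).
#' @param seed Optional integer seed (profile is reproducible given it).
#' @param exhaustive If `TRUE`, record the mean over all pairs within each
#'   window instead of one sampled pair (variance reduction; not the
#'   default design).
#' @return data.frame of class `window_profile` with columns window_low,
#'   window_high, midpoint, n_pairs, nt_distance, hap_distance,
#'   baseline_nt, baseline_hap; attributes `seed`, `width_km`, `step_km`.
#' @export
sliding_window_decay <- function(genetic, haplotype, geo, width_km = 40,
                                 step_km = 10, seed = NULL,
                                 exhaustive = FALSE) {
  check_conformable(genetic, haplotype, geo)
  n <- nrow(geo)
  lt <- which(lower.tri(unclass(geo)))
  gd <- unclass(geo)[lt]
  nt <- unclass(genetic)[lt]
  hap <- unclass(haplotype)[lt]
  starts <- seq(0, max(gd), by = step_km)
  res <- with_seed(seed, {
    rows <- lapply(starts, function(lo) {
      hi <- lo + width_km
      elig <- which(gd >= lo & gd < hi)
      if (!length(elig)) {
        return(data.frame(window_low = lo, window_high = hi,
                          midpoint = lo + width_km / 2, n_pairs = 0L,
                          nt_distance = NA_real_, hap_distance = NA_real_))
      }
      if (exhaustive) {
        data.frame(window_low = lo, window_high = hi,
                   midpoint = lo + width_km / 2, n_pairs = length(elig),
                   nt_distance = mean(nt[elig]), hap_distance = mean(hap[elig]))
      } else {
        k <- elig[sample.int(length(elig), 1L)]
        data.frame(window_low = lo, window_high = hi,
                   midpoint = lo + width_km / 2, n_pairs = length(elig),
                   nt_distance = nt[k], hap_distance = hap[k])
      }
    })
    prof <- do.call(rbind, rows)
    filled <- which(prof$n_pairs > 0L)
    if (!length(filled)) {
      stop_rg("all windows empty", class = "rhizogeo_input_error")
    }
    base_idx <- sample(length(gd), length(filled), replace = TRUE)
    prof$baseline_nt <- NA_real_
    prof$baseline_hap <- NA_real_
    prof$baseline_nt[filled] <- nt[base_idx]
    prof$baseline_hap[filled] <- hap[base_idx]
    prof
  })
  structure(res, class = c("window_profile", "data.frame"),
            seed = seed, width_km = width_km, step_km = step_km)
}

#' Spearman correlation between window midpoint and sampled distance
#'
#' Summary of a [sliding_window_decay()] profile: positive values indicate
#' distance decay of genetic similarity (isolation by distance).
#'
#' @param profile A `window_profile`.
#' @param which `"nt"` (nucleotide, default) or `"hap"` (haplotype).
#' @return Spearman rank correlation over non-empty windows.
#' @export
window_decay_correlation <- function(profile, which = c("nt", "hap")) {
  which <- match.arg(which)
  col <- if (which == "nt") "nt_distance" else "hap_distance"
  ok <- profile$n_pairs > 0
  stats::cor(profile$midpoint[ok], profile[[col]][ok], method = "spearman")
}
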