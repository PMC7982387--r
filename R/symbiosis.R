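# Greenhouse symbiotic-effectiveness analysis: synthetic response score
# (trait PCA), balanced variance components, Monte-Carlo Dunnett contrasts
# against the uninoculated control, and between-genospecies contrasts.
#
# Terminology follows the field: "symbiotic performance" is shoot dry
# weight (plant dry matter); "symbiotic response" is the first principal
# component of the scaled nodulation/biomass traits.

TRAIT_COLS <- c("nodule_number", "nodule_dw_mg", "shoot_dw_g", "root_dw_g")

#' Read a greenhouse trait table
#'
#' @param path CSV with columns strain, replicate, nodule_number,
#'   nodule_dw_mg, shoot_dw_g, root_dw_g.
#' @return data.frame of class `trait_table`.
#' @export
read_trait_table <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("strain", "replicate", TRAIT_COLS)
  if (!all(req %in% names(tt))) {
    stop_rg("trait table must have columns ", paste(req, collapse = ", "),
            class = "rhizogeo_input_error")
  }
  if (any(tt[TRAIT_COLS] < 0, na.rm = TRUE)) {
    stop_rg("negative trait measurements", class = "rhizogeo_input_error")
  }
  class(tt) <- c("trait_table", "data.frame")
  tt
}

#' Synthetic symbiotic-response score (first principal component)
#'
#' The (correlated) nodulation and biomass traits are standardized to zero
#' mean and unit variance and the first principal component of the scaled
#' matrix is used as a single symbiotic-response score. The sign is
#' oriented so that the loading on nodule dry weight is positive (response
#' increases with nodulation). Zero-variance traits are dropped with a
#' warning.
#'
#' @param tt A trait table (data.frame with `strain`, `replicate` and the
#'   four trait columns).
#' @return Object of class `response_score`: `scores` (data.frame strain,
#'   replicate, score), `loadings` (unit norm), `prop_variance` of PC1,
#'   `dropped` traits.
#' @export
response_pca <- function(tt) {
  traits <- intersect(TRAIT_COLS, names(tt))
  X <- as.matrix(tt[traits])
  v <- apply(X, 2, stats::var)
  if (all(v == 0)) {
    stop_rg("all traits have zero variance", class = "rhizogeo_input_error")
  }
  dropped <- traits[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance trait(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 2L) {
    stop_rg("need at least 2 traits with nonzero variance",
            class = "rhizogeo_input_error")
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  load1 <- pr$rotation[, 1]
  score <- pr$x[, 1]
  anchor <- if ("nodule_dw_mg" %in% names(load1)) "nodule_dw_mg"
            else names(load1)[1]
  if (load1[anchor] < 0) {
    load1 <- -load1
    score <- -score
  }
  structure(list(scores = data.frame(strain = tt$strain,
                                     replicate = tt$replicate,
                                     score = unname(score),
                                     stringsAsFactors = FALSE),
                 loadings = load1,
                 prop_variance = pr$sdev[1]^2 / sum(pr$sdev^2),
                 dropped = dropped),
            class = "response_score")
}

#' Variance components for a balanced strains-by-replicates design
#'
#' Two-way ANOVA without interaction on a balanced randomized complete
#' block design, treating strain and replicate as random. Components are
#' the method-of-moments solutions from the expected mean squares
#' (sigma2_strain = (MS_strain - MS_error) / r, sigma2_replicate =
#' (MS_replicate - MS_error) / s); negative estimates are truncated to
#' zero and flagged. The strain effect is tested with the exact
#' F = MS_strain / MS_error on (s-1, (s-1)(r-1)) degrees of freedom.
#' Unbalanced data is rejected rather than approximated.
#'
#' @param response Numeric response (e.g. the PC1 score), one value per
#'   strain x replicate cell.
#' @param strain,replicate Factors (or coercible) of the same length.
#' @return Object of class `variance_components`: `sigma2_strain`,
#'   `sigma2_replicate`, `sigma2_error`, `F`, `df`, `p.value`,
#'   `truncated` (which components were clipped at 0).
#' @export
variance_components <- function(response, strain, replicate) {
  strain <- factor(strain)
  replicate <- factor(replicate)
  s <- nlevels(strain)
  r <- nlevels(replicate)
  if (s < 2L || r < 2L) {
    stop_rg("need at least 2 strains and 2 replicates",
            class = "rhizogeo_input_error")
  }
  tab <- table(strain, replicate)
  if (any(tab != 1L)) {
    stop_rg("design is unbalanced (every strain must appear exactly once ",
            "per replicate); unbalanced designs are out of scope",
            class = "rhizogeo_input_error")
  }
  an <- suppressWarnings(
    stats::anova(stats::lm(response ~ strain + replicate)))
  MSs <- an["strain", "Mean Sq"]
  MSr <- an["replicate", "Mean Sq"]
  MSe <- an["Residuals", "Mean Sq"]
  # a numerically perfect fit (e.g. constant response) has no error term
  tol <- 1e-12 * max(mean(response^2), 1e-300)
  if (MSe < tol) MSe <- 0
  if (MSs < tol) MSs <- 0
  if (MSr < tol) MSr <- 0
  truncated <- character(0)
  s2_strain <- (MSs - MSe) / r
  s2_rep <- (MSr - MSe) / s
  if (s2_strain < 0) { s2_strain <- 0; truncated <- c(truncated, "strain") }
  if (s2_rep < 0) { s2_rep <- 0; truncated <- c(truncated, "replicate") }
  if (MSe == 0) {
    Fv <- NA_real_
    p <- NA_real_
  } else {
    Fv <- MSs / MSe
    p <- stats::pf(Fv, s - 1, (s - 1) * (r - 1), lower.tail = FALSE)
  }
  structure(list(sigma2_strain = s2_strain, sigma2_replicate = s2_rep,
                 sigma2_error = MSe, F = Fv,
                 df = c(s - 1, (s - 1) * (r - 1)), p.value = p,
                 truncated = truncated),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>\n")
  cat(sprintf("  sigma2: strain %.4g, replicate %.4g, error %.4g\n",
              x$sigma2_strain, x$sigma2_replicate, x$sigma2_error))
  cat(sprintf("  strain F(%d, %d) = %.3f, p = %.4g%s\n", x$df[1], x$df[2],
              x$F, x$p.value,
              if (length(x$truncated))
                paste0(" [truncated: ", paste(x$truncated, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Dunnett-style many-to-one comparisons against the uninoculated control
#'
#' Each strain is compared with the control on a common-variance t
#' statistic; the familywise-adjusted p-value is the probability, under
#' the null of equal means, that the maximum of the correlated t statistics
#' exceeds the observed one. That null distribution is estimated by seeded
#' Monte Carlo (`n_mc` draws of the correlated statistics via shared
#' control and variance draws), with Monte-Carlo error O(1/sqrt(n_mc)).
#' One-sided "greater" (strain exceeds control) is the default. Adjusted
#' p-values are clamped from below at the analytic per-comparison p, which
#' the exact Dunnett adjustment never undercuts.
#'
#' @param values Numeric measurements (typically shoot dry weight, g).
#' @param strain Group labels, same length as `values`.
#' @param control Label of the control group (must have >= 2 replicates).
#' @param alpha Familywise significance level for the `significant` flag.
#' @param n_mc Monte-Carlo samples of the max-t null (default 100000).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return data.frame of class `dunnett_result`: strain, n, mean,
#'   difference (vs control), t, p_unadjusted, p_adjusted, significant.
#' @export
dunnett_vs_control <- function(values, strain, control, alpha = 0.05,
                               n_mc = 100000, seed = NULL,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  strain <- as.character(strain)
  if (!control %in% strain) {
    stop_rg("control group '", control, "' not found",
            class = "rhizogeo_input_error")
  }
  groups <- split(values, strain)
  if (length(groups[[control]]) < 2L) {
    stop_rg("control must have at least 2 replicates",
            class = "rhizogeo_input_error")
  }
  trt <- setdiff(names(groups), control)
  if (length(trt) < 2L) {
    stop_rg("need at least 2 treatment strains",
            class = "rhizogeo_input_error")
  }
  ns <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  N <- sum(ns)
  k <- length(groups)
  df <- N - k
  if (df < 1L) {
    stop_rg("no residual degrees of freedom", class = "rhizogeo_input_error")
  }
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  s2 <- ss / df
  if (s2 == 0) {
    stop_rg("zero pooled variance", class = "rhizogeo_input_error")
  }
  se <- sqrt(s2 * (1 / ns[trt] + 1 / ns[control]))
  tstat <- (means[trt] - means[control]) / se
  p_unadj <- if (alternative == "greater") {
    stats::pt(tstat, df, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  # Monte-Carlo max-t null: shared control normal and shared chi-square
  # variance draw induce the Dunnett correlation structure.
  max_null <- with_seed(seed, {
    S <- sqrt(stats::rchisq(n_mc, df) / df)
    z0 <- stats::rnorm(n_mc) / sqrt(ns[control])
    m <- matrix(NA_real_, n_mc, length(trt))
    for (j in seq_along(trt)) {
      zj <- stats::rnorm(n_mc) / sqrt(ns[trt[j]])
      m[, j] <- (zj - z0) / (S * sqrt(1 / ns[trt[j]] + 1 / ns[control]))
    }
    if (alternative == "greater") apply(m, 1, max) else apply(abs(m), 1, max)
  })
  stat_for_adj <- if (alternative == "greater") tstat else abs(tstat)
  p_adj <- vapply(stat_for_adj, function(t0)
    (1 + sum(max_null >= t0)) / (n_mc + 1), numeric(1))
  p_adj <- pmax(p_adj, p_unadj)
  out <- data.frame(strain = trt, n = ns[trt], mean = means[trt],
                    difference = means[trt] - means[control],
                    t = tstat, p_unadjusted = p_unadj, p_adjusted = p_adj,
                    significant = p_adj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "control") <- control
  attr(out, "df") <- df
  attr(out, "n_mc") <- n_mc
  attr(out, "seed") <- seed
  attr(out, "alternative") <- alternative
  class(out) <- c("dunnett_result", "data.frame")
  out
}

#' Contrast symbiotic performance between two genospecies
#'
#' Two-sided Welch t-test and one-sided Wilcoxon rank-sum test (exact when
#' both groups have <= 15 strains and there are no ties, else the normal
#' approximation with tie correction) of per-strain performance between
#' groups A and B, with the one-sided alternative that A is smaller than B
#' by default. The percent difference is (mean_A - mean_B) / mean_A * 100.
#'
#' @param values Named numeric vector of per-strain performance.
#' @param labels Named character vector strain -> genospecies.
#' @param group_a,group_b Genospecies labels to contrast (>= 2 strains
#'   each).
#' @param alternative One-sided Wilcoxon alternative for A vs B
#'   (`"less"` default).
#' @return List: `mean_a`, `mean_b`, `percent_difference`, `t_p` (Welch,
#'   two-sided), `wilcoxon_p` (one-sided), group sizes.
#' @export
genospecies_contrast <- function(values, labels, group_a, group_b,
                                 alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(names(values)) || is.null(names(labels))) {
    stop_rg("values and labels must be named by strain",
            class = "rhizogeo_input_error")
  }
  a <- values[names(labels)[labels == group_a]]
  b <- values[names(labels)[labels == group_b]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_rg("both groups need at least 2 strains",
            class = "rhizogeo_input_error")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  exact <- length(a) <= 15 && length(b) <= 15 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = !exact))
  list(mean_a = mean(a), mean_b = mean(b),
       percent_difference = (mean(a) - mean(b)) / mean(a) * 100,
       t_p = tt$p.value, wilcoxon_p = wt$p.value,
       n_a = length(a), n_b = length(b))
}
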