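# PCA over core-genus relative abundances (mean-centered, unscaled — the
# Euclidean metric on relative abundances) and a one-way MANOVA on the
# leading principal-component scores, with Wilks' lambda and Bartlett's
# chi-square approximation.

#' Principal component analysis of core-genus abundances
#'
#' Mean-centered, unscaled SVD-based PCA. Sign convention: each loading
#' vector's largest-magnitude entry is positive (scores flipped to match),
#' so results are reproducible across platforms.
#'
#' @param t a `coregut_abund` or a genus x sample matrix.
#' @param samples sample subset; default all.
#' @param genera genus subset (typically the core set); default all.
#' @return a `coregut_pca`: `scores` (sample x component), `loadings`
#'   (genus x component), `explained` (variance ratios, non-increasing),
#'   `center`.
#' @export
pca_abundance <- function(t, samples = NULL, genera = NULL) {
  m <- if (inherits(t, "coregut_abund")) t$rel_abund else t
  .assert(is.matrix(m), "need a coregut_abund or a matrix")
  if (!is.null(genera)) m <- m[genera, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  x <- t(m)                                  # samples x genera
  .assert(nrow(x) >= 2, "need at least 2 samples for PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained = expl, center = pc$center),
            class = "coregut_pca")
}

#' One-way MANOVA on principal-component scores
#'
#' Tests class separation on the first `k` PC scores. Wilks' lambda is
#' `det(W) / det(W + B)` (within- and between-class cross-product
#' matrices); significance uses Bartlett's chi-square approximation,
#' `chi2 = -(n - 1 - (k + g)/2) * ln(lambda)` on `k (g - 1)` degrees of
#' freedom. If W is singular at the requested `k`, `k` is reduced with a
#' message until it is invertible.
#'
#' @param o a `coregut_pca`, or a sample x component score matrix.
#' @param labels per-sample class labels (>= 2 classes, each >= 2 samples).
#' @param k number of leading components to test (default 2, matching 2-D
#'   score plots); must satisfy `k <= n - g - 1`.
#' @return a `coregut_manova`: `wilks_lambda`, `statistic` (chi-square),
#'   `df`, `p`, `k`, `n`, `n_classes`.
#' @export
manova_test <- function(o, labels, k = 2L) {
  scores <- if (inherits(o, "coregut_pca")) o$scores else as.matrix(o)
  labels <- factor(labels)
  n <- nrow(scores)
  g <- nlevels(labels)
  .assert(length(labels) == n, "labels must match score rows")
  .assert(g >= 2, "need at least 2 classes")
  .assert(min(table(labels)) >= 2, "each class needs at least 2 samples")
  .assert(k >= 1 && k <= ncol(scores), "k out of range")
  .assert(k <= n - g - 1, "k too large for n = %d samples and g = %d classes", n, g)
  repeat {
    x <- scores[, seq_len(k), drop = FALSE]
    grand <- colMeans(x)
    W <- matrix(0, k, k); B <- matrix(0, k, k)
    for (lev in levels(labels)) {
      xi <- x[labels == lev, , drop = FALSE]
      mi <- colMeans(xi)
      ci <- sweep(xi, 2, mi)
      W <- W + crossprod(ci)
      dm <- mi - grand
      B <- B + nrow(xi) * tcrossprod(dm)
    }
    detW <- det(W)
    if (detW > .Machine$double.eps * max(abs(W))^k || k == 1) break
    message("singular within-class matrix at k = ", k, "; reducing to ", k - 1)
    k <- k - 1L
    if (k < 1) stop("within-class matrix singular at every k", call. = FALSE)
  }
  lambda <- detW / det(W + B)
  lambda <- min(max(lambda, .Machine$double.xmin), 1)
  stat <- -(n - 1 - (k + g) / 2) * log(lambda)
  df <- k * (g - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(wilks_lambda = lambda, statistic = stat, df = df, p = p,
                 k = k, n = n, n_classes = g),
            class = "coregut_manova")
}

#' @export
print.coregut_manova <- function(x, ...) {
  cat(sprintf(
    "One-way MANOVA on %d PC scores (%d samples, %d classes)\n", x$k, x$n,
    x$n_classes))
  cat(sprintf("  Wilks' lambda = %.4g, chi2 = %.4g on %d df, p = %.4g\n",
              x$wilks_lambda, x$statistic, x$df, x$p))
  invisible(x)
}
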