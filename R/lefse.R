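# Differential-abundance screen in the LEfSe style: a per-genus
# Kruskal-Wallis test gates entry, then a bootstrapped, regularized linear
# discriminant yields a log10 effect size ("LDA score") with the customary
# selection threshold of 2.0 on per-million-scaled abundances.

#' Kruskal-Wallis test for one genus
#'
#' Tie-corrected H with a chi-square null on `g - 1` degrees of freedom.
#' All-identical values give H = 0, p = 1 by convention.
#'
#' @param values per-sample abundances.
#' @param classes per-sample class labels (>= 2 non-empty classes).
#' @return named vector `c(H =, p =)`.
#' @export
kruskal_wallis <- function(values, classes) {
  classes <- factor(classes)
  .assert(nlevels(classes) >= 2, "need at least 2 classes")
  .assert(all(table(classes) > 0), "every class must be non-empty")
  if (length(unique(values)) == 1) return(c(H = 0, p = 1))
  kt <- stats::kruskal.test(values, classes)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Bootstrapped LDA effect size for a two-class comparison
#'
#' Abundances are scaled to per-million. For each of `n_boot` bootstrap
#' rounds, a fraction `sample_frac` of each class is drawn (without
#' replacement, bound to sorted sample ids so column order is irrelevant)
#' and a ridge-regularized linear discriminant is fitted; the per-genus
#' effect in a round is the average of the genus' contribution along the
#' discriminant direction and its raw class-mean difference. The effect
#' size is the absolute mean over rounds and the score is
#' `log10(1 + effect)`, so a zero effect maps to score 0. Deterministic
#' given `seed`.
#'
#' @param mat genus x sample matrix of relative abundances.
#' @param classes per-sample labels; exactly 2 classes.
#' @param n_boot bootstrap rounds (default 30).
#' @param sample_frac per-class subsample fraction (default 2/3); each
#'   round must keep at least 2 samples per class.
#' @param seed RNG seed.
#' @return data.frame `genus`, `effect`, `lda_score`, `enriched`.
#' @export
lda_effect_size <- function(mat, classes, n_boot = 30L, sample_frac = 2 / 3,
                            seed = 1L) {
  .assert(is.matrix(mat), "mat must be a genus x sample matrix")
  classes <- factor(classes)
  .assert(nlevels(classes) == 2, "LDA effect size needs exactly 2 classes")
  .assert(length(classes) == ncol(mat), "classes must match columns")
  lv <- levels(classes)
  x <- mat * 1e6                              # per-million scale
  ids <- colnames(x)
  if (is.null(ids)) ids <- sprintf("%09d", seq_len(ncol(x)))
  # resampling indices bound to sorted sample ids per class, with the RNG
  # sub-stream assigned by class membership (smallest member id), so both
  # column permutation and class relabeling leave the draws unchanged
  idx1 <- which(classes == lv[1])[order(ids[classes == lv[1]])]
  idx2 <- which(classes == lv[2])[order(ids[classes == lv[2]])]
  n1 <- max(2L, floor(sample_frac * length(idx1)))
  n2 <- max(2L, floor(sample_frac * length(idx2)))
  .assert(length(idx1) >= 2 && length(idx2) >= 2,
          "each class needs at least 2 samples")
  first1 <- ids[idx1[1]] <= ids[idx2[1]]
  set.seed(.substream_seed(seed, if (first1) 11 else 12))
  draws1 <- t(replicate(n_boot, sample.int(length(idx1), n1)))
  set.seed(.substream_seed(seed, if (first1) 12 else 11))
  draws2 <- t(replicate(n_boot, sample.int(length(idx2), n2)))
  k <- nrow(x)
  acc <- matrix(0, k, n_boot)
  for (b in seq_len(n_boot)) {
    s1 <- idx1[draws1[b, ]]
    s2 <- idx2[draws2[b, ]]
    mu1 <- rowMeans(x[, s1, drop = FALSE])
    mu2 <- rowMeans(x[, s2, drop = FALSE])
    d <- mu1 - mu2
    c1 <- x[, s1, drop = FALSE] - mu1
    c2 <- x[, s2, drop = FALSE] - mu2
    Sw <- (tcrossprod(c1) + tcrossprod(c2)) / (n1 + n2 - 2)
    ridge <- 0.01 * mean(diag(Sw)) + 1e-8
    w <- tryCatch(solve(Sw + diag(ridge, k), d),
                  error = function(e) d)      # fall back to the mean axis
    if (sum(w * d) < 0) w <- -w
    nw <- sqrt(sum(w^2))
    if (nw > 0) w <- w / nw
    ld <- sum(w * d)
    acc[, b] <- (w * ld + d) / 2
  }
  effect <- abs(rowMeans(acc))
  mu1_all <- rowMeans(x[, idx1, drop = FALSE])
  mu2_all <- rowMeans(x[, idx2, drop = FALSE])
  enriched <- ifelse(mu1_all >= mu2_all, lv[1], lv[2])
  enriched[effect == 0] <- NA_character_
  data.frame(genus = rownames(x), effect = effect,
             lda_score = log10(1 + effect), enriched = enriched,
             stringsAsFactors = FALSE)
}

#' LEfSe-style differential abundance over core genera
#'
#' Per genus, a Kruskal-Wallis screen at `alpha` (strict `p < alpha`); the
#' survivors enter [lda_effect_size()], and a genus is selected when its
#' LDA score strictly exceeds `lda_min` (customarily 2.0).
#'
#' @param t a `coregut_abund` or genus x sample matrix.
#' @param classes per-sample labels (2 classes for the LDA stage).
#' @param genera genus subset (typically the core set); default all rows.
#' @param samples sample subset aligned with `classes`; default all.
#' @param alpha Kruskal-Wallis screen level (default 0.05).
#' @param lda_min LDA score selection threshold (default 2.0).
#' @param n_boot,sample_frac,seed passed to [lda_effect_size()].
#' @return a `coregut_lefse` data.frame: `genus`, `H`, `p`,
#'   `passed_screen`, `lda_score`, `enriched`, `selected`, ordered by
#'   descending score (screen failures last).
#' @export
run_lefse <- function(t, classes, genera = NULL, samples = NULL,
                      alpha = 0.05, lda_min = 2.0,
                      n_boot = 30L, sample_frac = 2 / 3, seed = 1L) {
  m <- if (inherits(t, "coregut_abund")) t$rel_abund else t
  if (!is.null(genera)) m <- m[genera, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  classes <- factor(classes)
  .assert(length(classes) == ncol(m), "classes must match samples")
  kw <- t(apply(m, 1, kruskal_wallis, classes = classes))
  passed <- kw[, "p"] < alpha
  out <- data.frame(genus = rownames(m), H = kw[, "H"], p = kw[, "p"],
                    passed_screen = passed, lda_score = NA_real_,
                    enriched = NA_character_, selected = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (any(passed)) {
    eff <- lda_effect_size(m[passed, , drop = FALSE], classes,
                           n_boot = n_boot, sample_frac = sample_frac,
                           seed = seed)
    i <- match(eff$genus, out$genus)
    out$lda_score[i] <- eff$lda_score
    out$enriched[i] <- eff$enriched
    out$selected[i] <- eff$lda_score > lda_min
  }
  out <- out[order(-replace(out$lda_score, is.na(out$lda_score), -Inf),
                   out$genus), ]
  rownames(out) <- NULL
  class(out) <- c("coregut_lefse", "data.frame")
  out
}
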