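# Spearman co-abundance network over the core genera, Benjamini-Yekutieli
# FDR control over the full upper triangle of pairwise tests, and
# partitioning of the core set into co-abundance groups (CAGs).

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' `q_(i) = min_{j >= i} min(1, p_(j) * m * c(m) / j)` with
#' `c(m) = sum_{k=1..m} 1/k`. `m` may exceed `length(p)` when some tests in
#' the family were degenerate but still counted.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param m size of the test family; must be at least `length(p)`.
#' @return adjusted q-values, same length as `p`.
#' @export
by_adjust <- function(p, m = length(p)) {
  .assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  .assert(m >= length(p), "family size m (%d) smaller than number of p-values (%d)",
          m, length(p))
  stats::p.adjust(p, method = "BY", n = m)
}

#' Spearman correlation matrix over core genera
#'
#' Rho is the Pearson correlation of average-ranked abundances (ties share
#' the average rank; zeros rank lowest, tied among themselves); two-sided p
#' comes from the t approximation; q from [by_adjust()] over the full
#' `k(k-1)/2` upper triangle. A constant genus (zero variance) yields rho 0,
#' p 1 and a warning, so the partition can still cover the whole core set.
#'
#' @param t a `coregut_abund`, or a genus x sample numeric matrix.
#' @param samples sample subset (ids or indices); default all.
#' @param genera genus subset; default all rows.
#' @param r_min,q_max thresholds stored into the significance mask
#'   (strict `|rho| > r_min`, strict `q < q_max`).
#' @return a `coregut_corr`: `genera`, `n`, matrices `rho`, `pval`, `qval`,
#'   `sig_mask`, and the thresholds used.
#' @export
spearman_matrix <- function(t, samples = NULL, genera = NULL,
                            r_min = 0.5, q_max = 0.001) {
  m <- if (inherits(t, "coregut_abund")) t$rel_abund else t
  .assert(is.matrix(m), "need a coregut_abund or a matrix")
  if (!is.null(genera)) m <- m[genera, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  k <- nrow(m); n <- ncol(m)
  .assert(n >= 3, "need at least 3 samples for correlation")
  .assert(k >= 1, "need at least 1 genus")
  const <- apply(m, 1, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant genus (zero variance): ",
            paste(rownames(m)[const], collapse = ", "),
            "; rho set to 0, p to 1")
  }
  ranks <- t(apply(m, 1, rank))           # average ranks per genus
  rho <- suppressWarnings(stats::cor(t(ranks)))
  rho[is.na(rho)] <- 0
  rho[const, ] <- 0; rho[, const] <- 0
  diag(rho) <- 1
  pval <- matrix(1, k, k, dimnames = dimnames(rho))
  ut <- upper.tri(rho)
  pval[ut] <- vapply(which(ut), function(i) .spearman_p(rho[i], n), numeric(1))
  pval[lower.tri(pval)] <- t(pval)[lower.tri(pval)]
  n_tests <- k * (k - 1) / 2
  qv <- by_adjust(pval[ut], m = n_tests)
  qval <- matrix(1, k, k, dimnames = dimnames(rho))
  qval[ut] <- qv
  qval[lower.tri(qval)] <- t(qval)[lower.tri(qval)]
  diag(pval) <- NA_real_; diag(qval) <- NA_real_
  sig <- abs(rho) > r_min & qval < q_max
  sig[is.na(sig)] <- FALSE
  structure(list(genera = rownames(m), n = n, rho = rho, pval = pval,
                 qval = qval, sig_mask = sig, r_min = r_min, q_max = q_max),
            class = "coregut_corr")
}

#' Significant co-abundance edges
#'
#' An edge (i, j) is significant when `|rho| > r_min` (strict) and
#' `q < q_max` (strict). Negative edges are reported for intergroup
#' summaries but never used for grouping.
#'
#' @param c a `coregut_corr`.
#' @param r_min,q_max thresholds (defaults: those stored in `c`).
#' @param all if `TRUE`, return every upper-triangle pair with a
#'   `significant` flag instead of only the significant ones.
#' @return data.frame `genus_i`, `genus_j`, `rho`, `p`, `q`, `sign`,
#'   `significant`.
#' @export
significant_edges <- function(c, r_min = c$r_min, q_max = c$q_max, all = FALSE) {
  .assert(inherits(c, "coregut_corr"), "not a coregut_corr")
  ut <- which(upper.tri(c$rho), arr.ind = TRUE)
  df <- data.frame(genus_i = c$genera[ut[, 1]],
                   genus_j = c$genera[ut[, 2]],
                   rho = c$rho[ut], p = c$pval[ut], q = c$qval[ut],
                   stringsAsFactors = FALSE)
  df$sign <- sign(df$rho)
  df$significant <- abs(df$rho) > r_min & df$q < q_max
  if (!all) df <- df[df$significant, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Partition core genera into co-abundance groups
#'
#' Average-linkage agglomerative clustering on the distance `1 - rho`, cut
#' at height `cut_height` (default 0.5, i.e. mean within-cluster rho >=
#' 0.5). Singletons are permitted. Groups are labeled C1, C2, ... by
#' descending size, ties broken by descending mean prevalence; within each
#' group, genera are ordered by descending prevalence. An alternative
#' `method = "components"` uses connected components over significant
#' positive edges (sensitivity analysis only).
#'
#' @param c a `coregut_corr`.
#' @param prevalences named prevalence vector covering `c$genera`.
#' @param cut_height tree cut height on the `1 - rho` scale.
#' @param method `"average"` (default) or `"components"`.
#' @return a `coregut_cags`: data.frame (`genus`, `group`, `prevalence`)
#'   in report order, plus the genus -> group map as attribute `partition`.
#' @export
build_groups <- function(c, prevalences, cut_height = 0.5,
                         method = c("average", "components")) {
  .assert(inherits(c, "coregut_corr"), "not a coregut_corr")
  method <- match.arg(method)
  g <- c$genera
  .assert(all(g %in% names(prevalences)), "prevalences missing for some genera")
  prev <- prevalences[g]
  if (length(g) == 1) {
    memb <- setNames(1L, g)
  } else if (method == "average") {
    d <- as.dist(1 - c$rho)
    hc <- stats::hclust(d, method = "average")
    memb <- stats::cutree(hc, h = cut_height)
  } else {
    adj <- c$sig_mask & c$rho > 0
    diag(adj) <- TRUE
    memb <- .connected_components(adj)
    names(memb) <- g
  }
  sizes <- table(memb)
  mean_prev <- tapply(prev, memb, mean)
  ord_groups <- order(-as.numeric(sizes), -as.numeric(mean_prev))
  relabel <- setNames(seq_along(ord_groups), names(sizes)[ord_groups])
  group <- paste0("C", relabel[as.character(memb)])
  ord <- order(relabel[as.character(memb)], -prev, g)
  out <- data.frame(genus = g[ord], group = group[ord],
                    prevalence = unname(prev[ord]), stringsAsFactors = FALSE)
  attr(out, "partition") <- setNames(group, g)
  attr(out, "cut_height") <- cut_height
  attr(out, "method") <- method
  class(out) <- c("coregut_cags", "data.frame")
  out
}

#' @noRd
.connected_components <- function(adj) {
  k <- nrow(adj)
  comp <- rep(NA_integer_, k)
  cur <- 0L
  for (i in seq_len(k)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

#' Between-group correlation summary
#'
#' For each unordered pair of groups: the mean rho over all cross-group
#' genus pairs and the counts of significant positive and negative edges.
#'
#' @param g a `coregut_cags`.
#' @param c the `coregut_corr` it was built from.
#' @return data.frame `group_a`, `group_b`, `mean_rho`, `n_pos_sig`,
#'   `n_neg_sig`, `n_pairs`.
#' @export
intergroup_summary <- function(g, c) {
  .assert(inherits(g, "coregut_cags"), "not a coregut_cags")
  .assert(inherits(c, "coregut_corr"), "not a coregut_corr")
  part <- attr(g, "partition")
  .assert(setequal(names(part), c$genera), "grouping inconsistent with correlation")
  groups <- unique(g$group)
  idx <- lapply(groups, function(grp) match(names(part)[part == grp], c$genera))
  names(idx) <- groups
  res <- list()
  if (length(groups) >= 2) {
    for (a in seq_len(length(groups) - 1)) {
      for (b in (a + 1):length(groups)) {
        block_r <- c$rho[idx[[a]], idx[[b]], drop = FALSE]
        block_s <- c$sig_mask[idx[[a]], idx[[b]], drop = FALSE]
        res[[length(res) + 1]] <- data.frame(
          group_a = groups[a], group_b = groups[b],
          mean_rho = mean(block_r),
          n_pos_sig = sum(block_s & block_r > 0),
          n_neg_sig = sum(block_s & block_r < 0),
          n_pairs = length(block_r),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(group_a = character(), group_b = character(),
                         mean_rho = numeric(), n_pos_sig = integer(),
                         n_neg_sig = integer(), n_pairs = integer())
  rownames(out) <- NULL
  out
}
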