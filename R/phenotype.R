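# Spearman screen between principal-component scores of the core-genus
# ordination and host physiological parameters, with Benjamini-Hochberg
# FDR over the whole component x parameter family.

#' Correlate PC scores with host parameters
#'
#' Spearman rho and two-sided p (t approximation) per (component,
#' parameter) pair on pairwise-complete observations; pairs with fewer than
#' 3 complete observations are reported as NA. q-values are
#' Benjamini-Hochberg over all computed pairs in one family; significance
#' is strict `q < q_max` (default 0.1).
#'
#' @param o a `coregut_pca` or a sample x component score matrix.
#' @param params sample x parameter numeric matrix or data.frame; rows
#'   aligned with the score rows (matched by rowname when both are named).
#' @param k_components number of leading components tested (default 10,
#'   capped at availability).
#' @param q_max significance threshold on the FDR scale.
#' @return a `coregut_phenocorr` data.frame: `component`, `parameter`,
#'   `rho`, `p`, `q`, `n`, `significant`.
#' @export
correlate_pcs <- function(o, params, k_components = 10L, q_max = 0.1) {
  scores <- if (inherits(o, "coregut_pca")) o$scores else as.matrix(o)
  params <- as.matrix(as.data.frame(params))
  if (!is.null(rownames(scores)) && !is.null(rownames(params)) &&
      all(rownames(scores) %in% rownames(params))) {
    params <- params[rownames(scores), , drop = FALSE]
  }
  .assert(nrow(params) == nrow(scores),
          "host parameters must align with score rows")
  k <- min(k_components, ncol(scores))
  grid <- expand.grid(component = seq_len(k),
                      parameter = colnames(params),
                      stringsAsFactors = FALSE)
  res <- t(apply(grid, 1, function(r) {
    .spearman_pair(scores[, as.integer(r[["component"]])],
                   params[, r[["parameter"]]])
  }))
  out <- data.frame(component = paste0("PC", grid$component),
                    parameter = grid$parameter,
                    rho = res[, "rho"], p = res[, "p"],
                    n = as.integer(res[, "n"]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$p))) {
    message("pairs with fewer than 3 complete observations reported as NA: ",
            sum(is.na(out$p)))
  }
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$significant <- !is.na(out$q) & out$q < q_max
  class(out) <- c("coregut_phenocorr", "data.frame")
  out
}
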