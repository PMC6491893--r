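# Internal helpers shared across stages.

#' @noRd
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Spearman rho with two-sided p from the t approximation:
# t = r * sqrt((n-2)/(1-r^2)) on n-2 df. |r| = 1 maps to p = 0.
#' @noRd
.spearman_pair <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) return(c(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(rho = 0, p = 1, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  p <- .spearman_p(r, n)
  c(rho = r, p = p, n = n)
}

#' @noRd
.spearman_p <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

# Adjusted Rand index between two labelings of the same objects.
#' @noRd
.adjusted_rand <- function(a, b) {
  .assert(length(a) == length(b), "labelings differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Derive a sub-stage seed from the master seed by a fixed offset, kept
# within the 32-bit integer range expected by set.seed().
#' @noRd
.substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

#' @noRd
.write_tsv <- function(df, path, rownames = FALSE, rowname_header = "id") {
  if (rownames) {
    df <- data.frame(setNames(list(rownames(df)), rowname_header),
                     as.data.frame(df), check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
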