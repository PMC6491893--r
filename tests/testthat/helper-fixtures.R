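# Shared builders for small in-memory fixtures.

# OTU table object from a bare matrix
otu_fixture <- function(counts, flags = NULL) {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  storage.mode(counts) <- "integer"
  fl <- setNames(rep("", nrow(counts)), rownames(counts))
  if (!is.null(flags)) fl[names(flags)] <- flags
  structure(list(otu_ids = rownames(counts), sample_ids = colnames(counts),
                 counts = counts, flags = fl),
            class = "coregut_otu")
}

# relative-abundance object from a bare matrix (columns renormalized)
abund_fixture <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  rel <- sweep(m, 2, colSums(m), "/")
  structure(list(genus_ids = rownames(m), sample_ids = colnames(m),
                 rel_abund = rel, denominators = colSums(m),
                 phylum = setNames(rep(NA_character_, nrow(m)), rownames(m))),
            class = "coregut_abund")
}

# correlation object with a prescribed rho matrix (p/q consistent with n)
corr_fixture <- function(rho, n = 100, r_min = 0.5, q_max = 0.001,
                         qval = NULL) {
  k <- nrow(rho)
  if (is.null(rownames(rho))) {
    dimnames(rho) <- list(paste0("g", seq_len(k)), paste0("g", seq_len(k)))
  }
  if (is.null(qval)) {
    qval <- matrix(ifelse(abs(rho) > r_min, q_max / 10, 1), k, k,
                   dimnames = dimnames(rho))
  }
  pval <- qval
  diag(pval) <- NA_real_; diag(qval) <- NA_real_
  sig <- abs(rho) > r_min & qval < q_max
  sig[is.na(sig)] <- FALSE
  structure(list(genera = rownames(rho), n = n, rho = rho, pval = pval,
                 qval = qval, sig_mask = sig, r_min = r_min, q_max = q_max),
            class = "coregut_corr")
}

# independent average-rank computation (sort-based tie averaging), used as
# the Spearman oracle so it never shares code with the implementation
oracle_rank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  r[o] <- seq_along(x)
  for (v in unique(x)) {
    i <- which(x == v)
    r[i] <- mean(r[i])
  }
  r
}

oracle_pearson <- function(a, b) {
  a <- a - sum(a) / length(a)
  b <- b - sum(b) / length(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# brute-force BY step-up: literal evaluation of
# q_(i) = min_{j >= i} min(1, p_(j) * m * c(m) / j)
oracle_by <- function(p, m = length(p)) {
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  q <- numeric(length(p))
  for (i in seq_along(ps)) {
    q[i] <- min(1, min(ps[seq(i, length(ps))] * m * cm /
                         seq(i, length(ps))))
  }
  q[order(o)]
}

# tie-corrected Kruskal-Wallis H evaluated from the textbook formula
oracle_kw_h <- function(values, classes) {
  classes <- factor(classes)
  n <- length(values)
  r <- oracle_rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, classes, sum)^2 / tabulate(classes)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# caterpillar alignment with zero homoplasy: one column block per internal
# bipartition (A on one side, C on the other) plus taxon-private G columns,
# so every bootstrap replicate recovers the same fully resolved topology
perfect_signal_alignment <- function(n_taxa, per_split = 80, per_taxon = 20) {
  taxa <- paste0("t", seq_len(n_taxa))
  cols <- list()
  for (cut in 2:(n_taxa - 2)) {          # caterpillar bipartitions
    pat <- ifelse(seq_len(n_taxa) <= cut, "A", "C")
    cols <- c(cols, replicate(per_split, pat, simplify = FALSE))
  }
  for (i in seq_len(n_taxa)) {
    pat <- rep("A", n_taxa); pat[i] <- "G"
    cols <- c(cols, replicate(per_taxon, pat, simplify = FALSE))
  }
  aln <- do.call(cbind, cols)
  rownames(aln) <- taxa
  aln
}

# random additive tree + its path-length matrix (oracle for NJ consistency)
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tr)
  list(tree = tr, dist = d[order(rownames(d)), order(colnames(d))])
}
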