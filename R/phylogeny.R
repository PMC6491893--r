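# Distance-based phylogeny over representative sequences of the core
# genera: p-distances (pairwise deletion, optional Jukes-Cantor
# correction), classic neighbor-joining, and Felsenstein bootstrap
# supports. The NJ agglomeration is implemented here in full; trees are
# returned as ape "phylo" objects for interoperability.

VALID_BASES <- c("A", "C", "G", "T")

#' Read an aligned FASTA into a character matrix
#'
#' @param path aligned FASTA (equal-length sequences).
#' @return taxa x site uppercase character matrix.
#' @export
read_alignment <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  dna <- ape::read.FASTA(path)
  .assert(length(dna) >= 2, "need at least 2 sequences")
  lens <- lengths(dna)
  .assert(length(unique(lens)) == 1,
          "sequences are not aligned (unequal lengths)")
  m <- as.character(as.matrix(dna))
  m[] <- toupper(m)
  rownames(m) <- names(dna)
  m
}

#' Pairwise p-distances with pairwise deletion
#'
#' `d = mismatches / compared sites`, where compared sites are those with
#' an unambiguous A/C/G/T in both sequences (gaps and ambiguity codes are
#' deleted pairwise). `model = "JC69"` applies the Jukes-Cantor correction
#' `-3/4 ln(1 - 4 p / 3)`.
#'
#' @param aln character matrix from [read_alignment()] (or a path).
#' @param model `"raw"` (p-distance, default) or `"JC69"`.
#' @return a `coregut_dist`: symmetric matrix with zero diagonal.
#' @export
p_distance <- function(aln, model = c("raw", "JC69")) {
  model <- match.arg(model)
  if (is.character(aln) && length(aln) == 1 && file.exists(aln)) {
    aln <- read_alignment(aln)
  }
  .assert(is.matrix(aln) && nrow(aln) >= 2, "need an alignment of >= 2 taxa")
  aln[] <- toupper(aln)
  n <- nrow(aln)
  # integer encoding; 0 = gap/ambiguity, deleted pairwise via indicator algebra
  enc <- matrix(match(aln, VALID_BASES, nomatch = 0L), n, ncol(aln))
  V <- (enc > 0) * 1
  comp <- tcrossprod(V)
  off <- which(comp == 0 & upper.tri(comp), arr.ind = TRUE)
  if (nrow(off)) {
    stop(sprintf("no comparable sites between '%s' and '%s'",
                 rownames(aln)[off[1, 1]], rownames(aln)[off[1, 2]]),
         call. = FALSE)
  }
  match_cnt <- matrix(0, n, n)
  for (b in seq_along(VALID_BASES)) {
    Ib <- (enc == b) * 1
    match_cnt <- match_cnt + tcrossprod(Ib)
  }
  d <- (comp - match_cnt) / comp
  diag(d) <- 0
  if (model == "JC69") {
    .assert(max(d) < 0.75, "JC69 undefined at p >= 0.75")
    d <- -0.75 * log(1 - 4 * d / 3)
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(aln), rownames(aln))
  class(d) <- c("coregut_dist", class(d))
  d
}

#' Neighbor-joining tree
#'
#' Classic NJ (Saitou-Nei Q-matrix agglomeration) with lowest-index
#' tie-breaking; negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch, so the joined pair's path length is
#' preserved. Consistent: an additive matrix returns its generating
#' topology with its exact path metric.
#'
#' @param d symmetric distance matrix with taxon names.
#' @return an unrooted `phylo` (ape) tree.
#' @export
neighbor_joining <- function(d) {
  d <- unclass(d)
  .assert(is.matrix(d) && nrow(d) == ncol(d), "need a square matrix")
  .assert(max(abs(d - t(d))) < 1e-8, "distance matrix must be symmetric")
  n <- nrow(d)
  .assert(n >= 2, "need at least 2 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (n == 2) {
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         labs[1], d[1, 2] / 2,
                                         labs[2], d[1, 2] / 2)))
  }
  node <- labs                 # newick fragment per active node
  D <- d
  while (length(node) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index (row-major) tie-breaking on the minimum of Q
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newdist <- newdist[-c(i, j)]
    merged <- sprintf("(%s:%.10g,%s:%.10g)", node[i], li, node[j], lj)
    node <- c(node[-c(i, j)], merged)
    D <- rbind(cbind(D[-c(i, j), -c(i, j), drop = FALSE], newdist),
               c(newdist, 0))
  }
  # final three nodes: closed-form star branch lengths
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 node[1], l1, node[2], l2, node[3], l3)
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate is rebuilt with [p_distance()] + [neighbor_joining()], and the
#' support of each internal edge of the point-estimate tree is the fraction
#' of replicates containing its bipartition (Felsenstein bootstrap).
#' Deterministic given `seed`.
#'
#' @param aln alignment matrix or FASTA path.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param model distance model, see [p_distance()].
#' @return a `phylo` tree whose `node.label` holds supports in `[0, 1]`
#'   (3 decimals; the root label is empty).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              model = c("raw", "JC69")) {
  model <- match.arg(model)
  .assert(n_reps >= 1, "n_reps must be >= 1")
  if (is.character(aln) && length(aln) == 1 && file.exists(aln)) {
    aln <- read_alignment(aln)
  }
  tree <- neighbor_joining(p_distance(aln, model))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    reps[[b]] <- neighbor_joining(p_distance(aln[, cols, drop = FALSE], model))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supp <- counts / n_reps
  lab <- sprintf("%.3f", supp)
  lab[1] <- ""                  # root of the unrooted representation
  tree$node.label <- lab
  attr(tree, "supports") <- supp
  tree
}

#' Write a tree to Newick
#'
#' Branch lengths are retained and bootstrap supports (if present) are
#' written as internal-node labels.
#'
#' @param t a `phylo` tree.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_newick <- function(t, path) {
  .assert(inherits(t, "phylo"), "not a phylo tree")
  ok <- try(ape::write.tree(t, file = path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write tree to ", path, call. = FALSE)
  invisible(path)
}
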