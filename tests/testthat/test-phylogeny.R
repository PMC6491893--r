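aln_fixture <- function(seqs) {
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(seqs)
  m
}

test_that("p-distance counts mismatches over comparable sites", {
  a <- aln_fixture(c(x = "ACGT", y = "ACGT", z = "AGGT"))
  d <- p_distance(a)
  expect_equal(d["x", "y"], 0)
  expect_equal(d["x", "z"], 0.25)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
})

test_that("gap and ambiguity sites are deleted pairwise", {
  a <- aln_fixture(c(x = "A-GT", y = "ACCT"))
  d <- p_distance(a)
  expect_equal(d["x", "y"], 1 / 3)
  b <- aln_fixture(c(x = "ANGT", y = "ACCT"))
  expect_equal(p_distance(b)["x", "y"], 1 / 3)
})

test_that("a pair with no comparable sites errors by name", {
  a <- aln_fixture(c(x = "AC--", y = "--GT", z = "ACGT"))
  expect_error(p_distance(a), "'x' and 'y'")
})

test_that("Jukes-Cantor correction expands p-distances", {
  a <- aln_fixture(c(x = "AAAAAAAACC", y = "AAAAAAAATT"))
  d <- p_distance(a, model = "JC69")
  expect_equal(d["x", "y"], -0.75 * log(1 - 4 * 0.2 / 3), tolerance = 1e-12)
})

test_that("NJ reconstructs the classic additive four-taxon case exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> pairwise path lengths
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  # topology AB|CD
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  # the tree metric reproduces the input exactly
  dd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(dd, d, tolerance = 1e-9)
})

test_that("two- and three-taxon cases use the closed forms", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_equal(sum(t2$edge.length), 0.4)
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(d3)
  dd <- ape::cophenetic.phylo(t3)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(dd, d3, tolerance = 1e-12)
})

test_that("non-symmetric matrices are refused", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(d), "symmetric")
})

test_that("NJ is consistent on random additive matrices", {
  for (s in 1:20) {
    n <- sample(4:12, 1)
    ra <- random_additive(n, seed = 300 + s)
    tr <- neighbor_joining(ra$dist)
    expect_equal(ape::dist.topo(tr, ra$tree), 0, ignore_attr = TRUE)
    dd <- ape::cophenetic.phylo(tr)[rownames(ra$dist), colnames(ra$dist)]
    expect_lt(max(abs(dd - ra$dist)), 1e-9)
  }
})

test_that("taxon order does not change the recovered topology", {
  ra <- random_additive(8, seed = 31)
  t1 <- neighbor_joining(ra$dist)
  perm <- sample(rownames(ra$dist))
  t2 <- neighbor_joining(ra$dist[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("NJ topology agrees with an independent implementation", {
  set.seed(32)
  for (i in 1:5) {
    x <- matrix(runif(60), 10, 6)
    rownames(x) <- paste0("t", 1:10)
    d <- as.matrix(dist(x)) / 3          # non-additive, noisy
    t1 <- neighbor_joining(d)
    t2 <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(t1, ape::unroot(t2)), 0, ignore_attr = TRUE)
  }
})

test_that("zero-homoplasy signal gives bootstrap support 1 on every internal edge", {
  aln <- perfect_signal_alignment(8)
  tr <- bootstrap_support(aln, n_reps = 50, seed = 1)
  supp <- attr(tr, "supports")[-1]       # internal edges (root excluded)
  expect_true(all(supp == 1))
})

test_that("a fixed bipartition gets support near 1/3 on pure-noise alignments", {
  set.seed(34)
  ref <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  fixed <- replicate(12, {
    aln <- matrix(sample(c("A", "C", "G", "T"), 4 * 120, replace = TRUE),
                  4, 120, dimnames = list(paste0("t", 1:4), NULL))
    reps <- lapply(1:50, function(b) {
      cols <- sample.int(120, 120, replace = TRUE)
      neighbor_joining(p_distance(aln[, cols, drop = FALSE]))
    })
    class(reps) <- "multiPhylo"
    cnt <- ape::prop.clades(ref, reps, rooted = FALSE)[2]
    if (is.na(cnt)) cnt <- 0             # bipartition absent from every replicate
    cnt / 50
  })
  expect_lt(abs(mean(fixed) - 1 / 3), 0.15)
})

test_that("bootstrap supports are deterministic given the seed", {
  ra <- random_additive(6, seed = 35)
  set.seed(36)
  aln <- matrix(sample(c("A", "C", "G", "T"), 6 * 200, replace = TRUE),
                6, 200, dimnames = list(ra$tree$tip.label, NULL))
  t1 <- bootstrap_support(aln, n_reps = 25, seed = 9)
  t2 <- bootstrap_support(aln, n_reps = 25, seed = 9)
  expect_identical(attr(t1, "supports"), attr(t2, "supports"))
})

test_that("Newick round-trip preserves bipartitions and support labels", {
  part <- setNames(rep(c("C1", "C2"), each = 4), paste0("g", 1:8))
  seqs <- coregut:::.synthetic_alignment(part, length_bp = 400, seed = 37,
                                         block_rate = 0.3, genus_rate = 0.04)
  aln <- do.call(rbind, seqs)
  tr <- bootstrap_support(aln, n_reps = 30, seed = 2)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  txt <- readLines(path)
  expect_identical(sum(lengths(regmatches(txt, gregexpr("\\(", txt)))),
                   sum(lengths(regmatches(txt, gregexpr("\\)", txt)))))
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
  labs <- back$node.label[nzchar(back$node.label)]
  expect_true(all(grepl("^[01]\\.[0-9]{3}$", labs)))
  expect_true(all(as.numeric(labs) >= 0 & as.numeric(labs) <= 1))
})
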