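write_otu_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("a small OTU TSV round-trips values and shape", {
  p <- write_otu_tsv(data.frame(otu_id = c("a", "b", "c"),
                                S1 = c(1L, 0L, 5L), S2 = c(2L, 3L, 4L)))
  t <- read_otu_table(p)
  expect_identical(dim(t$counts), c(3L, 2L))
  expect_identical(unname(t$counts["c", "S2"]), 4L)
  expect_identical(t$sample_ids, c("S1", "S2"))
})

test_that("empty and malformed OTU tables raise parse errors", {
  p <- write_otu_tsv(data.frame(otu_id = character(), S1 = integer()))
  expect_error(read_otu_table(p), "no OTUs")
  p2 <- write_otu_tsv(data.frame(otu_id = "a", S1 = -3L))
  expect_error(read_otu_table(p2), "negative")
  p3 <- write_otu_tsv(data.frame(otu_id = "a", S1 = 1.5))
  expect_error(read_otu_table(p3), "non-integer")
})

test_that("BIOM and TSV encodings of the same data yield identical tables", {
  m <- matrix(c(1L, 0L, 5L, 2L, 3L, 4L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  p_tsv <- write_otu_tsv(data.frame(otu_id = rownames(m), S1 = m[, 1],
                                    S2 = m[, 2]))
  p_biom <- tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m), p_biom)
  t1 <- read_otu_table(p_tsv)
  t2 <- read_otu_table(p_biom, format = "biom")
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$otu_ids, t2$otu_ids)
})

write_tax <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

test_that("genus confidence threshold is inclusive at the boundary", {
  p <- write_tax(c(
    "o1\tBacteria\tdomain\t1.0\tFirmicutes\tphylum\t0.95\tBlautia\tgenus\t0.80",
    "o2\tBacteria\tdomain\t1.0\tFirmicutes\tphylum\t0.95\tBlautia\tgenus\t0.49",
    "o3\tBacteria\tdomain\t1.0\tFirmicutes\tphylum\t0.95\tRoseburia\tgenus\t0.90",
    "o4\tBacteria\tdomain\t1.0\tFirmicutes\tphylum\t0.95\tRoseburia\tgenus\t0.90"))
  tax80 <- suppressMessages(read_taxonomy(p, 0.80))
  expect_identical(tax80$genus[tax80$otu_id == "o1"], "Blautia")
  tax50 <- suppressMessages(read_taxonomy(p, 0.50))
  expect_identical(tax50$genus[tax50$otu_id == "o2"], "UNASSIGNED")
  expect_identical(tax50$genus[tax50$otu_id %in% c("o3", "o4")],
                   c("Roseburia", "Roseburia"))
})

test_that("a missing genus rank maps to UNASSIGNED rather than erroring", {
  p <- write_tax("o1\tBacteria\tdomain\t1.0\tFirmicutes\tphylum\t0.95")
  expect_message(tax <- read_taxonomy(p, 0.5), "UNASSIGNED")
  expect_identical(tax$genus, "UNASSIGNED")
  expect_identical(tax$phylum, "Firmicutes")
})

test_that("read-count, presence and QC-flag filters apply at their boundaries", {
  m <- rbind(low = c(3L, 3L, 2L, 1L),     # total 9 -> removed
             ok = c(3L, 3L, 2L, 2L),      # total 10 -> kept
             chim = c(5000L, 5000L, 100L, 100L),
             fine = c(10L, 10L, 10L, 10L))
  colnames(m) <- paste0("S", 1:4)
  t <- otu_fixture(m, flags = c(chim = "chimera"))
  f <- filter_otus(t)
  expect_identical(f$otu_ids, c("ok", "fine"))
  expect_identical(f$sample_ids, t$sample_ids)
})

test_that("presence rule uses the ceiling of 1% of samples", {
  m <- matrix(0L, 2, 200, dimnames = list(c("rare", "wide"), paste0("S", 1:200)))
  m["rare", 1] <- 100L                    # present in 1 < ceil(2) samples
  m["wide", 1:2] <- 50L
  f <- filter_otus(otu_fixture(m))
  expect_identical(f$otu_ids, "wide")
})

test_that("filtering is idempotent and can empty out with an explicit error", {
  m <- matrix(rpois(50, 20), 5, 10)
  storage.mode(m) <- "integer"
  t <- otu_fixture(m)
  once <- filter_otus(t)
  expect_identical(filter_otus(once)$counts, once$counts)
  all_bad <- otu_fixture(matrix(c(1L, 1L), 1, 2))
  expect_error(filter_otus(all_bad), "empty after filtering")
})

test_that("genus collapse sums rows, pools UNASSIGNED and ignores OTU order", {
  m <- rbind(o1 = c(1L, 2L), o2 = c(3L, 4L), o3 = c(10L, 20L))
  colnames(m) <- c("S1", "S2")
  map <- c(o1 = "Blautia", o2 = "Blautia", o3 = "UNASSIGNED")
  g <- collapse_to_genus(otu_fixture(m), map)
  expect_identical(unname(g$counts["Blautia", ]), c(4L, 6L))
  expect_identical(unname(g$residual), c(10, 20))
  g2 <- collapse_to_genus(otu_fixture(m[c(3, 1, 2), ]), map)
  expect_identical(g$counts, g2$counts)
  expect_identical(g$residual, g2$residual)
})

test_that("a fully unassigned table gives zero genus rows but keeps the residual", {
  m <- rbind(o1 = c(5L, 5L))
  colnames(m) <- c("S1", "S2")
  g <- collapse_to_genus(otu_fixture(m), c(o1 = "UNASSIGNED"))
  expect_identical(nrow(g$counts), 0L)
  expect_identical(unname(g$residual), c(5, 5))
})

test_that("relative abundances divide by the full denominator including residual", {
  m <- rbind(o1 = c(25L, 25L), o2 = c(75L, 25L), o3 = c(0L, 50L))
  colnames(m) <- c("S1", "S2")
  map <- c(o1 = "A", o2 = "B", o3 = "UNASSIGNED")
  rel <- to_relative(collapse_to_genus(otu_fixture(m), map))
  expect_equal(unname(rel$rel_abund[, "S1"]), c(0.25, 0.75))
  expect_equal(unname(rel$rel_abund[, "S2"]), c(0.25, 0.25))
  expect_equal(unname(colSums(rel$rel_abund)), c(1, 0.5))
  expect_equal(unname(rel$denominators), c(100, 100))
})

test_that("relative abundance is invariant to per-sample scaling", {
  m <- matrix(c(10L, 30L, 20L, 60L), 2, 2,
              dimnames = list(c("A", "B"), c("S1", "S2")))
  rel1 <- to_relative(m)
  rel2 <- to_relative(m * 3L)
  expect_equal(rel1$rel_abund, rel2$rel_abund)
})

test_that("zero-read samples are refused by name", {
  m <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
              dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_error(to_relative(m), "S2")
})

test_that("genus totals plus residual conserve the filtered sample totals", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rpois(60, 15), 6, 10)
    storage.mode(m) <- "integer"
    t <- filter_otus(otu_fixture(m))
    genera <- sample(c("A", "B", "C", "UNASSIGNED"), nrow(t$counts),
                     replace = TRUE)
    g <- collapse_to_genus(t, setNames(genera, t$otu_ids))
    expect_equal(unname(colSums(g$counts) + g$residual),
                 unname(colSums(t$counts)))
  }
})

test_that("metadata reader enforces the required column set", {
  md <- data.frame(sample_id = c("a", "b"), dataset_id = "D",
                   age_weeks = 12L, sex = "male", strain = "X",
                   health = "healthy")
  p <- tempfile(); write.table(md, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(read_metadata(p))
  p2 <- tempfile()
  write.table(md[, setdiff(names(md), "health")], p2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_metadata(p2), "health")
})
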