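# OTU table ingestion, quality filtering, genus collapse and relative
# abundance. Filters follow the usual 16S practice: drop OTUs flagged as
# chimeras or singletons upstream, OTUs with fewer than 10 reads in total,
# and OTUs present in fewer than 1% of samples.

#' Read an OTU count table
#'
#' TSV layout: first column = OTU id, remaining columns = samples; an
#' optional `flags` column carries comma-separated QC flags (`chimera`,
#' `singleton`). BIOM v1 (JSON) input is supported through the biomformat
#' package; flags are taken from an observation-metadata field named
#' `flags` when present.
#'
#' @param path input file.
#' @param format `"tsv"` or `"biom"`.
#' @return a `coregut_otu` object: integer count matrix (OTU x sample) plus
#'   per-OTU flags.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    .assert(nrow(df) > 0, "no OTUs in %s", path)
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    flags <- rep("", length(ids))
    if ("flags" %in% names(df)) {
      flags <- as.character(df[["flags"]])
      flags[is.na(flags)] <- ""
      df <- df[, names(df) != "flags", drop = FALSE]
    }
    .assert(ncol(df) > 0, "no sample columns in %s", path)
    for (j in seq_along(df)) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(v) | v < 0 | v != floor(v))
      if (length(bad)) {
        stop(sprintf(
          "non-integer or negative count in %s, column '%s', line %d",
          path, names(df)[j], bad[1] + 1L), call. = FALSE)
      }
      df[[j]] <- as.integer(v)
    }
    counts <- as.matrix(df)
    rownames(counts) <- ids
  } else {
    .assert(requireNamespace("biomformat", quietly = TRUE),
            "the biomformat package is required for BIOM input")
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")
    storage.mode(counts) <- "integer"
    .assert(nrow(counts) > 0, "no OTUs in %s", path)
    flags <- rep("", nrow(counts))
    om <- biomformat::observation_metadata(b)
    if (!is.null(om) && "flags" %in% colnames(om)) {
      flags <- as.character(om[rownames(counts), "flags"])
      flags[is.na(flags)] <- ""
    }
    ids <- rownames(counts)
  }
  .assert(!anyDuplicated(ids), "duplicate OTU ids in %s", path)
  .assert(!anyDuplicated(colnames(counts)), "duplicate sample ids in %s", path)
  structure(list(otu_ids = ids, sample_ids = colnames(counts),
                 counts = counts, flags = setNames(flags, ids)),
            class = "coregut_otu")
}

#' Read taxonomy assignments (RDP fixed-rank style)
#'
#' Expected dialect: tab-separated lines of `otu_id` followed by repeated
#' (taxon name, rank, confidence) triplets, one triplet per rank from domain
#' down to genus. An OTU whose genus-rank confidence falls below the
#' threshold — or that lacks a genus rank altogether — maps to
#' `"UNASSIGNED"`. The threshold is inclusive (confidence equal to the
#' threshold is kept) and is typically 0.5 for 454/V3 reads and 0.8 for
#' MiSeq V3-V4 reads.
#'
#' @param path taxonomy file.
#' @param confidence_threshold genus-rank confidence cutoff, in `[0, 1]`.
#' @return data.frame with columns `otu_id`, `genus`, `phylum`,
#'   `genus_confidence`; `genus` is `"UNASSIGNED"` where below threshold.
#' @export
read_taxonomy <- function(path, confidence_threshold = 0.5) {
  .assert(confidence_threshold >= 0 && confidence_threshold <= 1,
          "confidence_threshold must lie in [0, 1]")
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) > 0, "no taxonomy rows in %s", path)
  parse_line <- function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    otu <- parts[1]
    rest <- parts[-1]
    rest <- rest[nzchar(rest)]
    genus <- "UNASSIGNED"; phylum <- NA_character_; conf <- NA_real_
    if (length(rest) >= 3) {
      trip <- matrix(rest[seq_len(3 * (length(rest) %/% 3))], ncol = 3, byrow = TRUE)
      ranks <- tolower(trip[, 2])
      ip <- which(ranks == "phylum")
      if (length(ip)) phylum <- trip[ip[1], 1]
      ig <- which(ranks == "genus")
      if (length(ig)) {
        conf <- as.numeric(trip[ig[1], 3])
        if (!is.na(conf) && conf >= confidence_threshold) genus <- trip[ig[1], 1]
      }
    }
    if (identical(genus, "UNASSIGNED")) {
      message("taxonomy: OTU ", otu, " left UNASSIGNED")
    }
    data.frame(otu_id = otu, genus = genus, phylum = phylum,
               genus_confidence = conf, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(lines, parse_line))
  .assert(!anyDuplicated(out$otu_id), "duplicate OTU ids in %s", path)
  out
}

#' Apply the standard OTU quality filters
#'
#' Removes OTUs flagged `chimera` or `singleton`, OTUs with fewer than
#' `min_reads` (default 10) reads summed over all samples, and OTUs present
#' (count >= 1) in fewer than `ceiling(min_sample_frac * n_samples)` samples
#' (default 1%). The sample set is unchanged. Idempotent.
#'
#' @param t a `coregut_otu`.
#' @param min_reads total-read floor (OTUs strictly below are dropped).
#' @param min_sample_frac presence fraction; the count of required samples
#'   uses the ceiling.
#' @return a filtered `coregut_otu`.
#' @export
filter_otus <- function(t, min_reads = 10L, min_sample_frac = 0.01) {
  .assert(inherits(t, "coregut_otu"), "not a coregut_otu")
  flagged <- grepl("chimera", t$flags) | grepl("singleton", t$flags)
  total <- rowSums(t$counts)
  n_present <- rowSums(t$counts >= 1L)
  need <- ceiling(min_sample_frac * ncol(t$counts))
  keep <- !flagged & total >= min_reads & n_present >= need
  if (!any(keep)) stop("empty after filtering: no OTUs survive", call. = FALSE)
  structure(list(otu_ids = t$otu_ids[keep],
                 sample_ids = t$sample_ids,
                 counts = t$counts[keep, , drop = FALSE],
                 flags = t$flags[keep]),
            class = "coregut_otu")
}

#' Collapse an OTU table to genus level
#'
#' Counts are summed per (genus, sample); OTUs mapping to `"UNASSIGNED"` are
#' pooled into a residual row that is excluded from the genus list but kept
#' so relative-abundance denominators cover the full filtered read total.
#'
#' @param t a `coregut_otu` (typically after [filter_otus()]).
#' @param tax taxonomy data.frame from [read_taxonomy()], or a named
#'   character vector `otu_id -> genus`.
#' @return a `coregut_genus_counts`: genus x sample integer matrix,
#'   per-sample residual (unassigned) reads, and a genus -> phylum
#'   annotation where available.
#' @export
collapse_to_genus <- function(t, tax) {
  .assert(inherits(t, "coregut_otu"), "not a coregut_otu")
  if (is.data.frame(tax)) {
    map <- setNames(tax$genus, tax$otu_id)
    phylum_map <- tapply(tax$phylum, tax$genus, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) NA_character_ else names(sort(table(x), decreasing = TRUE))[1]
    })
  } else {
    map <- tax
    phylum_map <- NULL
  }
  .assert(all(t$otu_ids %in% names(map)),
          "taxonomy missing for %d OTUs", sum(!t$otu_ids %in% names(map)))
  genus <- as.character(map[t$otu_ids])
  unass <- genus == "UNASSIGNED"
  residual <- colSums(t$counts[unass, , drop = FALSE])
  keep <- t$counts[!unass, , drop = FALSE]
  g <- genus[!unass]
  if (nrow(keep) > 0) {
    counts <- rowsum(keep, group = g)
    counts <- counts[sort(rownames(counts)), , drop = FALSE]
  } else {
    counts <- matrix(0L, 0, ncol(t$counts),
                     dimnames = list(NULL, t$sample_ids))
  }
  storage.mode(counts) <- "integer"
  phylum <- if (is.null(phylum_map)) setNames(rep(NA_character_, nrow(counts)),
                                              rownames(counts))
            else setNames(as.character(phylum_map[rownames(counts)]), rownames(counts))
  structure(list(genus_ids = rownames(counts), sample_ids = t$sample_ids,
                 counts = counts, residual = residual, phylum = phylum),
            class = "coregut_genus_counts")
}

#' Convert genus counts to relative abundances
#'
#' The per-sample denominator is the total filtered read count including the
#' genus-unassigned residual, so genus columns sum to at most 1.
#'
#' @param gc a `coregut_genus_counts`, or a bare genus x sample count matrix
#'   (residual then taken as zero).
#' @param include_residual if `FALSE`, denominators cover assigned genera
#'   only (columns then sum to exactly 1).
#' @return a `coregut_abund`: `rel_abund` matrix in `[0, 1]`, per-sample
#'   `denominators`, and the phylum annotation.
#' @export
to_relative <- function(gc, include_residual = TRUE) {
  if (is.matrix(gc)) {
    gc <- structure(list(genus_ids = rownames(gc), sample_ids = colnames(gc),
                         counts = gc, residual = rep(0, ncol(gc)),
                         phylum = setNames(rep(NA_character_, nrow(gc)),
                                           rownames(gc))),
                    class = "coregut_genus_counts")
  }
  .assert(inherits(gc, "coregut_genus_counts"), "not a coregut_genus_counts")
  denom <- colSums(gc$counts) + if (include_residual) gc$residual else 0
  zero <- which(denom == 0)
  if (length(zero)) {
    stop("zero-read sample(s): ", paste(gc$sample_ids[zero], collapse = ", "),
         call. = FALSE)
  }
  rel <- sweep(gc$counts, 2, denom, "/")
  structure(list(genus_ids = gc$genus_ids, sample_ids = gc$sample_ids,
                 rel_abund = rel, denominators = denom, phylum = gc$phylum),
            class = "coregut_abund")
}

#' Read a sample metadata table
#'
#' @param path TSV with required columns `sample_id`, `dataset_id`,
#'   `age_weeks`, `sex`, `strain`, `health`; extra columns pass through.
#' @return data.frame keyed by unique `sample_id`.
#' @export
read_metadata <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  md <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "dataset_id", "age_weeks", "sex", "strain", "health")
  missing <- setdiff(required, names(md))
  .assert(length(missing) == 0,
          "metadata missing column(s): %s", paste(missing, collapse = ", "))
  .assert(!anyDuplicated(md$sample_id), "duplicate sample_id in %s", path)
  .assert(all(nzchar(md$health)), "empty health label in %s", path)
  md
}
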