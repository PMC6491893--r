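# Prevalence-based identification of the core genus set.
#
# A genus is "core" when it is detected (relative abundance > 0) in at least
# a stated fraction of the reference samples — 50% of healthy hosts by
# default, so that taxa shared across ages, sexes and strains are retained
# even when no single cohort carries them uniformly.

#' Per-genus prevalence over a sample subset
#'
#' @param t a `coregut_abund`.
#' @param samples character vector of sample ids (defaults to all).
#' @return named vector of detection fractions in `[0, 1]`.
#' @export
prevalence <- function(t, samples = t$sample_ids) {
  .assert(inherits(t, "coregut_abund"), "not a coregut_abund")
  .assert(length(samples) > 0, "empty sample subset")
  .assert(all(samples %in% t$sample_ids), "unknown sample id(s) in subset")
  m <- t$rel_abund[, samples, drop = FALSE]
  rowMeans(m > 0)
}

#' Identify the core genus set
#'
#' Genera whose prevalence is at least `threshold` (inclusive), ordered by
#' descending prevalence with ties broken by descending mean relative
#' abundance and then by name.
#'
#' @param prev named prevalence vector from [prevalence()].
#' @param threshold prevalence cutoff in `(0, 1]`; default 0.5.
#' @param mean_abund optional named vector of mean relative abundances over
#'   the same samples, used for tie-breaking and reporting.
#' @return a `coregut_core` data.frame (`genus`, `prevalence`,
#'   `mean_abund`), with the threshold stored as an attribute.
#' @export
identify_core <- function(prev, threshold = 0.5, mean_abund = NULL) {
  .assert(threshold > 0 && threshold <= 1, "threshold must lie in (0, 1]")
  keep <- names(prev)[prev >= threshold]
  if (length(keep) == 0) message("core set is empty at threshold ", threshold)
  ma <- if (is.null(mean_abund)) setNames(rep(NA_real_, length(keep)), keep)
        else mean_abund[keep]
  ord <- order(-prev[keep], -replace(ma, is.na(ma), -Inf), keep)
  out <- data.frame(genus = keep[ord],
                    prevalence = unname(prev[keep][ord]),
                    mean_abund = unname(ma[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("coregut_core", "data.frame")
  out
}

#' Convenience: core set straight from an abundance table
#'
#' @inheritParams prevalence
#' @inheritParams identify_core
#' @return a `coregut_core`, with mean abundances over `samples`.
#' @export
core_from_table <- function(t, samples = t$sample_ids, threshold = 0.5) {
  prev <- prevalence(t, samples)
  ma <- rowMeans(t$rel_abund[, samples, drop = FALSE])
  identify_core(prev, threshold, ma)
}

#' Summarize the read share of the core set
#'
#' Per dataset, the fraction of total filtered reads (assigned genera plus
#' residual) attributed to core genera; the average over datasets is
#' reported both unweighted and pooled over reads. Also lists core genera
#' whose mean relative abundance across the given samples exceeds
#' `abund_cut` (default 1%).
#'
#' @param core a `coregut_core`.
#' @param dataset_tables named list of `coregut_genus_counts`, one per
#'   dataset (shared genus namespace).
#' @param abund a `coregut_abund` used for the mean-abundance listing, or
#'   `NULL` to skip it.
#' @param samples samples over which mean abundances are taken.
#' @param abund_cut mean relative-abundance cutoff for the listing.
#' @return list with `per_dataset` (named fractions), `average_unweighted`,
#'   `average_pooled`, and `abundant_core` (data.frame, possibly empty).
#' @export
core_summary <- function(core, dataset_tables, abund = NULL,
                         samples = NULL, abund_cut = 0.01) {
  .assert(inherits(core, "coregut_core"), "not a coregut_core")
  .assert(length(dataset_tables) > 0, "no dataset tables given")
  fr <- vapply(dataset_tables, function(gc) {
    .assert(inherits(gc, "coregut_genus_counts"), "dataset table has wrong type")
    total <- sum(gc$counts) + sum(gc$residual)
    .assert(total > 0, "dataset with zero reads")
    sum(gc$counts[rownames(gc$counts) %in% core$genus, , drop = FALSE]) / total
  }, numeric(1))
  core_reads <- vapply(dataset_tables, function(gc)
    sum(gc$counts[rownames(gc$counts) %in% core$genus, , drop = FALSE]),
    numeric(1))
  all_reads <- vapply(dataset_tables, function(gc)
    sum(gc$counts) + sum(gc$residual), numeric(1))
  abundant <- NULL
  if (!is.null(abund)) {
    if (is.null(samples)) samples <- abund$sample_ids
    ma <- rowMeans(abund$rel_abund[, samples, drop = FALSE])
    ma <- ma[names(ma) %in% core$genus]
    ma <- sort(ma[ma > abund_cut], decreasing = TRUE)
    abundant <- data.frame(genus = names(ma), mean_abund = unname(ma),
                           stringsAsFactors = FALSE)
  }
  list(per_dataset = fr,
       average_unweighted = mean(fr),
       average_pooled = sum(core_reads) / sum(all_reads),
       abundant_core = abundant)
}

#' Export a log2-transformed abundance matrix for heatmap rendering
#'
#' @param t a `coregut_abund`.
#' @param genera rows to include (default: all).
#' @param samples columns to include (default: all).
#' @param pseudocount added before the log so structural zeros stay finite.
#' @return numeric matrix `log2(rel_abund + pseudocount)`.
#' @export
log2_abundance_matrix <- function(t, genera = t$genus_ids,
                                  samples = t$sample_ids,
                                  pseudocount = 1e-6) {
  .assert(inherits(t, "coregut_abund"), "not a coregut_abund")
  log2(t$rel_abund[genera, samples, drop = FALSE] + pseudocount)
}
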