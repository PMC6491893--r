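# End-to-end orchestration: ingest -> core -> co-abundance -> ordination +
# MANOVA per contrast -> LEfSe per contrast -> phenotype correlations ->
# phylogeny, with a manifest of output checksums and (when ground truth is
# available) a recovery report.

#' Build a pipeline configuration
#'
#' @param genus_counts path to a genus x sample count TSV (first column =
#'   genus id), or `NULL` when starting from an OTU table.
#' @param otu_table,taxonomy paths for OTU-level input (TSV; taxonomy in
#'   the RDP fixed-rank dialect); used when `genus_counts` is `NULL`.
#' @param confidence genus-rank confidence threshold for taxonomy
#'   assignment (0.5 for 454/V3-style data, 0.8 for MiSeq V3-V4-style).
#' @param metadata path to the sample metadata TSV (required columns
#'   `sample_id`, `dataset_id`, `age_weeks`, `sex`, `strain`, `health`).
#' @param host_params optional TSV of host parameters (first column =
#'   sample id).
#' @param alignment optional aligned FASTA of core-genus representative
#'   sequences for the phylogeny stage.
#' @param truth optional ground-truth YAML from [truth_report()]; enables
#'   the recovery report.
#' @param contrasts list of contrasts, each
#'   `list(variable =, levels = c(a, b), dataset = NULL)`.
#' @param core_prevalence,r_min,q_max,alpha,lda_min,pheno_q the stage
#'   thresholds.
#' @param manova_k PC dimensions entering MANOVA (default 2).
#' @param pheno_k PC dimensions entering the phenotype screen (default 10).
#' @param nj_boot bootstrap replicates for the NJ tree (default 1000).
#' @param pseudocount added before log2 for heatmap exports.
#' @param seed master seed for the stochastic stages.
#' @param out_dir output directory (created; must be empty or absent).
#' @return a `coregut_config` list.
#' @export
pipeline_config <- function(genus_counts = NULL, otu_table = NULL,
                            taxonomy = NULL, confidence = 0.5,
                            metadata, host_params = NULL, alignment = NULL,
                            truth = NULL,
                            contrasts = list(),
                            core_prevalence = 0.5, r_min = 0.5,
                            q_max = 0.001, alpha = 0.05, lda_min = 2.0,
                            pheno_q = 0.1, manova_k = 2L, pheno_k = 10L,
                            nj_boot = 1000L, pseudocount = 1e-6,
                            seed = 1L, out_dir = "coregut_out") {
  .assert(!is.null(genus_counts) || (!is.null(otu_table) && !is.null(taxonomy)),
          "need either genus_counts or otu_table + taxonomy")
  .assert(core_prevalence > 0 && core_prevalence <= 1,
          "core_prevalence must lie in (0, 1]")
  .assert(r_min >= 0 && r_min <= 1 && q_max > 0 && q_max <= 1 &&
            alpha > 0 && alpha <= 1 && pheno_q > 0 && pheno_q <= 1 &&
            lda_min >= 0,
          "a threshold is out of range")
  structure(list(genus_counts = genus_counts, otu_table = otu_table,
                 taxonomy = taxonomy, confidence = confidence,
                 metadata = metadata, host_params = host_params,
                 alignment = alignment, truth = truth,
                 contrasts = contrasts,
                 core_prevalence = core_prevalence, r_min = r_min,
                 q_max = q_max, alpha = alpha, lda_min = lda_min,
                 pheno_q = pheno_q, manova_k = as.integer(manova_k),
                 pheno_k = as.integer(pheno_k),
                 nj_boot = as.integer(nj_boot), pseudocount = pseudocount,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "coregut_config")
}

#' Read a pipeline configuration from YAML
#'
#' Paths in the file are resolved relative to the file's directory.
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return a `coregut_config`.
#' @export
read_pipeline_config <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (key in c("genus_counts", "otu_table", "taxonomy", "metadata",
                "host_params", "alignment", "truth")) {
    y[[key]] <- resolve(y[[key]])
  }
  if (!is.null(y$contrasts)) {
    y$contrasts <- lapply(y$contrasts, function(ct) {
      ct$levels <- unlist(ct$levels)
      ct
    })
  }
  do.call(pipeline_config, y)
}

#' Read a genus x sample count TSV
#'
#' @param path TSV, first column = genus id, remaining columns = samples.
#' @return a `coregut_genus_counts` (residual zero).
#' @export
read_genus_table <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(nrow(df) > 0, "no genera in %s", path)
  ids <- as.character(df[[1]])
  .assert(!anyDuplicated(ids), "duplicate genus ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  .assert(all(m >= 0) && all(m == floor(m)), "counts must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  structure(list(genus_ids = ids, sample_ids = colnames(m), counts = m,
                 residual = rep(0, ncol(m)),
                 phylum = setNames(rep(NA_character_, length(ids)), ids)),
            class = "coregut_genus_counts")
}

#' Run the full analysis pipeline
#'
#' Executes ingest -> core identification -> co-abundance grouping ->
#' per-contrast ordination/MANOVA and LEfSe -> phenotype correlations ->
#' phylogeny (when an alignment is supplied), writing every stage artifact
#' into `config$out_dir` along with `run.log`, `manifest.yaml` (output
#' checksums, seed, thresholds, package version) and, when ground truth is
#' available, `recovery.yaml`. Reruns with the same config and inputs are
#' bit-identical.
#'
#' @param config a `coregut_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return (invisibly) a list with the main stage results and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "coregut_config"), "not a coregut_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon), add = TRUE)
  log <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logcon)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  log("coregut %s pipeline, seed=%d", as.character(utils::packageVersion("coregut")),
      config$seed)
  log("threshold core_prevalence=%g", config$core_prevalence)
  log("threshold r_min=%g q_max=%g", config$r_min, config$q_max)
  log("threshold alpha=%g lda_min=%g", config$alpha, config$lda_min)
  log("threshold pheno_q=%g", config$pheno_q)
  log("manova_k=%d pheno_k=%d nj_boot=%d pseudocount=%g",
      config$manova_k, config$pheno_k, config$nj_boot, config$pseudocount)

  ## --- ingest ---------------------------------------------------------
  md <- stage("ingest", read_metadata(config$metadata))
  gc <- stage("ingest", {
    if (!is.null(config$genus_counts)) {
      read_genus_table(config$genus_counts)
    } else {
      otu <- read_otu_table(config$otu_table)
      tax <- read_taxonomy(config$taxonomy, config$confidence)
      collapse_to_genus(filter_otus(otu), tax)
    }
  })
  .assert(all(md$sample_id %in% gc$sample_ids),
          "metadata sample(s) missing from the count table")
  gc$counts <- gc$counts[, md$sample_id, drop = FALSE]
  gc$residual <- gc$residual[match(md$sample_id, gc$sample_ids)]
  gc$sample_ids <- md$sample_id
  abund <- to_relative(gc)
  log("ingest: %d genera x %d samples", nrow(gc$counts), ncol(gc$counts))

  ## --- core identification -------------------------------------------
  healthy <- md$sample_id[md$health == "healthy"]
  .assert(length(healthy) > 0, "no healthy samples in metadata")
  core <- stage("core", core_from_table(abund, healthy, config$core_prevalence))
  log("core: %d genera at prevalence >= %g over %d healthy samples",
      nrow(core), config$core_prevalence, length(healthy))
  per_ds <- split(md$sample_id, md$dataset_id)
  ds_tables <- lapply(per_ds, function(s) {
    structure(list(genus_ids = gc$genus_ids, sample_ids = s,
                   counts = gc$counts[, s, drop = FALSE],
                   residual = gc$residual[match(s, gc$sample_ids)],
                   phylum = gc$phylum),
              class = "coregut_genus_counts")
  })
  summ <- stage("core", core_summary(core, ds_tables, abund, healthy))
  .write_tsv(data.frame(genus = core$genus,
                        phylum = unname(gc$phylum[core$genus]),
                        prevalence = core$prevalence,
                        mean_rel_abund = core$mean_abund),
             file.path(out, "core_genera.tsv"))
  .write_tsv(data.frame(dataset = names(summ$per_dataset),
                        core_fraction = unname(summ$per_dataset)),
             file.path(out, "core_fractions.tsv"))
  hm <- log2_abundance_matrix(abund, core$genus, healthy, config$pseudocount)
  .write_tsv(as.data.frame(hm), file.path(out, "core_heatmap_log2.tsv"),
             rownames = TRUE, rowname_header = "genus")

  ## --- co-abundance ---------------------------------------------------
  corr <- NULL; cags <- NULL
  if (nrow(core) >= 2) {
    corr <- stage("coabundance",
                  spearman_matrix(abund, healthy, core$genus,
                                  r_min = config$r_min, q_max = config$q_max))
    prev <- setNames(core$prevalence, core$genus)
    cags <- stage("coabundance", build_groups(corr, prev))
    log("coabundance: %d groups over %d core genera (sizes %s)",
        length(unique(cags$group)), nrow(cags),
        paste(as.integer(table(cags$group)[unique(cags$group)]), collapse = "/"))
    .write_tsv(significant_edges(corr, all = TRUE),
               file.path(out, "coabundance_edges.tsv"))
    .write_tsv(as.data.frame(cags), file.path(out, "coabundance_groups.tsv"))
    .write_tsv(as.data.frame(corr$rho), file.path(out, "spearman_rho.tsv"),
               rownames = TRUE, rowname_header = "genus")
    .write_tsv(intergroup_summary(cags, corr),
               file.path(out, "intergroup_summary.tsv"))
  }

  ## --- contrasts: ordination + MANOVA + LEfSe -------------------------
  contrast_results <- list()
  for (ci in seq_along(config$contrasts)) {
    ct <- config$contrasts[[ci]]
    .assert(!is.null(ct$variable) && length(ct$levels) == 2,
            "contrast %d needs a variable and exactly 2 levels", ci)
    .assert(ct$variable %in% names(md),
            "contrast %d: metadata lacks column '%s'", ci, ct$variable)
    sel <- md$sample_id[md[[ct$variable]] %in% ct$levels]
    if (!is.null(ct$dataset)) {
      sel <- intersect(sel, md$sample_id[md$dataset_id %in% ct$dataset])
    }
    cls <- md[[ct$variable]][match(sel, md$sample_id)]
    tag <- sprintf("%s_%s_vs_%s", ct$variable, ct$levels[1], ct$levels[2])
    if (length(sel) < 6 || min(table(cls)) < 3) {
      log("contrast %s skipped: too few samples", tag)
      next
    }
    res <- stage(paste0("contrast:", tag), {
      pc <- pca_abundance(abund, sel, core$genus)
      k <- min(config$manova_k, ncol(pc$scores),
               length(sel) - length(unique(cls)) - 1)
      mv <- manova_test(pc, cls, k)
      lf <- run_lefse(abund, cls, genera = core$genus, samples = sel,
                      alpha = config$alpha, lda_min = config$lda_min,
                      seed = .substream_seed(config$seed, 100 + ci))
      list(pca = pc, manova = mv, lefse = lf, samples = sel, classes = cls)
    })
    log("contrast %s: n=%d, Wilks lambda=%.4g, p=%.4g; %d genera selected",
        tag, length(sel), res$manova$wilks_lambda, res$manova$p,
        sum(res$lefse$selected))
    .write_tsv(data.frame(sample_id = rownames(res$pca$scores),
                          class = res$classes,
                          res$pca$scores[, 1:min(5, ncol(res$pca$scores)),
                                         drop = FALSE]),
               file.path(out, sprintf("pca_scores_%s.tsv", tag)))
    .write_tsv(data.frame(lambda = res$manova$wilks_lambda,
                          chi2 = res$manova$statistic, df = res$manova$df,
                          p = res$manova$p, k = res$manova$k),
               file.path(out, sprintf("manova_%s.tsv", tag)))
    lf_out <- as.data.frame(res$lefse)
    if (!is.null(cags)) {
      lf_out$group <- attr(cags, "partition")[lf_out$genus]
    }
    .write_tsv(lf_out, file.path(out, sprintf("lefse_%s.tsv", tag)))
    contrast_results[[tag]] <- res
  }

  ## --- phenotype correlations -----------------------------------------
  pheno <- NULL
  if (!is.null(config$host_params)) {
    hp <- utils::read.delim(config$host_params, check.names = FALSE,
                            stringsAsFactors = FALSE)
    rownames(hp) <- hp[[1]]
    hp <- hp[, -1, drop = FALSE]
    sel <- intersect(md$sample_id, rownames(hp))
    .assert(length(sel) >= 3, "too few samples with host parameters")
    pheno <- stage("phenotype", {
      pc <- pca_abundance(abund, sel, core$genus)
      correlate_pcs(pc, hp[sel, , drop = FALSE],
                    k_components = config$pheno_k, q_max = config$pheno_q)
    })
    log("phenotype: %d pairs tested, %d significant at q<%g",
        nrow(pheno), sum(pheno$significant), config$pheno_q)
    .write_tsv(as.data.frame(pheno), file.path(out, "phenotype_correlations.tsv"))
  }

  ## --- phylogeny ------------------------------------------------------
  tree <- NULL
  if (!is.null(config$alignment)) {
    tree <- stage("phylogeny",
                  bootstrap_support(config$alignment, n_reps = config$nj_boot,
                                    seed = .substream_seed(config$seed, 200)))
    write_newick(tree, file.path(out, "core_nj_tree.nwk"))
    log("phylogeny: %d taxa, %d bootstrap replicates",
        length(tree$tip.label), config$nj_boot)
  }

  ## --- recovery report -------------------------------------------------
  recovery <- NULL
  if (!is.null(config$truth)) {
    truth <- read_truth(config$truth)
    recovery <- list()
    inter <- intersect(core$genus, truth$core_genera)
    uni <- union(core$genus, truth$core_genera)
    recovery$core <- list(
      n_identified = nrow(core), n_planted = length(truth$core_genera),
      jaccard = if (length(uni)) length(inter) / length(uni) else 1,
      missed = setdiff(truth$core_genera, core$genus),
      spurious = setdiff(core$genus, truth$core_genera))
    if (!is.null(cags)) {
      planted <- truth$group_partition[!is.na(truth$group_partition)]
      shared <- intersect(names(planted), names(attr(cags, "partition")))
      recovery$grouping <- list(
        n_compared = length(shared),
        ari = if (length(shared) >= 2)
          .adjusted_rand(planted[shared], attr(cags, "partition")[shared])
          else NA)
    }
    if (!is.null(truth$effects) && length(contrast_results)) {
      per_ct <- lapply(names(contrast_results), function(tag) {
        res <- contrast_results[[tag]]
        ct <- config$contrasts[[which(vapply(
          config$contrasts, function(x)
            sprintf("%s_%s_vs_%s", x$variable, x$levels[1], x$levels[2]),
          "") == tag)[1]]]
        planted <- unique(as.character(
          truth$effects$genus[truth$effects$variable == ct$variable &
                                truth$effects$level %in% ct$levels]))
        planted <- intersect(planted, res$lefse$genus)
        sel <- res$lefse$genus[res$lefse$selected]
        list(contrast = tag, n_planted = length(planted),
             n_selected = length(sel),
             sensitivity = if (length(planted))
               length(intersect(sel, planted)) / length(planted) else NA,
             false_selections = length(setdiff(sel, planted)))
      })
      recovery$lefse <- per_ct
    }
    yaml::write_yaml(recovery, file.path(out, "recovery.yaml"))
    log("recovery: core jaccard=%.3f%s",
        recovery$core$jaccard,
        if (!is.null(recovery$grouping))
          sprintf(", grouping ARI=%.3f", recovery$grouping$ari) else "")
  }

  ## --- manifest --------------------------------------------------------
  files <- sort(setdiff(list.files(out), c("manifest.yaml", "run.log")))
  sums <- tools::md5sum(file.path(out, files))
  manifest <- list(
    package = "coregut",
    version = as.character(utils::packageVersion("coregut")),
    seed = config$seed,
    thresholds = list(core_prevalence = config$core_prevalence,
                      r_min = config$r_min, q_max = config$q_max,
                      alpha = config$alpha, lda_min = config$lda_min,
                      pheno_q = config$pheno_q),
    outputs = as.list(setNames(unname(sums), files)))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  log("done: %d artifacts in %s", length(files), out)

  invisible(list(out_dir = out, core = core, corr = corr, cags = cags,
                 contrasts = contrast_results, pheno = pheno, tree = tree,
                 summary = summ, recovery = recovery, manifest = manifest))
}
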