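# Bundled synthetic input sets: a tiny smoke-test fixture and a
# study-scale one (205 samples across three pseudo-datasets, 101 of them
# healthy, 120 genera, five planted co-abundance blocks).

#' Generate a bundled synthetic input set
#'
#' Writes everything [run_pipeline()] consumes: genus counts, metadata,
#' host parameters, a ground-truth record, an aligned FASTA of synthetic
#' representative sequences for the planted-block genera, and a ready
#' `config.yaml`.
#'
#' `"study"` scale emulates a three-cohort healthy/disease design: dataset
#' PRO (48 healthy male C57BL/6J at 12/24 weeks + 32 high-fat-diet mice,
#' half with a probiotic intervention), CUG (34 healthy male ICR at 4/12/24
#' weeks + 36 accelerated-postnatal-growth mice) and FMT (19 healthy
#' C57BL/6J of both sexes + 36 metabolic-syndrome mice), 205 samples in
#' total. Planted class effects raise part of block C1/C2 with age and sex
#' and deplete block C2 under disease; host parameters load on the block
#' factors (butyrate positively on C1, glucose and adiposity negatively on
#' C1/C2). `"tiny"` is a 12-sample x 15-genus smoke fixture.
#'
#' @param size `"tiny"` or `"study"`.
#' @param seed master seed.
#' @param dir output directory for the fixture files.
#' @return (invisibly) list with the file `paths`, the generated `data`,
#'   and the `config` (a `coregut_config`).
#' @export
make_fixture <- function(size = c("tiny", "study"), seed = 1L,
                         dir = tempfile("coregut_fixture_")) {
  size <- match.arg(size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  if (size == "study") {
    labs <- .study_design_labels()
    effects <- data.frame(
      genus = c("g001", "g002", "g023", "g003", "g024",
                "g023", "g024", "g025", "g023", "g029", "g033"),
      variable = c("age_group", "age_group", "age_group", "sex", "sex",
                   "health", "health", "health", "health", "health", "health"),
      level = c("wk24", "wk24", "wk24", "female", "female",
                "HFD", "HFD", "HFD", "APG", "APG", "APG"),
      log2fc = c(1, 1, -1, 1, 1, -2, -2, -2, -2, 1.5, -1.5),
      stringsAsFactors = FALSE)
    pheno <- list(
      list(name = "fasting_glucose", loadings = c(-0.6, -0.4, 0, 0, 0),
           noise_sd = 0.6),
      list(name = "cecal_butyrate", loadings = c(0.8, 0, 0, 0, 0),
           noise_sd = 0.6),
      list(name = "fasting_insulin", loadings = c(-0.5, 0, 0.3, 0, 0),
           noise_sd = 0.8),
      list(name = "eAT_body_weight", loadings = c(-0.4, -0.3, 0, 0, 0),
           noise_sd = 0.8))
    cfg <- synthetic_config(n_samples = nrow(labs), n_genera = 120L,
                            group_sizes = c(22L, 6L, 5L, 3L, 1L),
                            class_labels = labs, effects = effects,
                            pheno_defs = pheno, seed = seed)
  } else {
    labs <- data.frame(
      dataset_id = rep("TOY", 12),
      age_weeks = rep(c(4L, 12L), each = 6),
      age_group = rep(c("wk4", "wk12"), each = 6),
      sex = rep(c("male", "female"), 6),
      strain = "C57BL/6J",
      health = rep(c("healthy", "healthy", "HFD"), 4),
      stringsAsFactors = FALSE)
    effects <- data.frame(genus = c("g001", "g005"),
                          variable = c("health", "health"),
                          level = c("HFD", "HFD"),
                          log2fc = c(-2, 2), stringsAsFactors = FALSE)
    pheno <- list(
      list(name = "fasting_glucose", loadings = c(-0.6, 0, 0),
           noise_sd = 0.6),
      list(name = "cecal_butyrate", loadings = c(0.8, 0, 0),
           noise_sd = 0.6))
    cfg <- synthetic_config(n_samples = 12L, n_genera = 15L,
                            group_sizes = c(4L, 3L, 2L),
                            factor_corr = diag(3),
                            class_labels = labs, effects = effects,
                            pheno_defs = pheno, depth = 2e4, seed = seed)
  }

  sim <- generate_community(cfg)
  md <- sim$metadata

  paths <- list(
    genus_counts = file.path(dir, "genus_counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    host_params = file.path(dir, "host_params.tsv"),
    truth = file.path(dir, "truth.yaml"),
    alignment = file.path(dir, "core_alignment.fasta"),
    config = file.path(dir, "config.yaml"))

  .write_tsv(as.data.frame(sim$counts), paths$genus_counts,
             rownames = TRUE, rowname_header = "genus")
  .write_tsv(md, paths$metadata)
  .write_tsv(data.frame(sample_id = rownames(sim$host_params),
                        as.data.frame(sim$host_params)), paths$host_params)
  truth_report(sim$truth, paths$truth)
  grouped <- names(sim$truth$group_partition)[!is.na(sim$truth$group_partition)]
  .write_alignment(.synthetic_alignment(
    sim$truth$group_partition[grouped],
    seed = .substream_seed(seed, 7)), paths$alignment)

  contrasts <- if (size == "study") list(
    list(variable = "age_group", levels = c("wk12", "wk24"), dataset = "PRO"),
    list(variable = "age_group", levels = c("wk4", "wk12"), dataset = "CUG"),
    list(variable = "sex", levels = c("male", "female"), dataset = "FMT"),
    list(variable = "health", levels = c("healthy", "HFD"), dataset = "PRO"),
    list(variable = "health", levels = c("healthy", "APG"), dataset = "CUG")
  ) else list(
    list(variable = "health", levels = c("healthy", "HFD")))

  config <- pipeline_config(
    genus_counts = paths$genus_counts, metadata = paths$metadata,
    host_params = paths$host_params, alignment = paths$alignment,
    truth = paths$truth, contrasts = contrasts,
    nj_boot = if (size == "tiny") 100L else 1000L,
    seed = seed, out_dir = file.path(dir, "out"))
  ycfg <- unclass(config)
  ycfg$contrasts <- lapply(ycfg$contrasts, function(ct) {
    ct$levels <- as.list(ct$levels); ct
  })
  yaml::write_yaml(ycfg[!vapply(ycfg, is.null, TRUE)], paths$config)

  invisible(list(paths = paths, data = sim, config = config))
}

# metadata layout of the three-cohort design (205 samples, 101 healthy)
#' @noRd
.study_design_labels <- function() {
  row_block <- function(n, ds, wk, sex, strain, health)
    data.frame(dataset_id = rep(ds, n), age_weeks = rep(wk, n),
               age_group = rep(paste0("wk", wk), n), sex = rep(sex, n),
               strain = rep(strain, n), health = rep(health, n),
               stringsAsFactors = FALSE)
  rbind(
    row_block(40, "PRO", 12, "male", "C57BL/6J", "healthy"),
    row_block(8,  "PRO", 24, "male", "C57BL/6J", "healthy"),
    row_block(16, "PRO", 12, "male", "C57BL/6J", "HFD"),
    row_block(16, "PRO", 12, "male", "C57BL/6J", "HFD_probiotic"),
    row_block(11, "CUG", 4,  "male", "ICR", "healthy"),
    row_block(12, "CUG", 12, "male", "ICR", "healthy"),
    row_block(11, "CUG", 24, "male", "ICR", "healthy"),
    row_block(36, "CUG", 12, "male", "ICR", "APG"),
    row_block(10, "FMT", 8,  "male", "C57BL/6J", "healthy"),
    row_block(9,  "FMT", 8,  "female", "C57BL/6J", "healthy"),
    row_block(36, "FMT", 8,  "male", "C57BL/6J", "MS"))
}

# Synthetic aligned 16S-like sequences: a random root sequence, one
# consensus per co-abundance block, then per-genus mutations — enough
# phylogenetic signal that block members tend to cluster.
#' @noRd
.synthetic_alignment <- function(partition, length_bp = 400L, seed = 1L,
                                 block_rate = 0.12, genus_rate = 0.03) {
  set.seed(seed)
  bases <- c("a", "c", "g", "t")
  mutate <- function(s, rate) {
    hit <- stats::runif(length(s)) < rate
    s[hit] <- sample(bases, sum(hit), replace = TRUE)
    s
  }
  root <- sample(bases, length_bp, replace = TRUE)
  blocks <- unique(partition)
  consensus <- lapply(blocks, function(b) mutate(root, block_rate))
  names(consensus) <- blocks
  seqs <- lapply(names(partition), function(g)
    mutate(consensus[[partition[g]]], genus_rate))
  names(seqs) <- names(partition)
  seqs
}

#' @noRd
.write_alignment <- function(seqs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(paste(seqs[[nm]], collapse = ""), con)
  }
  invisible(path)
}
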