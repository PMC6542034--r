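# Readers and writers for the plain-text interchange formats (OTU TSV,
# genotype TSV / PLINK-RAW, phenotype CSV, kernel TSV), run configuration,
# and the end-to-end pipeline driver.

#' Read an OTU count table
#'
#' Expects a TSV whose first column is `animal_id` and remaining columns
#' are OTU ids with non-negative integer cells.
#'
#' @param path file path.
#' @return integer count matrix, animals x OTUs.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (names(df)[1L] != "animal_id")
    stop_config("first column of an OTU table must be `animal_id`")
  ids <- as.character(df[[1L]])
  check_ids(ids, "animal")
  check_ids(names(df)[-1L], "OTU")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- ids
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_config("invalid OTU count at animal '%s', OTU '%s' (must be a non-negative integer)",
                ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
  }
  storage.mode(m) <- "integer"
  m
}

#' Write an OTU count table
#' @param table count matrix (animals x OTUs).
#' @param path output TSV path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(animal_id = rownames(table), table, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an OTU taxonomy sidecar
#'
#' Two-column TSV `otu_id<TAB>lineage` mapping OTU ids to taxonomic
#' lineage strings.
#'
#' @param path file path.
#' @return named character vector (names are OTU ids).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE,
                          col.names = c("otu_id", "lineage"))
  check_ids(df$otu_id, "OTU")
  stats::setNames(as.character(df$lineage), df$otu_id)
}

#' Read a genotype table (simple TSV or PLINK-RAW)
#'
#' The simple dialect has `animal_id` followed by SNP columns with cells
#' in `{0, 1, 2, NA}`.  The PLINK-RAW dialect (header starting
#' `FID IID PAT MAT SEX PHENOTYPE`) is detected automatically; its
#' pedigree/sex/phenotype columns are skipped and `IID` is used as the
#' animal id.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"tsv"` or `"plink-raw"`.
#' @return numeric matrix animals x SNPs with `NA` for missing.
#' @export
read_genotypes <- function(path, dialect = c("auto", "tsv", "plink-raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_config("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), "[\t ]+")[[1L]]
  if (dialect == "auto")
    dialect <- if (identical(header[1:2], c("FID", "IID"))) "plink-raw" else "tsv"
  if (dialect == "plink-raw") {
    df <- data.table::fread(path, header = TRUE, data.table = FALSE)
    if (!identical(names(df)[1:6],
                   c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")))
      stop_config("not a PLINK-RAW file: expected FID IID PAT MAT SEX PHENOTYPE columns")
    ids <- as.character(df$IID)
    m <- as.matrix(df[, -(1:6), drop = FALSE])
  } else {
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    if (names(df)[1L] != "animal_id")
      stop_config("first column of a genotype TSV must be `animal_id`")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
  }
  check_ids(ids, "animal")
  storage.mode(m) <- "numeric"
  rownames(m) <- ids
  ok <- is.na(m) | m %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_config("genotype code outside {0,1,2,NA} at animal '%s', SNP '%s'",
                ids[bad[1L]], colnames(m)[bad[2L]])
  }
  m
}

#' Write a genotype table (simple TSV dialect)
#' @param gt genotype matrix.
#' @param path output path.
#' @export
write_genotypes <- function(gt, path) {
  df <- data.frame(animal_id = rownames(gt), gt, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with columns `animal_id, herd, parity, dim, <trait columns...>`.
#'
#' @param path file path.
#' @return data frame with `herd` and `parity` as factors.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  df$animal_id <- as.character(df$animal_id)
  df$herd <- factor(df$herd)
  df$parity <- factor(df$parity)
  as_phenotype_records(df)
}

#' Write a phenotype table
#' @param pheno phenotype data frame.
#' @param path output CSV path.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- pheno
  for (tr in trait_columns(out)) out[[tr]] <- fmt_num(out[[tr]])
  data.table::fwrite(out, path, sep = ",", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a relationship kernel as TSV
#'
#' Full symmetric matrix with an id header row and id first column, 10
#' significant digits (values round-trip through [read_kernel()]).
#'
#' @param K a [rel_matrix()].
#' @param path output path.
#' @export
write_kernel <- function(K, path) {
  vals <- apply(unclass(K), 2L, fmt_num)
  df <- data.frame(animal_id = rownames(K), vals, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a relationship kernel written by [write_kernel()]
#' @param path file path.
#' @param kind kernel kind (default `"G"`).
#' @return a [rel_matrix()].
#' @export
read_kernel <- function(path, kind = "G") {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  rel_matrix(m, kind = kind)
}

fmt_num <- function(x) formatC(x, digits = 10, format = "g")

# ---- run configuration -------------------------------------------------

RUN_CONFIG_KEYS <- c("otu_table", "genotypes", "phenotypes", "out_dir",
                     "traits", "min_otu_count", "min_sample_reads",
                     "min_individual_call_rate", "min_locus_call_rate",
                     "min_maf", "max_dim", "linkage", "n_val", "n_reps",
                     "seed", "log_level")

#' Build and validate a pipeline run configuration
#'
#' @param otu_table,genotypes,phenotypes input file paths.
#' @param out_dir output directory.
#' @param traits `"all"` or a character vector of trait columns.
#' @param min_otu_count,min_sample_reads OTU-table filters (defaults 10 and
#'   50000).
#' @param min_individual_call_rate,min_locus_call_rate,min_maf genotype
#'   filters (defaults 0.80, 0.95, 0.01).
#' @param max_dim maximum days in milk (default 400).
#' @param linkage dendrogram linkage (default `"complete"`).
#' @param n_val,n_reps cross-validation dimensions (defaults 50 and 10).
#' @param seed master seed (default 1).
#' @param log_level `"info"` or `"quiet"`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(otu_table, genotypes, phenotypes, out_dir,
                       traits = "all", min_otu_count = 10,
                       min_sample_reads = 50000,
                       min_individual_call_rate = 0.80,
                       min_locus_call_rate = 0.95, min_maf = 0.01,
                       max_dim = 400, linkage = "complete",
                       n_val = 50, n_reps = 10, seed = 1L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  for (p in c(otu_table, genotypes, phenotypes))
    if (!file.exists(p)) stop_config("input file not found: %s", p)
  for (v in c(min_individual_call_rate, min_locus_call_rate, min_maf))
    if (v < 0 || v > 1) stop_config("call-rate/MAF thresholds must be in [0, 1]")
  if (min_otu_count < 0 || min_sample_reads < 0 || max_dim < 1)
    stop_config("count/dim thresholds out of range")
  structure(list(otu_table = otu_table, genotypes = genotypes,
                 phenotypes = phenotypes, out_dir = out_dir, traits = traits,
                 min_otu_count = min_otu_count,
                 min_sample_reads = min_sample_reads,
                 min_individual_call_rate = min_individual_call_rate,
                 min_locus_call_rate = min_locus_call_rate,
                 min_maf = min_maf, max_dim = max_dim, linkage = linkage,
                 n_val = n_val, n_reps = n_reps, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, cfg)
}

# ---- pipeline ----------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes, in order: reading and QC filtering of the OTU table, genotype
#' and phenotype inputs; standardization of counts and cow clustering;
#' kernel construction (G, M, GxM); per-trait single-kernel REML for the
#' heritability/microbiability table; cross-validated prediction with
#' models M4-M7; and the Welch/Bonferroni model comparison.  Every stage
#' logs its input/output dimensions; all randomness flows from the config
#' seed, so two runs with the same config produce byte-identical outputs.
#'
#' Output files in `out_dir`: `descriptives.tsv`, `variance_components.tsv`
#' (trait, h2_g, se_g, boundary flags, h2_B, se_B), `cv_report.tsv` (per
#' trait: PA and RMSE per model plus the three comparison p-values with
#' significance stars), `cv_replicates.json` (replicate-level PAs/RMSEs and
#' validation ids), `cow_dendrogram.nwk` (Newick) and `run_log.txt`.
#'
#' @param config a [run_config()] or the path to a YAML config file.
#' @return invisibly, a list with the in-memory results
#'   (`descriptives`, `varcomp`, `cv_reports`, `comparisons`, `kernels`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    stop_config("`config` must be a run_config or a YAML path")
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (config$log_level == "info") message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  say("seed: %d", config$seed)

  # -- preprocess
  otus <- stage("read_otu_table", read_otu_table(config$otu_table))
  say("OTU table: %d animals x %d OTUs", nrow(otus), ncol(otus))
  otus <- stage("filter_otus",
                filter_otus(otus, config$min_otu_count, config$min_sample_reads))
  say("after OTU filters: %d animals x %d OTUs (%d animals, %d OTUs dropped)",
      nrow(otus), ncol(otus), length(attr(otus, "dropped_animals")),
      length(attr(otus, "dropped_otus")))
  gt <- stage("read_genotypes", read_genotypes(config$genotypes))
  say("genotypes: %d animals x %d SNPs", nrow(gt), ncol(gt))
  gt <- stage("filter_genotypes",
              filter_genotypes(gt, config$min_individual_call_rate,
                               config$min_locus_call_rate, config$min_maf))
  say("after genotype filters: %d animals x %d SNPs", nrow(gt), ncol(gt))
  pheno <- stage("read_phenotypes", read_phenotypes(config$phenotypes))
  pheno <- stage("filter_animals",
                 filter_animals(pheno, list(rownames(otus), rownames(gt)),
                                config$max_dim))
  say("matched animals with dim <= %g: %d", config$max_dim, nrow(pheno))
  ids <- pheno$animal_id
  otus <- otus[ids, , drop = FALSE]
  gt <- gt[ids, , drop = FALSE]

  traits <- if (identical(config$traits, "all")) trait_columns(pheno)
            else config$traits
  desc <- stage("descriptive_stats", descriptive_stats(pheno, traits))
  write_stats_tsv(desc, file.path(config$out_dir, "descriptives.tsv"))

  B <- stage("standardize_counts", standardize_counts(otus))
  D <- stage("pearson_distance", pearson_distance(B))
  dend <- stage("hierarchical_cluster", hierarchical_cluster(D, config$linkage))
  ape::write.tree(ape::as.phylo(dend),
                  file.path(config$out_dir, "cow_dendrogram.nwk"))

  # -- kernels (computed once on the full matched animal set)
  G <- stage("grm_vanraden", grm_vanraden(gt))
  M <- stage("microbial_relationship", microbial_relationship(B))
  GxM <- stage("hadamard_kernel", hadamard_kernel(M, G))
  kernels <- list(G = G, M = M, GxM = GxM)
  say("kernels built: n = %d, psd jitter G %g, M %g, GxM %g", nrow(G),
      attr(G, "psd_adjustment"), attr(M, "psd_adjustment"),
      attr(GxM, "psd_adjustment"))

  # -- variance components (models with one kernel each)
  vc <- stage("variance_components",
              microbiability_table(pheno, G = G, M = M, traits = traits))
  write_stats_tsv(vc, file.path(config$out_dir, "variance_components.tsv"))
  say("variance components estimated for %d trait(s)", nrow(vc))

  # -- cross-validation (models M4-M7 on adjusted phenotypes)
  X <- build_design_matrix(pheno)
  reports <- lapply(traits, function(tr) {
    yt <- adjust_phenotypes(pheno, X, tr)
    cross_validate(yt, kernels, n_val = config$n_val, n_reps = config$n_reps,
                   seed = sub_seed(config$seed, 7L))
  })
  names(reports) <- traits
  cmp <- stage("compare_models", compare_models(reports))
  say("cross-validation: %d trait(s) x 4 models x %d replicates; %d comparisons",
      length(traits), config$n_reps, attr(cmp, "n_comparisons"))

  write_cv_tsv(reports, cmp, file.path(config$out_dir, "cv_report.tsv"))
  write_cv_json(reports, file.path(config$out_dir, "cv_replicates.json"))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(descriptives = desc, varcomp = vc, cv_reports = reports,
                 comparisons = cmp, kernels = kernels, dendrogram = dend))
}

# numeric columns at 10 significant digits so reports round-trip exactly
write_stats_tsv <- function(df, path) {
  out <- df
  for (j in names(out)) if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

write_cv_tsv <- function(reports, cmp, path) {
  rows <- lapply(reports, function(rp) {
    row <- data.frame(trait = rp$trait)
    for (m in names(rp$models)) {
      row[[paste0("pa_", m)]] <- fmt_num(rp$models[[m]]$mean_pa)
      row[[paste0("rmse_", m)]] <- fmt_num(rp$models[[m]]$mean_rmse)
    }
    for (pr in unique(cmp$pair)) {
      sub <- cmp[cmp$trait == rp$trait & cmp$pair == pr, ]
      row[[paste0("p_", pr)]] <- paste0(fmt_num(sub$p_one_sided),
                                        ifelse(sub$significant_bonferroni, "*", ""))
    }
    row
  })
  out <- do.call(rbind, rows)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

write_cv_json <- function(reports, path) {
  payload <- lapply(reports, function(rp) list(
    trait = rp$trait,
    n_val = rp$n_val, n_reps = rp$n_reps, seed = rp$seed,
    validation_ids = rp$splits,
    models = lapply(rp$models, function(m)
      list(pa = signif(m$pa, 10), rmse = signif(m$rmse, 10)))
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
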