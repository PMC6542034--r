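# Synthetic-data generator: genotypes, rumen OTU counts, and milk-trait
# phenotypes with the covariance structure the downstream models assume
# (fixed herd/parity/lactation-curve effects plus genomic, microbial,
# interaction and residual random effects), with ground truth retained.

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic study.  The defaults
#' describe a dairy-cattle cohort of the kind the models target: 292 cows
#' in 3 herds and 2 parities sampled between 3 and 398 days in milk, 5000
#' post-QC SNPs, 3055 post-filter rumen bacterial OTUs with a few dominant
#' taxa and strong between-animal overdispersion, and a five-trait panel
#' whose genetic/microbial architectures span (0, 0) to (0.7, 0.4).
#'
#' @param n_animals number of cows (default 292).
#' @param n_snps number of SNP loci (default 5000).
#' @param n_otus number of bacterial OTUs (default 3055).
#' @param maf_range allele-frequency range, within (0, 0.5] (default
#'   c(0.05, 0.5)).
#' @param genotype_missing_rate per-entry missingness probability
#'   (default 0.01, missing completely at random).
#' @param library_size_range reads per animal, drawn uniformly (default
#'   c(50000, 100000)).
#' @param dominance_shape positive real governing how top-heavy the OTU
#'   abundance distribution is: OTU j receives Dirichlet concentration
#'   `shape * j^(-1/shape)`, so small values give a few dominant OTUs and
#'   large values an even community (default 1).
#' @param herd_count,parity_levels numbers of herds and parities
#'   (defaults 3 and 2).
#' @param dim_range days-in-milk range (default c(3, 398)).
#' @param wilmink_b1 linear days-in-milk slope of the lactation curve
#'   (trait units per day, default 0.001).
#' @param wilmink_b2 coefficient of the `exp(-0.05 * DIM)` lactation term
#'   (default 0.8).
#' @param herd_effects,parity_effects fixed-effect values per level
#'   (recycled/validated against the level counts).
#' @param intercept overall mean (default 4, a fat%-like scale).
#' @param target_h2_g,target_h2_b,target_h2_gxm per-trait variance ratios
#'   in [0, 1): sigma_c^2 / (sigma_c^2 + sigma_e^2) for the genomic,
#'   microbial and interaction components.  Vectors define a multi-trait
#'   panel (recycled to a common length); the default panel is
#'   (0,0), (0.2,0.1), (0.5,0), (0,0.4), (0.7,0.4) with no interaction.
#' @param sigma_e2 residual variance (default 1).
#' @param seed master seed; sub-streams for genotypes, OTUs, cohort
#'   structure and effects are derived from it deterministically.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 292, n_snps = 5000, n_otus = 3055,
                       maf_range = c(0.05, 0.5), genotype_missing_rate = 0.01,
                       library_size_range = c(50000, 100000),
                       dominance_shape = 1,
                       herd_count = 3, parity_levels = 2,
                       dim_range = c(3, 398),
                       wilmink_b1 = 0.001, wilmink_b2 = 0.8,
                       herd_effects = NULL, parity_effects = NULL,
                       intercept = 4,
                       target_h2_g = c(0, 0.2, 0.5, 0, 0.7),
                       target_h2_b = c(0, 0.1, 0, 0.4, 0.4),
                       target_h2_gxm = 0,
                       sigma_e2 = 1, seed = 1L) {
  n_animals <- assert_count(n_animals, "n_animals", min = 2L)
  n_snps <- assert_count(n_snps, "n_snps")
  n_otus <- assert_count(n_otus, "n_otus", min = 2L)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range must lie within (0, 0.5] with lower <= upper")
  assert_prob(genotype_missing_rate, "genotype_missing_rate")
  if (length(library_size_range) != 2L || library_size_range[1] < 1 ||
      library_size_range[1] > library_size_range[2])
    stop_config("library_size_range must be an increasing pair of counts >= 1")
  if (!is.numeric(dominance_shape) || dominance_shape <= 0)
    stop_config("dominance_shape must be a positive real")
  herd_count <- assert_count(herd_count, "herd_count")
  parity_levels <- assert_count(parity_levels, "parity_levels")
  if (length(dim_range) != 2L || dim_range[1] < 1 || dim_range[1] > dim_range[2])
    stop_config("dim_range must be an increasing pair of days >= 1")
  herd_effects <- herd_effects %||% seq(0, by = 0.3,
                                        length.out = herd_count)
  parity_effects <- parity_effects %||% seq(0, by = 0.25,
                                            length.out = parity_levels)
  if (length(herd_effects) != herd_count)
    stop_config("herd_effects must have one value per herd")
  if (length(parity_effects) != parity_levels)
    stop_config("parity_effects must have one value per parity")

  n_traits <- max(length(target_h2_g), length(target_h2_b),
                  length(target_h2_gxm))
  target_h2_g <- rep_len(target_h2_g, n_traits)
  target_h2_b <- rep_len(target_h2_b, n_traits)
  target_h2_gxm <- rep_len(target_h2_gxm, n_traits)
  for (h in c(target_h2_g, target_h2_b, target_h2_gxm))
    if (is.na(h) || h < 0 || h >= 1)
      stop_config("every target variance ratio must lie in [0, 1)")
  if (!is.numeric(sigma_e2) || sigma_e2 <= 0)
    stop_config("sigma_e2 must be positive")

  structure(list(
    n_animals = n_animals, n_snps = n_snps, n_otus = n_otus,
    maf_range = as.numeric(maf_range),
    genotype_missing_rate = as.numeric(genotype_missing_rate),
    library_size_range = as.numeric(library_size_range),
    dominance_shape = as.numeric(dominance_shape),
    herd_count = herd_count, parity_levels = parity_levels,
    dim_range = as.numeric(dim_range),
    wilmink_b1 = as.numeric(wilmink_b1), wilmink_b2 = as.numeric(wilmink_b2),
    herd_effects = as.numeric(herd_effects),
    parity_effects = as.numeric(parity_effects),
    intercept = as.numeric(intercept),
    target_h2_g = as.numeric(target_h2_g),
    target_h2_b = as.numeric(target_h2_b),
    target_h2_gxm = as.numeric(target_h2_gxm),
    sigma_e2 = as.numeric(sigma_e2), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Allele frequencies are drawn uniformly in `maf_range`; each genotype is
#' the sum of two Bernoulli allele draws; entries are set missing
#' independently with probability `missing_rate`.
#'
#' @param n_animals,n_snps dimensions.
#' @param maf_range pair of frequencies in (0, 0.5].
#' @param missing_rate per-entry missingness probability.
#' @param seed RNG seed.
#' @return integer matrix animals x SNPs with entries `{0, 1, 2, NA}`,
#'   ids as dimnames and the drawn frequencies in attribute `drawn_maf`.
#' @export
simulate_genotypes <- function(n_animals, n_snps, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1L) {
  n_animals <- assert_count(n_animals, "n_animals", min = 2L)
  n_snps <- assert_count(n_snps, "n_snps")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range must lie within (0, 0.5] with lower <= upper")
  assert_prob(missing_rate, "missing_rate")
  set.seed(seed)
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  codes <- matrix(stats::rbinom(n_animals * n_snps, size = 2L,
                                prob = rep(p, each = n_animals)),
                  nrow = n_animals,
                  dimnames = list(make_ids("animal", n_animals),
                                  make_ids("snp", n_snps)))
  if (missing_rate > 0)
    codes[stats::runif(length(codes)) < missing_rate] <- NA_integer_
  structure(codes, drawn_maf = p)
}

#' Simulate rumen OTU counts (Dirichlet-multinomial)
#'
#' Each animal's community composition is drawn from a Dirichlet whose
#' concentration vector is fixed across animals and skewed by
#' `dominance_shape` (concentration of OTU j is `shape * j^(-1/shape)`);
#' counts are then multinomial with a per-animal library size uniform in
#' `library_size_range`.  Small shapes give a top-heavy rank-abundance
#' curve and strong between-animal overdispersion.
#'
#' @param n_animals,n_otus dimensions (`n_otus >= 2`).
#' @param library_size_range pair of read counts (>= 1).
#' @param dominance_shape positive real; see [sim_config()].
#' @param seed RNG seed.
#' @return integer count matrix animals x OTUs; each row sums to its drawn
#'   library size.
#' @export
simulate_otu_counts <- function(n_animals, n_otus,
                                library_size_range = c(50000, 100000),
                                dominance_shape = 1, seed = 1L) {
  n_animals <- assert_count(n_animals, "n_animals")
  n_otus <- assert_count(n_otus, "n_otus", min = 2L)
  if (!is.numeric(dominance_shape) || dominance_shape <= 0)
    stop_config("dominance_shape must be a positive real")
  if (length(library_size_range) != 2L || library_size_range[1] < 1 ||
      library_size_range[1] > library_size_range[2])
    stop_config("library_size_range must be an increasing pair of counts >= 1")
  set.seed(seed)
  alpha <- dominance_shape * seq_len(n_otus)^(-1 / dominance_shape)
  libs <- floor(stats::runif(n_animals, library_size_range[1],
                             library_size_range[2] + 1))
  counts <- matrix(0L, n_animals, n_otus,
                   dimnames = list(make_ids("animal", n_animals),
                                   make_ids("otu", n_otus)))
  for (i in seq_len(n_animals)) {
    g <- stats::rgamma(n_otus, shape = alpha, rate = 1)
    if (sum(g) == 0) g[1L] <- 1      # pathological tiny-shape draw
    counts[i, ] <- as.integer(stats::rmultinom(1L, size = libs[i],
                                               prob = g / sum(g)))
  }
  counts
}

#' Simulate a complete study with known ground truth
#'
#' Builds the genomic (G), microbial (M) and interaction (GxM) kernels from
#' freshly simulated genotypes and OTU counts, draws per-trait random
#' effects `g ~ N(0, G s_g^2)`, `m ~ N(0, M s_m^2)`,
#' `gxm ~ N(0, (GxM) s_gxm^2)` and `e ~ N(0, I s_e^2)`, and assembles
#' phenotypes as
#' `intercept + herd + parity + b1*DIM + b2*exp(-0.05*DIM) + g + m + gxm + e`.
#' Component variances are set from the target ratios so that, e.g.,
#' `s_g^2 = sigma_e2 * h2_g / (1 - h2_g)` — the same per-model ratio
#' definition the estimation stage uses.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_study` with elements `genotypes`,
#'   `otu_counts`, `phenotypes` (data frame: animal_id, herd, parity, dim,
#'   one column per trait), `kernels` (list G, M, GxM), `truth` (per trait:
#'   true effect vectors and variances) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  gt <- simulate_genotypes(cfg$n_animals, cfg$n_snps, cfg$maf_range,
                           cfg$genotype_missing_rate,
                           seed = sub_seed(cfg$seed, 1L))
  otus <- simulate_otu_counts(cfg$n_animals, cfg$n_otus,
                              cfg$library_size_range, cfg$dominance_shape,
                              seed = sub_seed(cfg$seed, 2L))
  G <- grm_vanraden(gt)
  B <- standardize_counts(otus)
  M <- microbial_relationship(B)
  GxM <- hadamard_kernel(M, G)
  ids <- rownames(gt)

  set.seed(sub_seed(cfg$seed, 3L))
  herd <- sample.int(cfg$herd_count, cfg$n_animals, replace = TRUE)
  parity <- sample.int(cfg$parity_levels, cfg$n_animals, replace = TRUE)
  dim_days <- sample(seq(cfg$dim_range[1], cfg$dim_range[2]), cfg$n_animals,
                     replace = TRUE)
  fixed_part <- cfg$intercept + cfg$herd_effects[herd] +
    cfg$parity_effects[parity] + cfg$wilmink_b1 * dim_days +
    cfg$wilmink_b2 * exp(-0.05 * dim_days)

  # pre-factor each kernel once for multivariate-normal draws
  roots <- lapply(list(g = G, m = M, gxm = GxM), kernel_root)

  n_traits <- length(cfg$target_h2_g)
  trait_names <- sprintf("trait_%d", seq_len(n_traits))
  pheno <- data.frame(animal_id = ids, herd = factor(herd),
                      parity = factor(parity), dim = dim_days,
                      stringsAsFactors = FALSE)
  truth <- vector("list", n_traits)
  names(truth) <- trait_names
  set.seed(sub_seed(cfg$seed, 4L))
  for (t in seq_len(n_traits)) {
    s2 <- c(g = cfg$sigma_e2 * cfg$target_h2_g[t] / (1 - cfg$target_h2_g[t]),
            m = cfg$sigma_e2 * cfg$target_h2_b[t] / (1 - cfg$target_h2_b[t]),
            gxm = cfg$sigma_e2 * cfg$target_h2_gxm[t] /
              (1 - cfg$target_h2_gxm[t]))
    eff <- lapply(names(roots), function(k) {
      if (s2[[k]] == 0) numeric(cfg$n_animals)
      else drop(roots[[k]] %*% stats::rnorm(ncol(roots[[k]]))) * sqrt(s2[[k]])
    })
    names(eff) <- names(roots)
    e <- stats::rnorm(cfg$n_animals, sd = sqrt(cfg$sigma_e2))
    y <- fixed_part + eff$g + eff$m + eff$gxm + e
    pheno[[trait_names[t]]] <- y
    truth[[t]] <- list(
      true_g = eff$g, true_m = eff$m, true_gxm = eff$gxm, true_e = e,
      sigma2 = c(s2, e = cfg$sigma_e2),
      realized_variances = c(
        g = stats::var(eff$g), m = stats::var(eff$m),
        gxm = stats::var(eff$gxm), e = stats::var(e))
    )
  }

  structure(list(genotypes = gt, otu_counts = otus, phenotypes = pheno,
                 kernels = list(G = G, M = M, GxM = GxM),
                 truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d animals, %d SNPs, %d OTUs, %d trait(s)\n",
              nrow(x$genotypes), ncol(x$genotypes), ncol(x$otu_counts),
              length(x$truth)))
  invisible(x)
}

# Symmetric square root of a kernel (eigen; negative eigenvalues within the
# PSD tolerance are clamped to zero).  Used for N(0, K sigma^2) draws.
kernel_root <- function(K) {
  eg <- eigen(unclass(K), symmetric = TRUE)
  if (min(eg$values) < -PSD_TOL)
    stop_config("kernel is not positive semi-definite after jitter; cannot simulate")
  ev <- pmax(eg$values, 0)
  eg$vectors %*% (sqrt(ev) * t(eg$vectors))
}

#' Write a synthetic study to an output directory
#'
#' Produces `genotypes.tsv`, `otus.tsv`, `phenotypes.csv` and `truth.json`
#' in the formats the readers of this package accept.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(study, dir) {
  if (!inherits(study, "synthetic_study"))
    stop_config("`study` must come from simulate_study()")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genotypes(study$genotypes, file.path(dir, "genotypes.tsv"))
  write_otu_table(study$otu_counts, file.path(dir, "otus.tsv"))
  write_phenotypes(study$phenotypes, file.path(dir, "phenotypes.csv"))
  truth <- lapply(study$truth, function(tr)
    lapply(tr, function(v) unname(signif(as.numeric(v), 10))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
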