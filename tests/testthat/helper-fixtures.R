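# Small in-code fixtures shared across test files.

# a compact synthetic study for fast end-to-end style checks
small_study <- function(n = 60, n_snps = 200, n_otus = 120,
                        h2_g = 0.4, h2_b = 0.3, h2_gxm = 0, seed = 101) {
  simulate_study(sim_config(
    n_animals = n, n_snps = n_snps, n_otus = n_otus,
    library_size_range = c(5000, 8000), genotype_missing_rate = 0,
    target_h2_g = h2_g, target_h2_b = h2_b, target_h2_gxm = h2_gxm,
    seed = seed))
}

# random PSD kernel with unit-ish diagonal, animal ids attached
random_psd_kernel <- function(n, ids = make_animal_ids(n), kind = "G") {
  Z <- matrix(rnorm(n * 2 * n), n, 2 * n)
  K <- tcrossprod(Z) / (2 * n)
  dimnames(K) <- list(ids, ids)
  rel_matrix(K, kind = kind)
}

make_animal_ids <- function(n) sprintf("animal_%03d", seq_len(n))

# strip rel_matrix class/attributes down to a plain numeric matrix
as_plain <- function(K) {
  m <- unclass(K)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# minimal valid phenotype frame
toy_pheno <- function(n = 12, seed = 7) {
  set.seed(seed)
  data.frame(
    animal_id = make_animal_ids(n),
    herd = factor(sample(rep_len(1:3, n))),     # every herd represented
    parity = factor(sample(rep_len(1:2, n))),
    dim = sample(3:398, n, replace = TRUE),
    fat = rnorm(n, 4, 0.7),
    protein = rnorm(n, 3.3, 0.35))
}
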