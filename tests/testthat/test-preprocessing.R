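# QC filters, standardization, descriptive statistics, distances and
# clustering.

counts_fixture <- function() {
  m <- matrix(c(5, 4, 60000,
                4, 6, 55000,
                1, 0, 49999), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(c("a1", "a2", "a3"), c("otu1", "otu2", "otu3"))
  storage.mode(m) <- "integer"
  m
}

test_that("OTU filter applies the depth threshold then the count threshold", {
  m <- counts_fixture()
  out <- filter_otus(m)   # defaults: >=10 per OTU, >=50000 reads per animal
  # a3 has 50000 total reads -> retained? 1 + 0 + 49999 = 50000 exactly
  expect_true("a3" %in% rownames(out))
  # otu1 totals 10 over retained animals -> kept; otu2 totals 10 -> kept
  expect_equal(colnames(out), c("otu1", "otu2", "otu3"))

  # drop one read from a3: row total 49999 -> animal removed first,
  # then otu totals are computed over the remaining animals
  m2 <- m; m2["a3", "otu3"] <- 49998L
  out2 <- filter_otus(m2)
  expect_identical(attr(out2, "dropped_animals"), "a3")
  expect_false("otu1" %in% colnames(out2))  # total 9 over a1, a2
  expect_true("otu2" %in% colnames(out2))   # total 10 retained

  expect_error(filter_otus(matrix(0L, 2, 2, dimnames = list(c("x", "y"), c("o1", "o2")))),
               "reads")
})

test_that("OTU filtering is idempotent", {
  set.seed(5)
  m <- matrix(rpois(200, 40), 10, 20,
              dimnames = list(make_animal_ids(10), sprintf("otu%02d", 1:20)))
  storage.mode(m) <- "integer"
  once <- filter_otus(m, min_total_count = 30, min_sample_reads = 700)
  twice <- filter_otus(once, min_total_count = 30, min_sample_reads = 700)
  expect_equal(unclass(once), unclass(twice), ignore_attr = TRUE)
})

test_that("standardization centers and scales with the n-1 divisor", {
  m <- matrix(c(0, 10, 3, 3), 2, 2,
              dimnames = list(c("a1", "a2"), c("o1", "o2")))
  B <- standardize_counts(m)
  expect_equal(unname(B[, "o1"]), c(-0.70711, 0.70711), tolerance = 1e-4)
  expect_identical(attr(B, "dropped_otus"), "o2")   # constant column

  set.seed(6)
  m2 <- matrix(rpois(48, 20), 6, 8,
               dimnames = list(make_animal_ids(6), sprintf("o%d", 1:8)))
  B2 <- standardize_counts(m2)
  expect_lt(max(abs(colMeans(B2))), 1e-12)
  expect_lt(max(abs(apply(B2, 2, sd) - 1)), 1e-12)

  expect_error(standardize_counts(matrix(5, 3, 2, dimnames = list(letters[1:3], c("o1", "o2")))),
               "constant")
})

test_that("standardization is exactly invertible on retained columns", {
  set.seed(7)
  m <- matrix(rpois(60, 15), 6, 10,
              dimnames = list(make_animal_ids(6), sprintf("o%d", 1:10)))
  B <- standardize_counts(m)
  rebuilt <- sweep(sweep(unclass(B), 2, attr(B, "scale"), `*`),
                   2, attr(B, "center"), `+`)
  expect_equal(rebuilt, m[, colnames(B)], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("genotype filter enforces call rates and MAF in order", {
  set.seed(8)
  n <- 100
  gt <- matrix(rbinom(n * 40, 2, 0.3), n, 40,
               dimnames = list(make_animal_ids(n), sprintf("snp%d", 1:40)))
  gt[1:6, 2] <- NA            # snp2 call rate 94% -> dropped
  gt[7:11, 3] <- NA           # snp3 call rate 95% -> retained
  gt[, 4] <- 0; gt[1, 4] <- 1 # MAF = 0.005 -> dropped
  out <- filter_genotypes(gt)
  expect_false("snp2" %in% colnames(out))
  expect_true("snp3" %in% colnames(out))
  expect_false("snp4" %in% colnames(out))

  # individual with call rate below 80% is dropped before locus stats
  gt2 <- gt[, -c(2, 3, 4)]
  gt2[1, seq_len(ceiling(0.25 * ncol(gt2)))] <- NA
  out2 <- filter_genotypes(gt2)
  expect_identical(attr(out2, "dropped_animals"), rownames(gt2)[1])

  # fully observed, common alleles: pass-through
  gt3 <- matrix(rbinom(40, 2, 0.4), 10, 4,
                dimnames = list(make_animal_ids(10), sprintf("s%d", 1:4)))
  expect_equal(unclass(filter_genotypes(gt3)), gt3, ignore_attr = TRUE)
})

test_that("animal filter intersects id sets and applies the DIM cutoff", {
  ph <- toy_pheno(6)
  ph$dim <- c(401, 400, 100, 200, 300, 50)
  out <- filter_animals(ph, matched_ids = list(ph$animal_id))
  expect_false(ph$animal_id[1] %in% out$animal_id)   # dim 401 removed
  expect_true(ph$animal_id[2] %in% out$animal_id)    # dim 400 retained

  out2 <- filter_animals(ph, matched_ids = list(ph$animal_id[3:6]))
  expect_setequal(out2$animal_id, ph$animal_id[3:6])

  expect_error(filter_animals(ph, matched_ids = list("nobody")), "no animals")
})

test_that("descriptive statistics use the sample SD and report CV%", {
  ph <- toy_pheno(2)
  ph$fat <- c(1, 3)
  st <- descriptive_stats(ph, traits = "fat")
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(st$cv, 100 * sqrt(2) / 2, tolerance = 1e-12)

  ph$protein <- rep(5, 2)
  st2 <- descriptive_stats(ph, traits = "protein")
  expect_equal(st2$cv, 0)

  ph$fat <- c(-1, 1)   # mean zero -> CV undefined
  st3 <- descriptive_stats(ph, traits = "fat")
  expect_true(is.na(st3$cv))
})

test_that("Pearson distance matches 1 - r and stays in [0, 2]", {
  B <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4,
                -1, -2, -3, -4), 3, 4, byrow = TRUE,
              dimnames = list(c("a1", "a2", "a3"), NULL))
  D <- pearson_distance(B)
  expect_equal(D["a1", "a2"], 0)
  expect_equal(D["a1", "a3"], 2)
  expect_equal(diag(D), c(a1 = 0, a2 = 0, a3 = 0))

  set.seed(9)
  B2 <- matrix(rnorm(100), 5, 20, dimnames = list(make_animal_ids(5), NULL))
  D2 <- pearson_distance(B2)
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (k in 1:5) brute[i, k] <- 1 - cor(B2[i, ], B2[k, ])
  diag(brute) <- 0
  expect_equal(unname(D2), brute, tolerance = 1e-12)
  expect_true(all(D2 >= -1e-12 & D2 <= 2 + 1e-12))

  B3 <- rbind(B2, flatrow = rep(1, 20))
  expect_error(pearson_distance(B3), "flatrow")
})

test_that("hierarchical clustering merges nearest pairs first", {
  D <- matrix(1, 3, 3); diag(D) <- 0; D[1, 2] <- D[2, 1] <- 0.1
  dimnames(D) <- list(c("a", "b", "c"), c("a", "b", "c"))
  hc <- hierarchical_cluster(D)
  expect_equal(hc$height[1], 0.1)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))   # leaves a and b merge first

  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  hc2 <- hierarchical_cluster(D2)
  expect_equal(hc2$height, 0.4)

  set.seed(10)
  P <- matrix(rnorm(80), 8, 10, dimnames = list(make_animal_ids(8), NULL))
  D3 <- pearson_distance(P)
  hc3 <- hierarchical_cluster(D3, "complete")
  expect_true(all(diff(hc3$height) >= -1e-12))   # complete linkage monotone

  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(hierarchical_cluster(matrix(c(0, -1, -1, 0), 2, 2)),
               "non-negative")
})
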