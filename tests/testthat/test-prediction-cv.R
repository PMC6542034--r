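# Phenotype adjustment, GBLUP prediction, cross-validation machinery,
# Welch's t and the Bonferroni comparison table.

test_that("adjusted phenotypes are orthogonal to the design", {
  ph <- toy_pheno(40)
  X <- build_design_matrix(ph)

  # y exactly in span(X): residuals all zero
  y_lin <- drop(X %*% rnorm(ncol(X)))
  ph$lin <- y_lin
  expect_lt(max(abs(adjust_phenotypes(ph, X, "lin"))), 1e-10)

  # constant y absorbed by the intercept
  ph$const <- 5
  expect_lt(max(abs(adjust_phenotypes(ph, X, "const"))), 1e-10)

  # random y: mean zero, orthogonal to each column
  yt <- adjust_phenotypes(ph, X, "fat")
  expect_lt(abs(mean(yt)), 1e-10)
  expect_lt(max(abs(crossprod(X[names(yt), ], yt))), 1e-8)
})

test_that("GBLUP prediction matches the hand-inverted 2x2 case", {
  ids <- c("t1", "t2", "v1")
  K <- matrix(c(1, 0.2, 0.5,
                0.2, 1, 0.1,
                0.5, 0.1, 1), 3, 3, dimnames = list(ids, ids))
  K <- rel_matrix(K, "G")
  y_tr <- c(t1 = 1.4, t2 = -0.6)
  s2g <- 0.7; s2e <- 0.4
  fit <- structure(list(sigma2 = c(G = s2g, residual = s2e),
                        kernel_names = "G"), class = "vc_fit")
  pred <- gfblup_predict(y_tr, list(G = K), fit, "v1")

  V <- s2g * unclass(K)[1:2, 1:2] + s2e * diag(2)
  Vinv <- solve(V)
  mu <- sum(Vinv %*% y_tr) / sum(Vinv)
  by_hand <- mu + s2g * unclass(K)[3, 1:2] %*% Vinv %*% (y_tr - mu)
  expect_equal(unname(pred), drop(by_hand), tolerance = 1e-12)
})

test_that("zero kernel variances predict the GLS mean everywhere", {
  st <- small_study(n = 40, seed = 41)
  ids <- st$phenotypes$animal_id
  y <- setNames(rnorm(40), ids)
  fit <- structure(list(sigma2 = c(G = 0, residual = 1),
                        kernel_names = "G"), class = "vc_fit")
  pred <- gfblup_predict(y[ids[1:30]], st$kernels, fit, ids[31:40])
  expect_equal(unname(pred), rep(mean(y[ids[1:30]]), 10), tolerance = 1e-12)
})

test_that("a validation animal duplicating a training row inherits its value", {
  # kernel row of v equals that of t1 -> as residual variance vanishes the
  # conditional expectation converges to t1's centered phenotype
  ids <- c("t1", "t2", "t3", "v")
  Z <- matrix(rnorm(3 * 12), 3, 12)
  Z <- rbind(Z, Z[1, ])                      # v is a copy of t1
  K <- tcrossprod(Z) / 12
  dimnames(K) <- list(ids, ids)
  K <- rel_matrix(K, "G")
  y_tr <- c(t1 = 2.0, t2 = -1.0, t3 = 0.5)
  fit <- structure(list(sigma2 = c(G = 1, residual = 1e-9),
                        kernel_names = "G"), class = "vc_fit")
  pred <- gfblup_predict(y_tr, list(G = K), fit, "v")
  V <- unclass(K)[1:3, 1:3] + 1e-9 * diag(3)
  mu <- sum(solve(V) %*% y_tr) / sum(solve(V))
  expect_equal(unname(pred), 2.0, tolerance = 1e-3)
  expect_equal(unname(pred) - mu, 2.0 - mu, tolerance = 1e-3)
})

test_that("splits are reproducible, disjoint and exhaustive", {
  ids <- make_animal_ids(292)
  s1 <- make_cv_splits(ids, 50, 10, seed = 7)
  s2 <- make_cv_splits(ids, 50, 10, seed = 7)
  expect_identical(s1, s2)
  for (v in s1) {
    expect_equal(length(v), 50)
    expect_equal(length(setdiff(ids, v)), 242)
    expect_true(all(v %in% ids))
  }
  expect_error(make_cv_splits(ids, 292, 10, seed = 1), "smaller")
})

test_that("model nesting is consistent: M6 with zero microbial variance equals M4", {
  st <- small_study(n = 80, seed = 42)
  yt <- adjust_phenotypes(st$phenotypes, trait = "trait_1")
  splits <- make_cv_splits(names(yt), 16, 3, seed = 5)
  for (val_ids in splits) {
    tr_ids <- setdiff(names(yt), val_ids)
    fit4 <- reml_fit(yt[tr_ids], NULL,
                     list(G = align_kernel(st$kernels$G, tr_ids)))
    p4 <- gfblup_predict(yt[tr_ids], st$kernels, fit4, val_ids)
    fit6 <- fit4
    fit6$sigma2 <- c(G = fit4$sigma2[["G"]], M = 0,
                     residual = fit4$sigma2[["residual"]])
    fit6$kernel_names <- c("G", "M")
    p6 <- gfblup_predict(yt[tr_ids], st$kernels, fit6, val_ids)
    expect_equal(cor(p4, yt[val_ids]), cor(p6, yt[val_ids]),
                 tolerance = 1e-8)
  }
})

test_that("with zero variances the RMSE equals the validation SD around the mean", {
  st <- small_study(n = 50, seed = 43)
  ids <- st$phenotypes$animal_id
  set.seed(44)
  y <- setNames(rnorm(50), ids)
  fit <- structure(list(sigma2 = c(G = 0, residual = 1),
                        kernel_names = "G"), class = "vc_fit")
  val <- ids[41:50]
  pred <- gfblup_predict(y[ids[1:40]], st$kernels, fit, val)
  rmse <- sqrt(mean((pred - y[val])^2))
  expect_equal(rmse,
               sqrt(mean((y[val] - mean(y[ids[1:40]]))^2)),
               tolerance = 1e-10)
  expect_gte(rmse, 0)
})

test_that("destroying the kernel structure destroys predictive ability", {
  st <- small_study(n = 120, n_snps = 300, h2_g = 0.7, h2_b = 0, seed = 45)
  ids <- st$phenotypes$animal_id
  # noiseless genetic trait: ytilde is the true breeding value
  yt <- structure(setNames(st$truth$trait_1$true_g, ids), trait = "g_only")
  rep_true <- cross_validate(yt, st$kernels, n_val = 24, n_reps = 10,
                             seed = 46, models = "M4")
  set.seed(47)
  perm <- sample(ids)
  Gp <- unclass(st$kernels$G)[perm, perm]
  dimnames(Gp) <- list(ids, ids)
  kernels_perm <- list(G = rel_matrix(Gp, "G"))
  rep_perm <- cross_validate(yt, kernels_perm, n_val = 24, n_reps = 10,
                             seed = 46, models = "M4")
  wins <- sum(rep_true$models$M4$pa > rep_perm$models$M4$pa)
  expect_gte(wins, 9)
})

test_that("Welch's t behaves at the reference points and matches the textbook formulas", {
  a <- c(0.1, 0.2, 0.3, 0.25)
  w0 <- welch_t(a, a)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 0.5)

  b <- c(1, 2, 3); bb <- b + 10
  expect_gt(welch_t(b, bb)$p, 0.99)

  x <- c(0.30, 0.35, 0.40, 0.32, 0.38)
  y <- c(0.10, 0.15, 0.12, 0.11, 0.14)
  w <- welch_t(x, y)
  # independent textbook computation of the Welch statistic and dof
  se2 <- var(x) / 5 + var(y) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  dof_hand <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
  p_hand <- pt(t_hand, dof_hand, lower.tail = FALSE)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$dof, dof_hand, tolerance = 1e-12)
  expect_equal(w$p, p_hand, tolerance = 1e-12)

  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("comparison table enumerates 3 contrasts per trait with a strict threshold", {
  fake_report <- function(trait, shift = 0) {
    set.seed(nchar(trait) + 50)
    mods <- lapply(c(M4 = 0, M5 = 0, M6 = shift, M7 = shift),
                   function(d) {
                     pa <- rnorm(10, 0.2 + d, 0.05)
                     list(pa = pa, rmse = abs(rnorm(10, 1, 0.1)),
                          mean_pa = mean(pa))
                   })
    structure(list(trait = trait, models = mods, n_val = 50, n_reps = 10,
                   seed = 1), class = "cv_report")
  }
  reports <- lapply(sprintf("trait_%02d", 1:19), fake_report)
  cmp <- compare_models(reports)
  expect_equal(nrow(cmp), 57)
  expect_equal(attr(cmp, "n_comparisons"), 57)

  cmp1 <- compare_models(fake_report("solo"))
  expect_equal(nrow(cmp1), 3)
  # threshold is 0.05 / n_comparisons with strict inequality
  expect_equal(cmp1$significant_bonferroni, cmp1$p_one_sided < 0.05 / 3)
  expect_equal(cmp$significant_bonferroni, cmp$p_one_sided < 0.05 / 57)

  broken <- fake_report("broken")
  broken$models$M7 <- NULL
  expect_error(compare_models(broken), "M7")
})
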