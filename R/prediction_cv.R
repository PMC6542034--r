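# Two-step cross-validated prediction: phenotypes adjusted for fixed
# effects, then GBLUP/GFBLUP prediction from genomic (M4), microbial (M5),
# joint (M6) and joint-plus-interaction (M7) kernel models, with Welch's-t
# model comparison under Bonferroni correction.

CV_MODELS <- list(M4 = "G", M5 = "M", M6 = c("G", "M"),
                  M7 = c("G", "M", "GxM"))

#' Adjust phenotypes for fixed effects
#'
#' Ordinary least-squares fit of a trait on the fixed-effects design
#' (herd, parity, days in milk, Wilmink term); the residuals are the
#' adjusted phenotypes used by the prediction models.  They have mean zero
#' and are orthogonal to every design column.
#'
#' @param pheno phenotype data frame.
#' @param X design matrix from [build_design_matrix()] (built from `pheno`
#'   if `NULL`).
#' @param trait trait column name.
#' @return named numeric vector of residuals (one per non-missing animal),
#'   with attribute `trait`.
#' @export
adjust_phenotypes <- function(pheno, X = NULL, trait) {
  pheno <- as_phenotype_records(pheno)
  if (!trait %in% names(pheno)) stop_config("trait '%s' not found", trait)
  X <- X %||% build_design_matrix(pheno)
  y <- stats::setNames(pheno[[trait]], pheno$animal_id)
  keep <- !is.na(y)
  y <- y[keep]
  Xk <- X[names(y), , drop = FALSE]
  if (nrow(Xk) < ncol(Xk))
    stop_config("fewer animals (%d) than design columns (%d)", nrow(Xk), ncol(Xk))
  res <- stats::setNames(stats::lm.fit(Xk, y)$residuals, names(y))
  structure(res, trait = trait)
}

#' GBLUP prediction of validation animals from a fitted training model
#'
#' Conditional expectation of the summed random effects of the validation
#' animals given the training phenotypes, plus the GLS intercept:
#' `yhat_val = mu + sum_k s_k^2 K_(val,train) Vtrain^{-1} (y_train - mu)`
#' with `Vtrain = sum_k s_k^2 K_(train,train) + s_e^2 I`.
#'
#' @param y_train named training phenotype vector (adjusted phenotypes).
#' @param kernels named list of [rel_matrix()] covering train and
#'   validation animals; names must match `fit$kernel_names`.
#' @param fit a [reml_fit()] result estimated on the training animals.
#' @param validation_ids animal ids to predict.
#' @return named numeric vector of predictions for `validation_ids`.
#' @export
gfblup_predict <- function(y_train, kernels, fit, validation_ids) {
  if (!inherits(fit, "vc_fit")) stop_config("`fit` must come from reml_fit()")
  train_ids <- names(y_train)
  if (is.null(train_ids)) stop_config("`y_train` must be named by animal id")
  if (length(intersect(train_ids, validation_ids)))
    stop_config("training and validation sets overlap")
  all_ids <- c(train_ids, validation_ids)
  n_tr <- length(train_ids)

  s2 <- fit$sigma2
  Vtr <- diag(s2[["residual"]], n_tr)
  Kvt_sum <- matrix(0, length(validation_ids), n_tr)
  for (nm in fit$kernel_names) {
    if (!nm %in% names(kernels))
      stop_config("kernel '%s' required by the fit is missing", nm)
    K <- unclass(align_kernel(kernels[[nm]], all_ids))
    Vtr <- Vtr + s2[[nm]] * K[train_ids, train_ids, drop = FALSE]
    Kvt_sum <- Kvt_sum + s2[[nm]] * K[validation_ids, train_ids, drop = FALSE]
  }
  ch <- tryCatch(chol(Vtr), error = function(e) NULL)
  if (is.null(ch)) {
    diag(Vtr) <- diag(Vtr) + 1e-8
    ch <- tryCatch(chol(Vtr), error = function(e)
      stop_config("training covariance matrix is singular even after jitter"))
  }
  Vinv_y <- function(v) backsolve(ch, forwardsolve(t(ch), v))
  ones <- rep(1, n_tr)
  mu <- sum(Vinv_y(as.numeric(y_train)) * ones) / sum(Vinv_y(ones) * ones)
  pred <- drop(Kvt_sum %*% Vinv_y(as.numeric(y_train) - mu)) + mu
  stats::setNames(pred, validation_ids)
}

#' Reproducible cross-validation splits
#'
#' @param ids animal ids (or a count).
#' @param n_val validation-set size per replicate.
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @return list of character vectors (validation ids per replicate).
#' @export
make_cv_splits <- function(ids, n_val = 50, n_reps = 10, seed = 1L) {
  if (length(ids) == 1L && is.numeric(ids)) ids <- make_ids("animal", ids)
  n <- length(ids)
  n_val <- assert_count(n_val, "n_val")
  if (n_val >= n)
    stop_config("n_val (%d) must be smaller than the number of animals (%d)",
                n_val, n)
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) sort(sample(ids, n_val)))
}

#' Cross-validated predictive ability of the kernel models
#'
#' For each replicate, a validation set is drawn at random; for each model
#' (M4: G; M5: M; M6: G + M; M7: G + M + GxM) the variance components are
#' re-estimated on the training animals with an intercept-only design,
#' the validation animals are predicted by [gfblup_predict()], and the
#' Pearson correlation (predictive ability, PA) and root-mean-square error
#' between predicted and observed adjusted phenotypes are recorded.
#' Splits are identical across models, so model contrasts are paired.
#'
#' @param ytilde adjusted phenotype vector from [adjust_phenotypes()].
#' @param kernels named list with elements `G`, `M` and (for M7) `GxM`.
#' @param n_val validation animals per replicate (default 50).
#' @param n_reps replicates (default 10).
#' @param seed RNG seed for the splits.
#' @param models subset of `c("M4", "M5", "M6", "M7")` to run (default all).
#' @return object of class `cv_report`: list with `trait`, `models` (per
#'   model: `pa` and `rmse` vectors over replicates, `mean_pa`,
#'   `mean_rmse`), `splits`, `n_val`, `seed`.
#' @export
cross_validate <- function(ytilde, kernels, n_val = 50, n_reps = 10,
                           seed = 1L, models = names(CV_MODELS)) {
  ids <- names(ytilde)
  if (is.null(ids)) stop_config("`ytilde` must be named by animal id")
  models <- match.arg(models, names(CV_MODELS), several.ok = TRUE)
  needed <- unique(unlist(CV_MODELS[models]))
  miss <- setdiff(needed, names(kernels))
  if (length(miss))
    stop_config("missing kernel(s): %s", paste(miss, collapse = ", "))
  splits <- make_cv_splits(ids, n_val, n_reps, seed)

  res <- lapply(models, function(m) list(pa = numeric(n_reps),
                                         rmse = numeric(n_reps)))
  names(res) <- models
  for (r in seq_len(n_reps)) {
    val_ids <- splits[[r]]
    train_ids <- setdiff(ids, val_ids)
    y_tr <- ytilde[train_ids]
    y_val <- ytilde[val_ids]
    for (m in models) {
      ks <- kernels[CV_MODELS[[m]]]
      fit <- reml_fit(y_tr, X = NULL,
                      kernels = lapply(ks, align_kernel, ids = train_ids))
      pred <- gfblup_predict(y_tr, kernels, fit, val_ids)
      if (stats::sd(pred) < 1e-12) {
        warning(sprintf("model %s replicate %d: constant predictions; PA set to 0",
                        m, r), call. = FALSE)
        res[[m]]$pa[r] <- 0
      } else {
        res[[m]]$pa[r] <- stats::cor(pred, y_val)
      }
      res[[m]]$rmse[r] <- sqrt(mean((pred - y_val)^2))
    }
  }
  for (m in models) {
    res[[m]]$mean_pa <- mean(res[[m]]$pa)
    res[[m]]$mean_rmse <- mean(res[[m]]$rmse)
  }
  structure(list(trait = attr(ytilde, "trait") %||% "trait",
                 models = res, splits = splits, n_val = n_val,
                 n_reps = n_reps, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> trait %s, %d replicates of %d validation animals\n",
              x$trait, x$n_reps, x$n_val))
  for (m in names(x$models))
    cat(sprintf("  %s: mean PA %.3f (RMSE %.3f)\n", m,
                x$models[[m]]$mean_pa, x$models[[m]]$mean_rmse))
  invisible(x)
}

#' Welch's unequal-variance t test (one-sided)
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`,
#' returning the statistic, Welch-Satterthwaite degrees of freedom and the
#' one-sided p-value for `mean(a) > mean(b)`.
#'
#' @param a,b numeric vectors of replicate predictive abilities (each with
#'   at least 2 values).
#' @param alternative passed to `t.test` (default `"greater"`).
#' @return list with `t`, `dof`, `p`.
#' @export
welch_t <- function(a, b, alternative = "greater") {
  if (length(a) < 2L || length(b) < 2L)
    stop_config("each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop_config("both samples have zero variance; t statistic undefined")
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Pairwise model comparisons across traits with Bonferroni correction
#'
#' Performs the three one-sided contrasts per trait — M6 over M4 (does the
#' microbiome add predictive information?), M6 over M5 (does the genome?),
#' M7 over M6 (does the interaction?) — with the richer model on the
#' `greater` arm.  The Bonferroni threshold divides 0.05 by the total
#' number of comparisons across all traits (strict inequality), e.g. 57
#' for a 19-trait panel.
#'
#' @param reports list of [cross_validate()] results (one per trait), each
#'   containing models M4-M7.
#' @param alpha familywise level (default 0.05).
#' @return data frame of class `model_comparison`: `trait`, `pair`,
#'   `t_statistic`, `dof`, `p_one_sided`, `significant_bonferroni`;
#'   attribute `n_comparisons`.
#' @export
compare_models <- function(reports, alpha = 0.05) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  contrasts <- list(M4vsM6 = c("M6", "M4"),
                    M5vsM6 = c("M6", "M5"),
                    M6vsM7 = c("M7", "M6"))
  rows <- list()
  for (rep_ in reports) {
    miss <- setdiff(unique(unlist(contrasts)), names(rep_$models))
    if (length(miss))
      stop_config("trait '%s' lacks model(s): %s", rep_$trait,
                  paste(miss, collapse = ", "))
    for (nm in names(contrasts)) {
      pair <- contrasts[[nm]]
      wt <- welch_t(rep_$models[[pair[1L]]]$pa, rep_$models[[pair[2L]]]$pa)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = rep_$trait, pair = nm, t_statistic = wt$t, dof = wt$dof,
        p_one_sided = wt$p)
    }
  }
  out <- do.call(rbind, rows)
  n_comp <- nrow(out)
  out$significant_bonferroni <- out$p_one_sided < alpha / n_comp
  rownames(out) <- NULL
  structure(out, n_comparisons = n_comp,
            class = c("model_comparison", "data.frame"))
}
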