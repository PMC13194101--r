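# Nested cross-validated discrimination of aMCI vs HC from the Route
# Efficiency construction, plus single-variable ROC analyses. All fitted
# transformations (standardization, PCA, orientation, logistic model) are
# learned on training folds only.

#' Empirical AUC (Mann-Whitney identity)
#'
#' Rank-based AUC of `scores` for detecting `positive` labels:
#' U / (n1 * n2) with midranks for ties.
#'
#' @param scores numeric predictor (higher = more like `positive`)
#' @param labels class labels
#' @param positive positive class label
#' @return AUC in [0, 1]; `NA` with a warning for a constant predictor
#' @export
empirical_auc <- function(scores, labels, positive = "aMCI") {
  x <- scores[labels == positive]
  y <- scores[labels != positive]
  if (!length(x) || !length(y)) stop("both classes must be present")
  if (length(unique(c(x, y))) == 1L) {
    warning("constant predictor; AUC undefined")
    return(NA_real_)
  }
  r <- rank(c(x, y))
  n1 <- length(x)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * length(y))
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer members than folds")
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

# One train/test split: standardize, PCA, orient, logistic on PC1; returns
# held-out predicted probabilities of the positive class.
cv_fold_scores <- function(Xtr, ytr, Xte) {
  res <- pca_corr(Xtr)
  v <- orient_pc1(res$loadings, colnames(Xtr))
  ztr <- sweep(sweep(Xtr, 2, res$means), 2, res$sds, "/")
  zte <- sweep(sweep(Xte, 2, res$means), 2, res$sds, "/")
  str_ <- -as.numeric(ztr %*% v)  # Route Efficiency convention
  ste <- -as.numeric(zte %*% v)
  dtr <- data.frame(y = ytr, s = str_)
  fit <- suppressWarnings(stats::glm(y ~ s, data = dtr,
                                     family = stats::binomial()))
  # quasi-separation may inflate coefficients; ranks (hence AUC) stay defined
  list(prob = as.numeric(stats::predict(fit, data.frame(s = ste),
                                        type = "response")),
       converged = fit$converged)
}

#' Nested cross-validated AUC for aMCI detection
#'
#' For each of `reps` repetitions, participants (complete cases) are
#' partitioned into `k` stratified folds. Per fold, the five global metrics
#' are standardized with training means/SDs, PCA is fitted on the training
#' rows only, PC1 is oriented with the deterministic sign rule, held-out rows
#' are projected, and a logistic model of group on the training PC1 score is
#' applied to the held-out rows. The reported AUC is the mean over all
#' `k * reps` fold-level AUCs (`aggregate = "fold"`); the pooled-prediction
#' variant is available with `aggregate = "pooled"`.
#'
#' @param summaries participant summary data.frame with a `group` column
#' @param k number of folds
#' @param reps number of repetitions
#' @param seed RNG seed (NULL = use current state)
#' @param aggregate "fold" (mean of fold AUCs) or "pooled" (single AUC on all
#'   held-out predictions)
#' @param vars variables entering the fold-internal PCA
#' @return object of class `vm_cv_result`: `auc`, `fold_aucs`
#'   (reps x k matrix), `pooled_scores` (mean held-out probability per
#'   participant), `n`, `aggregate`, `n_nonconverged`
#' @export
nested_cv_auc <- function(summaries, k = 5, reps = 10, seed = NULL,
                          aggregate = c("fold", "pooled"), vars = RE_VARS) {
  aggregate <- match.arg(aggregate)
  stopifnot(k >= 2)
  if (!is.null(seed)) set.seed(seed)
  X <- re_matrix(summaries, vars)
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  labels <- summaries$group[cc]
  if (length(unique(labels)) != 2L) stop("both classes must be present")
  y <- as.integer(labels == "aMCI")
  n <- nrow(X)

  fold_aucs <- matrix(NA_real_, reps, k)
  pooled_prob <- matrix(NA_real_, n, reps)
  nonconv <- 0L
  for (r in seq_len(reps)) {
    fold <- stratified_folds(labels, k)
    for (f in seq_len(k)) {
      te <- fold == f
      sc <- cv_fold_scores(X[!te, , drop = FALSE], y[!te],
                           X[te, , drop = FALSE])
      if (!sc$converged) nonconv <- nonconv + 1L
      pooled_prob[te, r] <- sc$prob
      fold_aucs[r, f] <- empirical_auc(sc$prob, labels[te])
    }
  }
  pooled_scores <- rowMeans(pooled_prob)
  auc <- if (aggregate == "fold") mean(fold_aucs)
         else empirical_auc(pooled_scores, labels)
  structure(list(auc = auc, fold_aucs = fold_aucs,
                 pooled_scores = data.frame(
                   participant_id = rownames(X),
                   group = labels, score = pooled_scores),
                 n = n, k = k, reps = reps, aggregate = aggregate,
                 n_nonconverged = nonconv),
            class = "vm_cv_result")
}

#' Bootstrap confidence interval for the nested-CV AUC
#'
#' `method = "participant"` (default): resample participants with
#' replacement, stratified by class, and recompute the full nested-CV mean
#' AUC per bootstrap sample (with `reps` repetitions per sample, typically
#' reduced relative to the point estimate for tractability).
#' `method = "pooled"`: run the nested CV once, then bootstrap the pooled
#' per-participant held-out scores. Percentile 2.5/97.5 interval either way.
#'
#' @param summaries participant summary data.frame with a `group` column
#' @param k folds
#' @param reps CV repetitions per bootstrap sample (participant method) or
#'   for the single CV run (pooled method)
#' @param n_boot bootstrap iterations
#' @param seed RNG seed
#' @param method "participant" or "pooled"
#' @return list with `low`, `high`, `method`, `boot_aucs`
#' @export
bootstrap_auc_ci <- function(summaries, k = 5, reps = 2, n_boot = 1000,
                             seed = NULL, method = c("participant", "pooled")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  X <- re_matrix(summaries)
  cc <- stats::complete.cases(X)
  summ_cc <- summaries[cc, , drop = FALSE]
  labels <- summ_cc$group
  boot_aucs <- numeric(n_boot)
  if (method == "pooled") {
    cv <- nested_cv_auc(summ_cc, k = k, reps = max(reps, 10))
    sc <- cv$pooled_scores
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(nrow(sc), replace = TRUE)
        if (length(unique(sc$group[idx])) == 2L) break
      }
      boot_aucs[b] <- empirical_auc(sc$score[idx], sc$group[idx])
    }
  } else {
    idx_by_class <- split(seq_len(nrow(summ_cc)), labels)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(idx_by_class, function(ii)
        sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
      bs <- summ_cc[idx, , drop = FALSE]
      bs$participant_id <- sprintf("B%03d", seq_len(nrow(bs)))
      cv <- tryCatch(nested_cv_auc(bs, k = k, reps = reps),
                     error = function(e) NULL)
      boot_aucs[b] <- if (is.null(cv)) NA_real_ else cv$auc
    }
    boot_aucs <- boot_aucs[!is.na(boot_aucs)]
  }
  qs <- stats::quantile(boot_aucs, c(0.025, 0.975), names = FALSE,
                        na.rm = TRUE)
  list(low = qs[1], high = qs[2], method = method, boot_aucs = boot_aucs)
}

#' Single-variable AUCs
#'
#' Empirical (rank) AUC of each global participant-level metric for
#' detecting aMCI, oriented so the reported AUC is >= 0.5, with the
#' direction stated explicitly. Constant variables are flagged undefined.
#'
#' @param summaries participant summary data.frame with a `group` column
#' @param vars variables (global level)
#' @return data.frame: variable, auc, direction
#' @export
single_variable_aucs <- function(summaries,
                                 vars = c(RE_VARS, "target_total")) {
  rows <- lapply(vars, function(v) {
    col <- paste0(v, "_global")
    x <- summaries[[col]]
    ok <- !is.na(x)
    a <- suppressWarnings(empirical_auc(x[ok], summaries$group[ok]))
    if (is.na(a)) {
      return(data.frame(variable = v, auc = NA_real_,
                        direction = "undefined (constant variable)"))
    }
    if (a >= 0.5) data.frame(variable = v, auc = a,
                             direction = "higher in aMCI")
    else data.frame(variable = v, auc = 1 - a, direction = "lower in aMCI")
  })
  do.call(rbind, rows)
}
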