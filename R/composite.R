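# Route Efficiency composite: correlation-matrix PCA of the five continuous
# participant-level metrics, sign-oriented and inverted so higher = better,
# plus the association and effect-size analyses.

RE_VARS <- c("path_length", "latency", "path_distance_ratio",
             "quadrant_crossings", "time_in_target_quadrant")

re_matrix <- function(summaries, vars = RE_VARS) {
  cols <- paste0(vars, "_global")
  miss <- setdiff(cols, names(summaries))
  if (length(miss)) stop("missing summary columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(summaries[, cols])
  colnames(m) <- vars
  rownames(m) <- summaries$participant_id
  m
}

# Eigendecomposition of the correlation matrix of X (columns = variables).
pca_corr <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  zero <- which(sdev == 0)
  if (length(zero))
    stop("zero-variance variable(s): ", paste(colnames(X)[zero], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  ee <- eigen(stats::cor(Z), symmetric = TRUE)
  list(means = mu, sds = sdev, loadings = ee$vectors,
       eigenvalues = pmax(ee$values, 0))
}

#' PCA of standardized participant-level navigation means
#'
#' Correlation-matrix PCA of the five continuous global metrics on
#' complete-case participants (listwise deletion). Each variable is
#' z-standardized with the complete-case mean/SD and the correlation matrix
#' eigendecomposed; PC1 is retained and a flag records whether it is the
#' only eigenvalue above 1 (Kaiser criterion).
#'
#' @param summaries participant summary data.frame
#' @param vars variables entering the PCA (defaults to the five continuous
#'   metrics)
#' @param min_complete minimum number of complete cases (stability guard)
#' @return object of class `vm_pca`: variable names, `means`, `sds`,
#'   `loadings` (columns unit-norm), `eigenvalues`, `var_share`,
#'   `retained = 1`, `kaiser_only_pc1`, `n_complete`, `complete_ids`
#' @export
fit_pca <- function(summaries, vars = RE_VARS, min_complete = 6L) {
  X <- re_matrix(summaries, vars)
  cc <- stats::complete.cases(X)
  if (sum(cc) < min_complete)
    stop("need at least ", min_complete, " complete cases, got ", sum(cc))
  res <- pca_corr(X[cc, , drop = FALSE])
  ev <- res$eigenvalues
  structure(list(
    variables = vars,
    means = res$means,
    sds = res$sds,
    loadings = res$loadings,
    eigenvalues = ev,
    var_share = ev / sum(ev),
    retained = 1L,
    kaiser_only_pc1 = (ev[1] > 1) && all(ev[-1] <= 1),
    n_complete = sum(cc),
    complete_ids = rownames(X)[cc]
  ), class = "vm_pca")
}

# Deterministic PC1 orientation: positive path-length loading (the
# "inefficiency" axis); fall back to a negative time-in-target-quadrant
# loading when the path-length loading is exactly zero.
orient_pc1 <- function(loadings, variables) {
  v <- loadings[, 1]
  ipl <- match("path_length", variables)
  itq <- match("time_in_target_quadrant", variables)
  if (!is.na(ipl) && v[ipl] != 0) {
    if (v[ipl] < 0) v <- -v
  } else if (!is.na(itq) && v[itq] != 0) {
    if (v[itq] > 0) v <- -v
  } else {
    stop("cannot orient PC1: anchor loadings are zero")
  }
  v
}

#' Route Efficiency scores from a fitted PCA
#'
#' Projects the standardized metrics onto PC1 oriented so the path-length
#' loading is positive, then inverts the score: Route Efficiency =
#' -(oriented PC1 score), so higher values reflect better navigation.
#' Participants with missing variables get `NA`.
#'
#' @param pca a `vm_pca`
#' @param summaries participant summary data.frame
#' @return data.frame: participant_id, route_efficiency (and group if
#'   present in `summaries`)
#' @export
orient_and_score <- function(pca, summaries) {
  X <- re_matrix(summaries, pca$variables)
  v <- orient_pc1(pca$loadings, pca$variables)
  Z <- sweep(sweep(X, 2, pca$means), 2, pca$sds, "/")
  score <- -as.numeric(Z %*% v)
  out <- data.frame(participant_id = summaries$participant_id,
                    route_efficiency = score)
  if ("group" %in% names(summaries)) out$group <- summaries$group
  out
}

# Pearson partial correlation of x and y controlling for covariates (matrix z).
partial_cor <- function(x, y, z) {
  z <- as.matrix(z)
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  r <- stats::cor(rx, ry)
  n <- length(x)
  k <- ncol(z)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df))
}

spearman <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  # internal cross-check: Spearman rho equals Pearson on midranks
  stopifnot(abs(unname(ct$estimate) - stats::cor(rank(x), rank(y))) < 1e-10)
  data.frame(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Associations between Route Efficiency and cognitive scores
#'
#' Spearman correlations of Route Efficiency with MoCA and MoCA-MIS on the
#' full sample and within each group (skipped with a notice for groups of
#' fewer than 3), Pearson partial correlations controlling for a binary
#' group indicator, and the covariate-adjusted group effect from the linear
#' model `route_efficiency ~ group + sex + age + education`.
#'
#' @param scores data.frame from [orient_and_score()]
#' @param cohort cohort data.frame
#' @return list with `spearman` (data.frame), `partial` (data.frame) and
#'   `adjusted_group` (data.frame with beta, se, p for the aMCI indicator)
#' @export
associate <- function(scores, cohort) {
  d <- merge(scores, cohort, by = "participant_id")
  d <- d[!is.na(d$route_efficiency), ]
  grp <- if ("group.x" %in% names(d)) "group.x" else "group"
  d$group <- d[[grp]]
  sp <- list()
  pc <- list()
  for (v in c("moca", "moca_mis")) {
    s <- spearman(d$route_efficiency, d[[v]])
    sp[[length(sp) + 1L]] <- cbind(data.frame(score = v, sample = "full"), s)
    for (g in c("HC", "aMCI")) {
      dg <- d[d$group == g, ]
      if (nrow(dg) < 3L) {
        message("within-group correlation skipped for ", g, " (n < 3)")
        next
      }
      s <- spearman(dg$route_efficiency, dg[[v]])
      sp[[length(sp) + 1L]] <- cbind(data.frame(score = v, sample = g), s)
    }
    p <- partial_cor(d$route_efficiency, d[[v]],
                     as.numeric(d$group == "aMCI"))
    pc[[length(pc) + 1L]] <- data.frame(score = v, partial_r = p$r,
                                        p_value = p$p)
  }
  d$group_f <- factor(d$group, levels = c("HC", "aMCI"))
  d$sex_f <- as.numeric(d$sex == "M")
  fit <- stats::lm(route_efficiency ~ group_f + sex_f + age + education_years,
                   data = d)
  ct <- stats::coef(summary(fit))["group_faMCI", ]
  list(spearman = do.call(rbind, sp),
       partial = do.call(rbind, pc),
       adjusted_group = data.frame(beta = ct[1], se = ct[2],
                                   p_value = ct[4], row.names = NULL))
}

#' Cohen's d and post-hoc power for the Route Efficiency group difference
#'
#' d = (mean HC - mean aMCI) / pooled SD (n-1 weights). Post-hoc power of the
#' two-sided two-sample t test at level `alpha` with the observed d and group
#' sizes, computed from the noncentral t distribution.
#'
#' @param scores data.frame with route_efficiency and group columns
#' @param alpha significance level
#' @return list with `d`, `power`, group means/SEs and ns
#' @export
effect_size_and_power <- function(scores, alpha = 0.05) {
  x <- scores$route_efficiency[scores$group == "HC"]
  y <- scores$route_efficiency[scores$group == "aMCI"]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled SD")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  tc <- stats::qt(1 - alpha / 2, df)
  power <- 1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  list(d = d, power = power,
       mean_hc = mean(x), se_hc = stats::sd(x) / sqrt(n1), n_hc = n1,
       mean_amci = mean(y), se_amci = stats::sd(y) / sqrt(n2), n_amci = n2,
       power_method = "noncentral t, two-sided two-sample t test")
}
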