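#' Binarize a CGI-S score
#'
#' CGI-S of 4 or less is low severity; above 4 is high severity.
#'
#' @param score integer vector with values in 1..7
#' @return factor with levels `low`, `high`
#' @export
binarize_cgis <- function(score) {
  score <- as.integer(score)
  if (any(!score %in% 1:7)) stop("CGI-S scores must be integers in 1..7")
  factor(ifelse(score <= 4, "low", "high"), levels = c("low", "high"))
}

#' Labelled patient-visit feature table
#'
#' @param features numeric matrix or data.frame, rows = patient-visits,
#'   named columns
#' @param patient_id character vector, one per row
#' @param label factor (`low`/`high`) or CGI-S integer scores 1..7
#' @param family character vector tagging each column with its feature
#'   family: "HRV", "ACT", "MSTE" or "MSNR"
#' @return a `feature_table`
#' @export
feature_table <- function(features, patient_id, label, family) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) stop("feature columns must be named")
  if (nrow(X) != length(patient_id)) stop("patient_id length mismatch")
  if (length(family) != ncol(X)) stop("family tag per column required")
  if (!all(family %in% c("HRV", "ACT", "MSTE", "MSNR"))) {
    stop("families must be HRV, ACT, MSTE or MSNR")
  }
  if (is.numeric(label)) label <- binarize_cgis(label)
  label <- factor(label, levels = c("low", "high"))
  if (nrow(X) != length(label)) stop("label length mismatch")
  if (anyNA(X)) stop("feature table must have no missing values")
  structure(list(X = X, patient_id = as.character(patient_id),
                 label = label, family = family),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d visits x %d features (%s), %d patients\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", names(table(x$family)),
                            table(x$family)), collapse = " "),
              length(unique(x$patient_id))))
  invisible(x)
}

#' Enumerate the 15 feature-family combinations
#'
#' All non-empty subsets of {HRV, ACT, MSTE, MSNR}, in the order:
#' singletons, pairs, triples, all four.
#'
#' @return named list of 15 character vectors
#' @export
enumerate_combinations <- function() {
  fam <- c("HRV", "ACT", "MSTE", "MSNR")
  combos <- list(
    fam[1], fam[2], fam[3], fam[4],
    fam[c(1, 2)], fam[c(1, 3)], fam[c(1, 4)], fam[c(2, 3)],
    fam[c(2, 4)], fam[c(3, 4)],
    fam[c(1, 2, 3)], fam[c(1, 2, 4)], fam[c(1, 3, 4)], fam[c(2, 3, 4)],
    fam)
  names(combos) <- vapply(combos, paste, "", collapse = "+")
  combos
}

#' Pooled rank-based AUC
#'
#' Probability that a random high-severity visit scores above a random
#' low-severity one; ties get half credit (Mann-Whitney).
#'
#' @param probs predicted probabilities of the high class
#' @param labels factor `low`/`high` (or coercible)
#' @return AUC in `[0, 1]`
#' @export
pooled_auc <- function(probs, labels) {
  labels <- factor(labels, levels = c("low", "high"))
  n_hi <- sum(labels == "high")
  n_lo <- sum(labels == "low")
  if (n_hi == 0 || n_lo == 0) stop("both classes must be present")
  r <- rank(probs)
  (sum(r[labels == "high"]) - n_hi * (n_hi + 1) / 2) / (n_hi * n_lo)
}

# Patient-level label (majority vote over visits; ties -> high).
patient_labels <- function(tab) {
  pats <- unique(tab$patient_id)
  vapply(pats, function(p) {
    l <- tab$label[tab$patient_id == p]
    if (sum(l == "high") * 2 >= length(l)) "high" else "low"
  }, "")
}

# 50-value log-spaced lambda grid from lambda_max down to 1e-4 lambda_max.
lambda_grid <- function(Xs, y01, n_lambda = 50L) {
  lmax <- max(abs(crossprod(Xs, y01 - mean(y01)))) / length(y01)
  lmax <- max(lmax, 1e-6)
  exp(seq(log(lmax), log(1e-4 * lmax), length.out = n_lambda))
}

#' Leave-one-patient-out LASSO classification experiment
#'
#' Outer folds leave out all visits of one patient. Per fold, features are
#' z-scored on the training rows only; zero-variance columns are dropped
#' for that fold. All fits use balanced class weights, so the intercept
#' does not encode the training class balance (which in
#' leave-one-patient-out CV is set by the held-out patient's own class and
#' would leak it into the pooled ranking). The L1 penalty is selected from
#' a 50-value log-spaced grid spanning `[lambda_max, 1e-4 lambda_max]` by
#' an inner 3-fold CV (patients split into folds, stratified by
#' patient-level label, reshuffled per repetition) minimising mean
#' held-out binomial deviance under the one-standard-error rule (largest
#' penalty within one SE of the minimum). Deviance is smooth in the
#' penalty where rank-based criteria are flat, and the one-SE rule
#' returns the null model (constant probabilities) on uninformative folds
#' instead of an arbitrary overfit penalty. The experiment is repeated
#' `n_reps` times with
#' different inner splits; each held-out visit's pooled probability is
#' the median over repetitions, and the pooled AUC is computed once
#' against the ground truth.
#'
#' @param tab a [feature_table]
#' @param families feature families to include (default: all present)
#' @param n_reps repetitions (default 5)
#' @param base_seed seed for the inner-fold shuffles
#' @param inner_folds inner CV folds (default 3)
#' @param n_lambda penalty grid size (default 50)
#' @return a `cv_experiment`: list with `pooled_probs`, `pooled_auc`,
#'   `labels`, `models` (per repetition x fold: lambda and named
#'   coefficient vector), `n_models`, `combination`
#' @export
loocv_experiment <- function(tab, families = unique(tab$family),
                             n_reps = 5L, base_seed = 1L, inner_folds = 3L,
                             n_lambda = 50L) {
  stopifnot(inherits(tab, "feature_table"))
  cols <- tab$family %in% families
  if (!any(cols)) stop("no features in the requested families")
  X <- tab$X[, cols, drop = FALSE]
  y <- tab$label
  y01 <- as.integer(y == "high")
  pats <- unique(tab$patient_id)
  plab <- patient_labels(tab)
  if (length(unique(plab)) < 2 || min(table(plab)) < 2) {
    stop("need at least 2 patients per class")
  }

  models <- list()
  prob_mat <- matrix(NA_real_, nrow(X), n_reps)
  for (rep_i in seq_len(n_reps)) {
    for (pi in seq_along(pats)) {
      test_rows <- which(tab$patient_id == pats[pi])
      train_rows <- setdiff(seq_len(nrow(X)), test_rows)
      ytr <- y01[train_rows]
      if (length(unique(ytr)) < 2 || min(table(ytr)) < 2) {
        warning(sprintf(
          "fold for patient %s skipped: a class is (nearly) absent",
          pats[pi]))
        next
      }
      Xtr <- X[train_rows, , drop = FALSE]
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, sd)
      keep <- sdv > 0
      Xs <- scale(Xtr[, keep, drop = FALSE], mu[keep], sdv[keep])
      Xte <- scale(X[test_rows, keep, drop = FALSE], mu[keep], sdv[keep])
      lambdas <- lambda_grid(Xs, ytr, n_lambda)
      # balanced class weights: otherwise the null-model intercept encodes
      # the training class balance, which in LOOCV is set by the held-out
      # patient's own class and leaks it into the pooled ranking
      cls_w <- length(ytr) / (2 * table(factor(ytr, levels = 0:1)))
      wtr <- as.numeric(cls_w[ytr + 1])

      # inner 3-fold CV over training patients, stratified by label
      tr_pats <- pats[-pi]
      fold_of <- with_seed(seed_stream(base_seed, rep_i, pi), {
        f <- integer(length(tr_pats))
        for (cl in c("low", "high")) {
          idx <- sample(which(plab[tr_pats] == cl))
          f[idx] <- rep_len(seq_len(inner_folds), length(idx))
        }
        f
      })
      dev_by_lambda <- matrix(NA_real_, inner_folds, length(lambdas))
      tr_pat_of_row <- tab$patient_id[train_rows]
      for (k in seq_len(inner_folds)) {
        inner_te <- tr_pat_of_row %in% tr_pats[fold_of == k]
        if (length(unique(ytr[!inner_te])) < 2 ||
            min(table(ytr[!inner_te])) < 2 ||
            length(unique(ytr[inner_te])) < 2) next
        w_in <- length(ytr[!inner_te]) /
          (2 * table(factor(ytr[!inner_te], levels = 0:1)))
        fit <- glmnet::glmnet(Xs[!inner_te, , drop = FALSE], ytr[!inner_te],
                              family = "binomial", lambda = lambdas,
                              weights = as.numeric(w_in[ytr[!inner_te] + 1]),
                              standardize = FALSE)
        pr <- predict(fit, Xs[inner_te, , drop = FALSE],
                      type = "response")
        got <- match(fit$lambda, lambdas)
        yv <- ytr[inner_te]
        for (j in seq_along(got)) {
          p <- pmin(pmax(pr[, j], 1e-8), 1 - 1e-8)
          dev_by_lambda[k, got[j]] <-
            -2 * mean(yv * log(p) + (1 - yv) * log(1 - p))
        }
      }
      mean_dev <- colMeans(dev_by_lambda, na.rm = TRUE)
      mean_dev[is.nan(mean_dev)] <- Inf
      # one-SE rule (largest penalty within one SE of the minimum), and a
      # null-model benchmark: unless the minimum beats the held-out
      # deviance of the all-zero model (lambda_max column) by more than
      # one SE, keep the null model. Uninformative folds then emit
      # constant probabilities instead of chance fits that anti-predict
      # the held-out patient
      se_min <- apply(dev_by_lambda, 2, function(z)
        sd(z, na.rm = TRUE) / sqrt(max(1, sum(!is.na(z)))))
      i_min <- which.min(mean_dev)
      se_i <- ifelse(is.finite(se_min[i_min]), se_min[i_min], 0)
      if (!is.finite(mean_dev[i_min]) ||
          mean_dev[i_min] + 2 * se_i >= mean_dev[1]) {
        best <- 1L
      } else {
        best <- which(mean_dev <= mean_dev[i_min] + se_i)[1]
      }

      fit <- glmnet::glmnet(Xs, ytr, family = "binomial", lambda = lambdas,
                            weights = wtr, standardize = FALSE)
      beta <- numeric(ncol(X))
      names(beta) <- colnames(X)
      cf <- as.numeric(coef(fit, s = lambdas[best]))[-1]
      beta[keep] <- cf
      prob_mat[test_rows, rep_i] <-
        as.numeric(predict(fit, Xte, s = lambdas[best], type = "response"))
      models[[length(models) + 1]] <-
        list(rep = rep_i, patient = pats[pi], lambda = lambdas[best],
             coef = beta)
    }
  }
  pooled <- apply(prob_mat, 1, median, na.rm = TRUE)
  structure(list(pooled_probs = pooled,
                 pooled_auc = pooled_auc(pooled, y),
                 labels = y, models = models,
                 n_models = length(models),
                 combination = paste(families, collapse = "+")),
            class = "cv_experiment")
}

#' @export
print.cv_experiment <- function(x, ...) {
  cat(sprintf("<cv_experiment> %s: pooled AUC %.3f over %d models\n",
              x$combination, x$pooled_auc, x$n_models))
  invisible(x)
}

#' Feature popularity scores
#'
#' For each feature, the fraction of fitted models in which its L1
#' coefficient is non-zero: `rho = #{models with |coef| > zero_tol} /
#' #models`, on the grid {0, 1/N, ..., 1}.
#'
#' @param result a `cv_experiment`
#' @param zero_tol coefficient magnitude treated as zero
#' @return data.frame with `feature`, `rho` and `rank` (competition
#'   ranking: 1 + number of features with strictly greater rho, so tied
#'   features share a rank), sorted by decreasing rho, ties by name
#' @export
feature_popularity <- function(result, zero_tol = 1e-10) {
  stopifnot(inherits(result, "cv_experiment"))
  cmat <- vapply(result$models, function(m) m$coef,
                 numeric(length(result$models[[1]]$coef)))
  nz <- rowSums(abs(cmat) > zero_tol)
  rho <- nz / length(result$models)
  df <- data.frame(feature = rownames(cmat), rho = rho,
                   rank = vapply(rho, function(r) 1L + sum(rho > r), 1L))
  df[order(-df$rho, df$feature), , drop = FALSE]
}

#' ROC curve coordinates from pooled probabilities
#'
#' @param probs predicted probabilities of the high class
#' @param labels factor `low`/`high`
#' @return data.frame with `threshold`, `fpr`, `tpr`, one row per distinct
#'   threshold plus the (0,0) and (1,1) endpoints
#' @export
roc_points <- function(probs, labels) {
  labels <- factor(labels, levels = c("low", "high"))
  th <- c(Inf, sort(unique(probs), decreasing = TRUE), -Inf)
  n_hi <- sum(labels == "high")
  n_lo <- sum(labels == "low")
  data.frame(threshold = th,
             fpr = vapply(th, function(t)
               sum(probs >= t & labels == "low") / n_lo, 0),
             tpr = vapply(th, function(t)
               sum(probs >= t & labels == "high") / n_hi, 0))
}

#' Run all 15 feature-combination experiments
#'
#' @param tab a [feature_table] with all four families present
#' @param n_reps repetitions per combination (default 5)
#' @param base_seed seed
#' @return a `full_experiment`: list with `results` (15 `cv_experiment`s),
#'   `summary` (data.frame combination/AUC/models) and `top_popularity`
#'   (top-10 popularity table per combination)
#' @export
run_full_experiment <- function(tab, n_reps = 5L, base_seed = 1L) {
  combos <- enumerate_combinations()
  results <- list()
  for (i in seq_along(combos)) {
    results[[names(combos)[i]]] <- tryCatch(
      loocv_experiment(tab, combos[[i]], n_reps,
                       seed_stream(base_seed, i)),
      error = function(e) e)
  }
  ok <- !vapply(results, inherits, TRUE, "error")
  summ <- data.frame(
    combination = names(combos),
    pooled_auc = vapply(results, function(r)
      if (inherits(r, "error")) NA_real_ else r$pooled_auc, 0),
    n_models = vapply(results, function(r)
      if (inherits(r, "error")) NA_integer_ else r$n_models, 0L))
  pop <- lapply(results[ok], function(r) head(feature_popularity(r), 10))
  roc <- lapply(results[ok], function(r)
    roc_points(r$pooled_probs, r$labels))
  structure(list(results = results, summary = summ, top_popularity = pop,
                 roc = roc),
            class = "full_experiment")
}

#' @export
print.full_experiment <- function(x, ...) {
  cat("<full_experiment> pooled AUC by feature combination:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
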