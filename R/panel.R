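#' L1-penalized logistic regression at a fixed penalty
#'
#' Minimizes the penalized binomial objective
#' \eqn{-\ell(\beta) + \lambda \|\beta\|_1} (log-likelihood summed over
#' observations, intercept unpenalized) via the glmnet coordinate-descent
#' path. Features are expected standardized; a constant feature receives
#' coefficient zero. Because \eqn{\lambda} multiplies the summed (not
#' averaged) deviance, duplicating every observation while doubling
#' \eqn{\lambda} leaves the solution unchanged.
#'
#' @param X numeric matrix, samples x features, no missing entries.
#' @param y 0/1 case indicator containing both classes.
#' @param lambda penalty on the sum-deviance scale.
#' @return named coefficient vector, intercept first.
#' @export
fit_l1_logistic <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing entries")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- nrow(X)
  lam <- lambda / n  # glmnet scales the deviance by 1/n
  lam_seq <- lambda_path(X, y, lam)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lam_seq, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lam, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(X) %||%
                   paste0("V", seq_len(ncol(X))))
  cf
}

# decreasing lambda sequence that passes through the target value
lambda_path <- function(X, y, lam_target) {
  n <- nrow(X)
  p_bar <- mean(y)
  lmax <- max(abs(crossprod(X, y - p_bar))) / n
  lmax <- max(lmax, lam_target, .Machine$double.eps)
  lo <- max(min(lam_target, lmax * 1e-4), 1e-10)
  sort(unique(c(exp(seq(log(lmax * 1.05), log(lo), length.out = 80)),
                lam_target)), decreasing = TRUE)
}

#' ROC metrics on pooled predictions
#'
#' AUC is the Mann-Whitney probability that a random case scores above a
#' random control, with half credit for ties; sensitivity is the
#' fraction of cases at or above the threshold, specificity the fraction
#' of controls below it.
#'
#' @param scores predicted case probabilities (or any scores).
#' @param labels 0/1 labels, both classes present.
#' @param threshold classification threshold (score >= threshold flags a
#'   case).
#' @return named numeric vector (auc, sensitivity, specificity).
#' @export
roc_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # ties averaged -> half credit
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(auc = auc,
    sensitivity = mean(scores[labels == 1L] >= threshold),
    specificity = mean(scores[labels == 0L] < threshold))
}

#' Stable feature set from selection frequencies
#'
#' @param stability data.frame with columns feature, count, fraction
#'   (as produced by \code{\link{loocv_panel}}).
#' @param frac minimum selection fraction; a feature selected in exactly
#'   that fraction of fits is included.
#' @return character vector of features, highest fraction first (ties
#'   lexicographic).
#' @export
stable_set <- function(stability, frac = 0.5) {
  keep <- stability$fraction >= frac
  s <- stability[keep, , drop = FALSE]
  s$feature[order(-s$fraction, s$feature)]
}

#' Assemble a design matrix across lectin peptide matrices
#'
#' Builds the classification problem: y = 1 for cases, 0 for benign and
#' healthy pooled; X holds the peptide features of the scoped lectin(s)
#' under lectin-qualified names ("LECTIN-peptide"). Standard peptides are
#' excluded, and samples with any missing feature in scope are dropped
#' (count recorded), mirroring per-lectin sample-size differences.
#'
#' @param matrices named list (lectin -> peptide matrix, log2).
#' @param metadata sample annotation with sample_id and group.
#' @param scope a lectin name or \code{"combined"}.
#' @param exclude_samples optional sample ids to drop (e.g. QC
#'   outliers).
#' @return list(X, y, samples); attribute \code{n_dropped} counts
#'   samples dropped for missingness.
#' @export
build_design <- function(matrices, metadata, scope = "combined",
                         exclude_samples = NULL) {
  use <- if (identical(scope, "combined")) names(matrices)
         else {
           if (!scope %in% names(matrices))
             stop("unknown lectin scope: ", scope)
           scope
         }
  blocks <- lapply(use, function(l) {
    m <- matrices[[l]]
    std <- unlist(attr(m, "standards"), use.names = FALSE)
    m <- m[setdiff(rownames(m), std), , drop = FALSE]
    rownames(m) <- paste0(l, "-", rownames(m))
    m
  })
  samples <- Reduce(intersect, lapply(blocks, colnames))
  samples <- setdiff(samples, exclude_samples)
  if (!length(samples)) stop("no samples shared across the scoped lectins")
  Xt <- do.call(rbind, lapply(blocks, function(b)
    b[, samples, drop = FALSE]))
  complete <- colSums(is.na(Xt)) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped)
    message(n_dropped, " sample(s) dropped for missing features")
  samples <- samples[complete]
  if (!length(samples)) stop("no complete samples in scope")
  X <- t(Xt[, samples, drop = FALSE])
  grp <- metadata$group[match(samples, metadata$sample_id)]
  if (anyNA(grp)) stop("samples missing from metadata")
  y <- as.integer(grp == "case")
  out <- list(X = X, y = y, samples = samples)
  attr(out, "n_dropped") <- n_dropped
  out
}

standardize_train <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd,
       X = sweep(sweep(X, 2L, mu), 2L, sd, "/"))
}

#' Leave-one-out cross-validated lasso panel
#'
#' For each sample: standardize on the remaining n - 1 samples, select
#' the penalty by inner 5-fold cross-validated deviance (one-standard-
#' error rule) on that training split only, fit the L1-penalized
#' logistic model, and record the selected features and the predicted
#' case probability of the left-out sample. AUC, sensitivity and
#' specificity are computed on the n pooled left-out predictions, with
#' stratified bootstrap percentile intervals; selection counts across
#' the n fits give each peptide's stability, and the stable set keeps
#' those at or above \code{stability_frac}. A final model is fit on the
#' full data the same way.
#'
#' @param X samples x features matrix (unstandardized), no missing
#'   entries.
#' @param y 0/1 case indicator, both classes with at least 3 samples.
#' @param config an \code{\link{analysis_config}}; uses
#'   \code{stability_frac}, \code{classification_threshold},
#'   \code{n_boot} and \code{seed}.
#' @param lambda_rule \code{"1se"} (default) or \code{"min"} inner
#'   selection.
#' @return list of class \code{glyco_panel}: folds (left-out sample,
#'   prediction, selected features), metrics at the configured threshold
#'   (+stratified bootstrap percentile intervals) and at the
#'   Youden-optimal threshold, stability table, stable set, final
#'   coefficients.
#' @export
loocv_panel <- function(X, y, config = analysis_config(),
                        lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 samples")
  if (min(sum(y == 1L), sum(y == 0L)) < 3L)
    stop("both classes need at least 3 samples")
  if (anyNA(X)) stop("X contains missing entries")
  feats <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- feats

  preds <- numeric(n)
  sel <- matrix(FALSE, n, ncol(X), dimnames = list(NULL, feats))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    st <- standardize_train(X[tr, , drop = FALSE])
    fit <- inner_lasso_fit(st$X, y[tr],
                           seed = stream_seed(config$seed,
                                              paste0("fold-", i)),
                           rule = lambda_rule)
    xi <- (X[i, ] - st$mu) / st$sd
    eta <- fit$a0 + sum(fit$beta * xi)
    # centre each fold's linear predictor on its training-prevalence
    # baseline: pooling raw LOOCV probabilities ranks left-out cases
    # below controls whenever the model shrinks to the intercept (the
    # training set holds one fewer case for a left-out case), biasing
    # the pooled AUC pessimistically; recalibrating every fold to the
    # full-data prevalence removes that artifact without touching the
    # within-fold ranking
    eta0 <- stats::qlogis(mean(y[tr]))
    preds[i] <- stats::plogis(eta - eta0 + stats::qlogis(mean(y)))
    sel[i, ] <- fit$beta != 0
  }

  met <- roc_metrics(preds, y, config$classification_threshold)
  # Youden-optimal alternative threshold: lasso-shrunk LOOCV
  # probabilities concentrate near the prevalence, so a fixed 0.5 cut
  # can sit outside their range; both operating points are reported
  cand_thr <- sort(unique(preds))
  youden <- vapply(cand_thr, function(t) {
    m <- roc_metrics(preds, y, t)
    m[["sensitivity"]] + m[["specificity"]] - 1
  }, numeric(1))
  thr_youden <- cand_thr[which.max(youden)]
  met_youden <- roc_metrics(preds, y, thr_youden)
  ci <- with_seed(stream_seed(config$seed, "panel-boot"), {
    i1 <- which(y == 1L); i0 <- which(y == 0L)
    reps <- vapply(seq_len(config$n_boot), function(b) {
      ib <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      roc_metrics(preds[ib], y[ib], config$classification_threshold)
    }, numeric(3))
    apply(reps, 1L, stats::quantile, probs = c(0.025, 0.975))
  })

  stability <- data.frame(feature = feats, count = colSums(sel),
                          fraction = colSums(sel) / n,
                          stringsAsFactors = FALSE)
  stability <- stability[order(-stability$fraction, stability$feature), ]
  rownames(stability) <- NULL

  st_full <- standardize_train(X)
  final <- inner_lasso_fit(st_full$X, y,
                           seed = stream_seed(config$seed, "final"),
                           rule = lambda_rule)

  out <- list(
    folds = data.frame(sample = seq_len(n), truth = y, prediction = preds),
    selected = sel,
    metrics = data.frame(
      metric = c("auc", "sensitivity", "specificity"),
      value = unname(met),
      lower = unname(ci[1, ]), upper = unname(ci[2, ]),
      stringsAsFactors = FALSE),
    metrics_youden = data.frame(
      metric = c("auc", "sensitivity", "specificity"),
      value = unname(met_youden), stringsAsFactors = FALSE),
    threshold_youden = thr_youden,
    stability = stability,
    stable = stable_set(stability, config$stability_frac),
    final_coefficients = c("(Intercept)" = final$a0,
                           stats::setNames(final$beta, feats)),
    n = n)
  class(out) <- "glyco_panel"
  out
}

# inner model fit: 5-fold cv.glmnet on the (already standardized)
# training split with a seeded, stratified fold assignment
inner_lasso_fit <- function(Xs, ytr, seed, rule = "1se") {
  foldid <- with_seed(seed, {
    f <- integer(length(ytr))
    for (cls in unique(ytr)) {
      idx <- which(ytr == cls)
      f[idx] <- sample(rep_len(1:5, length(idx)))
    }
    f
  })
  # glmnet warns when an inner fold holds < 8 of one class; expected at
  # these sample sizes and harmless for deviance-based selection
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(Xs, ytr, family = "binomial", alpha = 1,
                      foldid = foldid, standardize = FALSE,
                      type.measure = "deviance"),
    warning = function(w) {
      if (grepl("fewer than 8 observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  s <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  cf <- as.numeric(glmnet::coef.glmnet(cv$glmnet.fit, s = s))
  list(a0 = cf[1L], beta = cf[-1L], lambda = s)
}

#' @export
print.glyco_panel <- function(x, ...) {
  cat("Leave-one-out lasso panel:", x$n, "samples,",
      nrow(x$stability), "features\n")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %5.1f%% (%.1f%%, %.1f%%)\n", m$metric[i],
                100 * m$value[i], 100 * m$lower[i], 100 * m$upper[i]))
  my <- x$metrics_youden
  cat(sprintf("  at Youden threshold %.3f: sens %.1f%%, spec %.1f%%\n",
              x$threshold_youden, 100 * my$value[2], 100 * my$value[3]))
  cat("  stable peptides:", length(x$stable), "\n")
  invisible(x)
}
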