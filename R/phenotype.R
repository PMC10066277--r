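# Language phenotype scoring: z-scored features -> leave-one-out linear
# SVM -> Platt-calibrated posteriors -> per-participant composite ->
# accuracy, permutation significance, ROC, and severity validation.

#' Z-score the feature columns of a feature table
#'
#' Each feature column is centered and scaled to unit sample standard
#' deviation (denominator n - 1).  Constant columns carry no information
#' and are dropped with a warning.  The transformation parameters are
#' attached as attributes `center` and `scale`.
#'
#' @param table a `feature_table`.
#' @return The standardized `feature_table`.
#' @export
standardize <- function(table) {
  fn <- feature_names(table)
  X <- feature_matrix(table)
  sds <- apply(X, 2L, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (all(const)) err_validation("all feature columns are constant")
  if (any(const)) {
    warning(sprintf("dropped %d constant feature column(s): %s",
                    sum(const), paste(fn[const], collapse = ", ")),
            call. = FALSE)
    X <- X[, !const, drop = FALSE]
    fn <- fn[!const]
    sds <- sds[!const]
  }
  mu <- colMeans(X)
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sds, "/")
  out <- cbind(as.data.frame(table)[, c("conversation_id", "participant_id",
                                        "group")],
               as.data.frame(Z))
  out <- as_feature_table(out)
  attr(out, "center") <- mu
  attr(out, "scale") <- sds
  out
}

# Resolve which group label is the case group (autism-analog).  NULL means
# "first level in order of appearance"; callers are expected to set it.
.resolve_case_group <- function(groups, case_group) {
  lev <- unique(groups)
  if (is.null(case_group)) return(lev[1L])
  if (!case_group %in% lev)
    err_validation(sprintf("case_group '%s' not among group labels (%s)",
                           case_group, paste(lev, collapse = ", ")))
  case_group
}

# Platt's two-parameter sigmoid: fit P(y = +1 | f) = 1 / (1 + exp(A f + B))
# by regularized maximum likelihood with the standard smoothed targets
# t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2), which keep the fit finite even
# for perfectly separated decision values.
fit_platt <- function(decision, is_positive) {
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  targ <- ifelse(is_positive, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    fApB <- par[1L] * decision + par[2L]
    sum(ifelse(fApB >= 0,
               targ * fApB + log1p(exp(-fApB)),
               (targ - 1) * fApB + log1p(exp(fApB))))
  }
  grad <- function(par) {
    fApB <- par[1L] * decision + par[2L]
    d <- targ - stats::plogis(-fApB)  # targ - P(y=+1)
    c(sum(d * decision), sum(d))
  }
  init <- c(0, log((n_neg + 1) / (n_pos + 1)))
  fit <- stats::optim(init, nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(A = fit$par[1L], B = fit$par[2L])
}

platt_posterior <- function(decision, platt) {
  p <- stats::plogis(-(platt$A * decision + platt$B))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Leave-one-out linear SVM classification of conversations
#'
#' Trains an L2-regularized hinge-loss (soft-margin) linear support vector
#' classifier in a leave-one-out loop: each conversation is scored by a
#' model trained on all other conversations.  The cross-validated signed
#' decision values are then mapped to posterior probabilities with a
#' single pooled Platt sigmoid fitted against the true labels, oriented so
#' that higher posteriors mean more control-group-like language.
#'
#' By default the feature table is z-scored once on all conversations
#' before cross-validation (mirroring the reference pipeline's order of
#' operations); `per_fold_standardize = TRUE` instead re-estimates the
#' standardization inside each training fold, which avoids the mild
#' information leakage of global scaling at the price of a different
#' protocol.  `grouped = TRUE` holds out all of a participant's
#' conversations together (leave-one-participant-out) instead of treating
#' conversations as independent.
#'
#' @param table a `feature_table` (raw; standardization is handled here).
#' @param regularization_strength SVM cost parameter C.
#' @param case_group label of the case group (decision values are oriented
#'   positive towards the other, control, group).
#' @param per_fold_standardize re-estimate z-scoring within each fold.
#' @param grouped leave-one-participant-out instead of leave-one-
#'   conversation-out.
#' @param tol convergence tolerance of the SVM solver (maximal
#'   Karush-Kuhn-Tucker violation).
#' @return data.frame of class `conversation_scores`: `conversation_id`,
#'   `participant_id`, `group`, `decision_value`, `posterior`; the fitted
#'   Platt coefficients are attached as attribute `platt`.
#' @export
loo_classify <- function(table, regularization_strength = 1.0,
                         case_group = NULL,
                         per_fold_standardize = FALSE,
                         grouped = FALSE, tol = 1e-5) {
  case_group <- .resolve_case_group(table$group, case_group)
  y <- ifelse(table$group == case_group, -1, 1)
  n <- length(y)

  folds <- if (grouped) {
    split(seq_len(n), table$participant_id)
  } else {
    as.list(seq_len(n))
  }
  for (f in folds) {
    ytr <- y[-f]
    if (length(unique(ytr)) < 2L)
      err_validation("a cross-validation fold would lose an entire group")
  }

  decision <- numeric(n)
  if (!per_fold_standardize) {
    Z <- feature_matrix(standardize(table))
    K <- tcrossprod(Z)
    if (!grouped) {
      decision <- .svm_loo_kernel(K, y, regularization_strength, tol)
    } else {
      for (f in folds) {
        fit <- .svm_fit_kernel(K[-f, -f, drop = FALSE], y[-f],
                               regularization_strength, tol)
        beta <- fit$alpha * y[-f]
        decision[f] <- drop(K[f, -f, drop = FALSE] %*% beta) + fit$b
      }
    }
  } else {
    X <- feature_matrix(table)
    for (f in folds) {
      Xtr <- X[-f, , drop = FALSE]
      sds <- apply(Xtr, 2L, stats::sd)
      keep <- sds > 0
      mu <- colMeans(Xtr[, keep, drop = FALSE])
      Ztr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2L, mu, "-"),
                   2L, sds[keep], "/")
      Zte <- sweep(sweep(X[f, keep, drop = FALSE], 2L, mu, "-"),
                   2L, sds[keep], "/")
      fit <- .svm_fit_kernel(tcrossprod(Ztr), y[-f], regularization_strength,
                             tol)
      beta <- fit$alpha * y[-f]
      decision[f] <- drop(Zte %*% t(Ztr) %*% beta) + fit$b
    }
  }

  platt <- fit_platt(decision, y > 0)
  out <- data.frame(conversation_id = table$conversation_id,
                    participant_id = table$participant_id,
                    group = table$group,
                    decision_value = as.numeric(decision),
                    posterior = platt_posterior(decision, platt),
                    stringsAsFactors = FALSE)
  attr(out, "platt") <- platt
  attr(out, "case_group") <- case_group
  class(out) <- c("conversation_scores", "data.frame")
  out
}

#' Average conversation posteriors into participant composite scores
#'
#' A participant's composite score is the arithmetic mean of the
#' Platt-calibrated posteriors of their conversations.  A composite
#' strictly below the cutoff predicts the case group; a composite exactly
#' at the cutoff is classified as control (only scores *lower than* the
#' cutoff indicate the case group).
#'
#' @param scores `conversation_scores` from [loo_classify()].
#' @param roster data.frame `participant_id`, `group` (defaults to the
#'   roster carried in `scores`).
#' @param cutoff composite cutoff (default 0.5).
#' @param case_group case-group label; defaults to the orientation stored
#'   in `scores`.
#' @return data.frame of class `participant_composites`: `participant_id`,
#'   `composite`, `n_conversations`, `true_group`, `predicted_group`.
#' @export
composite_scores <- function(scores, roster = NULL, cutoff = 0.5,
                             case_group = NULL) {
  if (is.null(case_group)) case_group <- attr(scores, "case_group")
  if (is.null(roster))
    roster <- unique(as.data.frame(scores)[, c("participant_id", "group")])
  names(roster)[names(roster) == "group"] <- "true_group"
  unk <- setdiff(scores$participant_id, roster$participant_id)
  if (length(unk))
    err_validation(sprintf("conversation(s) from unrostered participant(s): %s",
                           paste(unique(unk), collapse = ", ")))
  zero <- setdiff(roster$participant_id, scores$participant_id)
  if (length(zero)) {
    warning(sprintf("participant(s) with no conversations excluded: %s",
                    paste(zero, collapse = ", ")), call. = FALSE)
    roster <- roster[!roster$participant_id %in% zero, , drop = FALSE]
  }
  comp <- tapply(scores$posterior, scores$participant_id, mean)
  nconv <- tapply(scores$posterior, scores$participant_id, length)
  out <- data.frame(participant_id = names(comp),
                    composite = as.numeric(comp),
                    n_conversations = as.integer(nconv),
                    stringsAsFactors = FALSE)
  out <- merge(out, roster, by = "participant_id", sort = TRUE)
  lev <- unique(roster$true_group)
  control_group <- setdiff(lev, case_group)[1L]
  out$predicted_group <- ifelse(out$composite < cutoff,
                                case_group, control_group)
  class(out) <- c("participant_composites", "data.frame")
  attr(out, "case_group") <- case_group
  attr(out, "cutoff") <- cutoff
  out
}

#' Classification accuracy of participant composites
#' @param composites `participant_composites` from [composite_scores()].
#' @return Fraction of participants whose predicted group matches their
#'   true group.
#' @export
evaluate_accuracy <- function(composites) {
  if (nrow(composites) < 1L) err_validation("no participants to evaluate")
  mean(composites$predicted_group == composites$true_group)
}

# One full classify -> composite -> accuracy pass against a supplied group
# labeling (used by the observed run and by every permutation).
.pipeline_accuracy <- function(table, groups, regularization_strength,
                               cutoff, case_group, ...) {
  tab <- table
  tab$group <- groups
  sc <- loo_classify(tab, regularization_strength, case_group = case_group,
                     ...)
  cmp <- composite_scores(sc, cutoff = cutoff, case_group = case_group)
  evaluate_accuracy(cmp)
}

#' Permutation test of classifier accuracy
#'
#' Builds the null distribution of composite classification accuracy by
#' permuting diagnosis labels at the participant level (all of a
#' participant's conversations receive the same permuted label, so group
#' sizes are preserved exactly), rerunning the full leave-one-out
#' classification, calibration and composite scoring against the permuted
#' labels each time.  The primary p-value is the proportion of
#' permutations whose accuracy is strictly greater than the observed
#' accuracy; the add-one smoothed estimator `(#\{null >= observed\} + 1) /
#' (n + 1)`, which can never be exactly zero, is reported alongside.
#'
#' @param table a `feature_table`.
#' @param n_permutations number of label permutations.
#' @param seed seed for the permutation stream.
#' @param regularization_strength,cutoff,case_group,tol as in
#'   [loo_classify()] and [composite_scores()].
#' @param ... passed on to [loo_classify()] (e.g. `grouped`).
#' @return List with `observed_accuracy`, `permutation_p` (strict),
#'   `permutation_p_smoothed`, `null_accuracies`, `n_permutations`.
#' @export
permutation_test <- function(table, n_permutations = 1000, seed = 1,
                             regularization_strength = 1.0, cutoff = 0.5,
                             case_group = NULL, tol = 1e-5, ...) {
  if (n_permutations < 1) err_validation("n_permutations must be >= 1")
  case_group <- .resolve_case_group(table$group, case_group)
  observed <- .pipeline_accuracy(table, table$group, regularization_strength,
                                 cutoff, case_group, tol = tol, ...)
  roster <- participant_roster(table)
  pmatch_idx <- match(table$participant_id, roster$participant_id)

  fast <- length(list(...)) == 0L
  if (fast) {
    # the z-scoring (and hence the kernel) does not depend on the labels,
    # so the leave-one-out sweep can reuse one precomputed kernel
    Z <- feature_matrix(suppressWarnings(standardize(table)))
    K <- tcrossprod(Z)
    pfac <- factor(table$participant_id, levels = roster$participant_id)
    one_perm <- function(perm_groups) {
      y <- ifelse(perm_groups[pmatch_idx] == case_group, -1, 1)
      d <- .svm_loo_kernel(K, y, regularization_strength, tol)
      post <- platt_posterior(d, fit_platt(d, y > 0))
      comp <- tapply(post, pfac, mean)
      pred_case <- comp < cutoff
      mean(pred_case == (perm_groups == case_group))
    }
  } else {
    one_perm <- function(perm_groups) {
      groups <- perm_groups[pmatch_idx]
      .pipeline_accuracy(table, groups, regularization_strength,
                         cutoff, case_group, tol = tol, ...)
    }
  }
  nulls <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_permutations), function(b)
      one_perm(sample(roster$group)), numeric(1))
  })
  list(observed_accuracy = observed,
       permutation_p = sum(nulls > observed) / n_permutations,
       permutation_p_smoothed = (sum(nulls >= observed) + 1) /
         (n_permutations + 1),
       null_accuracies = nulls,
       n_permutations = as.integer(n_permutations))
}

#' Spearman validation of composites against clinical severity
#'
#' Correlates case-group composite scores with an ordinal severity rating
#' (an ADOS-2 Social Communication-like score, administered to the case
#' group only).  Ranks use the average-rank tie convention; the two-sided
#' p-value is exact (enumeration) for n <= 9 without ties and otherwise
#' uses the large-sample t approximation.
#'
#' @param composites `participant_composites`.
#' @param severity data.frame `participant_id`, `severity`.
#' @return List `rho`, `p_value`, `n`.
#' @export
validate_severity <- function(composites, severity) {
  if (!all(c("participant_id", "severity") %in% names(severity)))
    err_format("severity table needs participant_id and severity columns")
  m <- merge(as.data.frame(composites), severity, by = "participant_id")
  m <- m[!is.na(m$severity), , drop = FALSE]
  n <- nrow(m)
  if (n < 4L)
    err_validation(sprintf(
      "severity validation needs >= 4 paired observations, found %d", n))
  rho <- stats::cor(rank(m$composite), rank(m$severity))
  ties <- anyDuplicated(m$composite) || anyDuplicated(m$severity)
  p <- if (n <= 9L && !ties) {
    stats::cor.test(m$composite, m$severity, method = "spearman",
                    exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    t_pvalue(tstat, n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' ROC analysis of the composite score
#'
#' Treats the composite as a continuous score for control-group
#' membership (higher = more control-like).  Points are computed at every
#' distinct threshold; the AUC uses the trapezoidal rule, which for a step
#' ROC equals the rank-sum statistic: the probability that a random
#' control participant scores above a random case participant, ties
#' counting one half.
#'
#' @param composites `participant_composites`.
#' @param case_group case-group label; defaults to the stored orientation.
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_analysis <- function(composites, case_group = NULL) {
  if (is.null(case_group)) case_group <- attr(composites, "case_group")
  is_control <- composites$true_group != case_group
  if (!any(is_control) || all(is_control))
    err_validation("ROC analysis needs both groups")
  s <- composites$composite
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(s[is_control] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!is_control] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Run the full classifier evaluation chain on a feature table
#'
#' Convenience wrapper chaining [loo_classify()], [composite_scores()],
#' [evaluate_accuracy()], [permutation_test()], [roc_analysis()] and
#' (when a severity table is given) [validate_severity()].
#'
#' @param table a `feature_table`.
#' @param config a `phenoconn_config`.
#' @param severity optional severity table.
#' @param ... passed to [loo_classify()].
#' @return List of class `classifier_evaluation` with elements `scores`,
#'   `composites`, `accuracy`, `n_correct`, `n_total`, `permutation_p`,
#'   `permutation_p_smoothed`, `null_accuracies`, `roc_auc`, `roc`, and
#'   optionally `severity_rho`, `severity_p`.
#' @export
evaluate_classifier <- function(table, config = run_config(),
                                severity = NULL, ...) {
  case_group <- .resolve_case_group(table$group, config$case_group)
  sc <- loo_classify(table, config$regularization_strength,
                     case_group = case_group, ...)
  cmp <- composite_scores(sc, cutoff = config$composite_cutoff,
                          case_group = case_group)
  acc <- evaluate_accuracy(cmp)
  pt <- permutation_test(table, config$n_permutations, seed = config$seed,
                         regularization_strength =
                           config$regularization_strength,
                         cutoff = config$composite_cutoff,
                         case_group = case_group, ...)
  roc <- roc_analysis(cmp, case_group = case_group)
  out <- list(scores = sc, composites = cmp,
              accuracy = acc,
              n_correct = as.integer(round(acc * nrow(cmp))),
              n_total = nrow(cmp),
              permutation_p = pt$permutation_p,
              permutation_p_smoothed = pt$permutation_p_smoothed,
              null_accuracies = pt$null_accuracies,
              roc_auc = roc$auc, roc = roc$roc,
              case_group = case_group)
  if (!is.null(severity)) {
    case_cmp <- cmp[cmp$true_group == case_group, , drop = FALSE]
    sv <- validate_severity(case_cmp, severity)
    out$severity_rho <- sv$rho
    out$severity_p <- sv$p_value
    out$severity_n <- sv$n
  }
  class(out) <- "classifier_evaluation"
  out
}

#' @exportS3Method base::print
print.classifier_evaluation <- function(x, ...) {
  cat("Classifier evaluation\n")
  cat(sprintf("  accuracy: %.1f%% (%d/%d participants)\n",
              100 * x$accuracy, x$n_correct, x$n_total))
  cat(sprintf("  permutation p: %.4g (smoothed %.4g, %d permutations)\n",
              x$permutation_p, x$permutation_p_smoothed,
              length(x$null_accuracies)))
  cat(sprintf("  ROC AUC: %.3f\n", x$roc_auc))
  if (!is.null(x$severity_rho))
    cat(sprintf("  severity Spearman rho: %.2f (p = %.3g, n = %d)\n",
                x$severity_rho, x$severity_p, x$severity_n))
  invisible(x)
}

#' Negative-control classifier on conversation-partner speech
#'
#' Runs the identical classification, permutation and (optionally)
#' severity-validation chain on features derived from the conversation
#' partner's speech in the same conversations.  The partner table must
#' cover exactly the same conversations as the participant table; a
#' successful control shows chance-level accuracy, confirming the
#' participant-speech classifier is not driven by systematic partner
#' behavior.
#'
#' @param partner_table `feature_table` of partner-speech features.
#' @param participant_table `feature_table` used for the main analysis
#'   (defines the conversation roster).
#' @param config a `phenoconn_config`.
#' @param severity optional severity table.
#' @param ... passed to [loo_classify()].
#' @return A `classifier_evaluation`.
#' @export
control_classifier <- function(partner_table, participant_table,
                               config = run_config(), severity = NULL, ...) {
  a <- sort(partner_table$conversation_id)
  b <- sort(participant_table$conversation_id)
  if (!identical(a, b))
    err_validation("partner table must cover exactly the same conversations")
  evaluate_classifier(partner_table, config, severity = severity, ...)
}
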