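test_that("standardization yields exact zero mean / unit SD and drops constants", {
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(6:30, 1)
    f <- sample(2:6, 1)
    tab <- tiny_table(rnorm(n), rep_len(c("a", "b"), n),
                      extra = as.data.frame(matrix(rnorm(n * f), n)))
    z <- standardize(tab)
    Z <- feature_matrix(z)
    expect_true(all(abs(colMeans(Z)) < 1e-10))
    expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))
  }
  const <- tiny_table(c(1, 2, 3, 4), c("a", "a", "b", "b"),
                      extra = data.frame(f2 = rep(7, 4)))
  expect_warning(z <- standardize(const), "constant")
  expect_equal(feature_names(z), "f1")
  allc <- tiny_table(rep(1, 4), c("a", "a", "b", "b"))
  expect_error(standardize(allc), class = "phenoconn_validation_error")
})

test_that("leave-one-out SVM matches a brute-force convex oracle on tiny data", {
  # n = 6 conversations, one feature: every fold is hand-checkable
  set.seed(11)
  vals <- c(-1.4, -0.9, -0.2, 0.3, 1.0, 1.5)
  tab <- tiny_table(vals, rep(c("case", "ctrl"), each = 3))
  sc <- loo_classify(tab, regularization_strength = 1, case_group = "case",
                     tol = 1e-9)
  Z <- feature_matrix(standardize(tab))
  y <- ifelse(tab$group == "case", -1, 1)
  for (i in seq_along(vals)) {
    Ztr <- Z[-i, , drop = FALSE]
    fit <- phenoconn:::.svm_fit_kernel(tcrossprod(Ztr), y[-i], 1, 1e-10)
    w_ours <- drop(t(Ztr) %*% (fit$alpha * y[-i]))
    bf <- bf_svm(Ztr, y[-i], 1)
    expect_equal(w_ours, bf$w, tolerance = 1e-4, ignore_attr = TRUE)
    if (any(fit$alpha > 1e-7 & fit$alpha < 1 - 1e-7)) {
      # free support vectors pin down the bias: decisions comparable
      d_bf <- unname(bf_svm_decision(Ztr, y[-i], Z[i, , drop = FALSE],
                                     C = 1))
      expect_equal(sc$decision_value[i], d_bf, tolerance = 1e-4)
    }
  }

  # and on a 2-feature instance with a different cost.  When a training
  # fold leaves no free support vector (all alphas at bound) the bias
  # term is a non-unique interval and only the weight vector and the
  # objective value are well defined, so those are compared instead.
  set.seed(12)
  X <- matrix(rnorm(16), 8, 2)
  tab2 <- tiny_table(X[, 1], rep(c("case", "ctrl"), 4),
                     extra = data.frame(f2 = X[, 2]))
  C2 <- 0.5
  sc2 <- loo_classify(tab2, regularization_strength = C2,
                      case_group = "case", tol = 1e-9)
  Z2 <- feature_matrix(standardize(tab2))
  y2 <- ifelse(tab2$group == "case", -1, 1)
  for (i in 1:8) {
    Ztr <- Z2[-i, , drop = FALSE]
    ytr <- y2[-i]
    fit <- phenoconn:::.svm_fit_kernel(tcrossprod(Ztr), ytr, C2, 1e-10)
    w_ours <- drop(t(Ztr) %*% (fit$alpha * ytr))
    bf <- bf_svm(Ztr, ytr, C2)
    obj <- function(w, b)
      0.5 * sum(w^2) + C2 * sum(pmax(0, 1 - ytr * (Ztr %*% w + b)))
    expect_equal(w_ours, bf$w, tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(obj(w_ours, fit$b), bf$obj, tolerance = 1e-6)
    free_sv <- any(fit$alpha > 1e-7 & fit$alpha < C2 - 1e-7)
    if (free_sv) {
      d_bf <- unname(bf_svm_decision(Ztr, ytr, Z2[i, , drop = FALSE],
                                     C = C2))
      expect_equal(sc2$decision_value[i], d_bf, tolerance = 1e-4)
    }
  }
})

test_that("SMO solver agrees with the independent e1071 implementation", {
  skip_if_not_installed("e1071")
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(c(-1, 1), 10)
  X[y > 0, ] <- X[y > 0, ] + 0.8
  K <- tcrossprod(X)
  fit <- phenoconn:::.svm_fit_kernel(K, y, 1.0, 1e-10)
  m <- e1071::svm(X, factor(y, levels = c(-1, 1)), kernel = "linear",
                  cost = 1, scale = FALSE, tolerance = 1e-10)
  dv <- attr(predict(m, X, decision.values = TRUE), "decision.values")
  d <- drop(dv)
  if (colnames(dv)[1] == "-1/1") d <- -d
  expect_equal(fit$decision, unname(d), tolerance = 1e-6)
})

test_that("separable clusters are classified perfectly with correct orientation", {
  set.seed(2)
  n <- 20
  tab <- tiny_table(c(rnorm(10, -5), rnorm(10, 5)),
                    rep(c("case", "ctrl"), each = 10),
                    extra = data.frame(f2 = c(rnorm(10, -5), rnorm(10, 5))))
  sc <- loo_classify(tab, case_group = "case")
  expect_true(all(sc$posterior[tab$group == "case"] < 0.5))
  expect_true(all(sc$posterior[tab$group == "ctrl"] > 0.5))
  cmp <- composite_scores(sc, case_group = "case")
  expect_equal(evaluate_accuracy(cmp), 1.0)
  # posteriors strictly inside (0,1) and monotone in the decision value
  expect_true(all(sc$posterior > 0 & sc$posterior < 1))
  ord <- order(sc$decision_value)
  expect_true(all(diff(sc$posterior[ord]) >= 0) ||
                all(diff(sc$posterior[ord]) <= 0))
})

test_that("decision values are invariant to feature order and dropped constants", {
  set.seed(3)
  tab <- tiny_table(rnorm(12), rep(c("a", "b"), 6),
                    extra = as.data.frame(matrix(rnorm(36), 12)))
  sc <- loo_classify(tab, case_group = "a", tol = 1e-9)
  fn <- feature_names(tab)
  shuffled <- as_feature_table(as.data.frame(tab)[
    , c("conversation_id", "participant_id", "group", rev(fn))])
  sc2 <- loo_classify(shuffled, case_group = "a", tol = 1e-9)
  expect_equal(sc2$decision_value, sc$decision_value, tolerance = 1e-6)
  withc <- tab
  withc$const <- 5
  sc3 <- suppressWarnings(loo_classify(as_feature_table(withc),
                                       case_group = "a", tol = 1e-9))
  expect_equal(sc3$decision_value, sc$decision_value, tolerance = 1e-6)
})

test_that("folds that would lose a group are refused", {
  tab <- tiny_table(c(-1, 0, 1), c("a", "b", "b"))
  expect_error(loo_classify(tab, case_group = "a"),
               class = "phenoconn_validation_error")
})

test_that("composites average posteriors and apply the strict-cutoff rule", {
  sc <- data.frame(conversation_id = paste0("c", 1:7),
                   participant_id = c("p1", "p1", "p1", "p2", "p2", "p2", "p3"),
                   group = c(rep("case", 3), rep("ctrl", 4)),
                   decision_value = 0,
                   posterior = c(0.2, 0.4, 0.6, 0.5, 0.5, 0.5, 0.8))
  class(sc) <- c("conversation_scores", "data.frame")
  attr(sc, "case_group") <- "case"
  cmp <- composite_scores(sc, cutoff = 0.5, case_group = "case")
  expect_equal(cmp$composite[cmp$participant_id == "p1"], 0.4)
  expect_equal(cmp$predicted_group[cmp$participant_id == "p1"], "case")
  # composite exactly at the cutoff is control ("lower than" rule)
  expect_equal(cmp$composite[cmp$participant_id == "p2"], 0.5)
  expect_equal(cmp$predicted_group[cmp$participant_id == "p2"], "ctrl")
  # single conversation: composite is that posterior
  expect_equal(cmp$composite[cmp$participant_id == "p3"], 0.8)
  expect_true(all(cmp$composite >= 0 & cmp$composite <= 1))

  # a rostered participant without conversations is dropped with a warning
  roster <- data.frame(participant_id = c("p1", "p2", "p3", "p4"),
                       group = c("case", "ctrl", "ctrl", "ctrl"))
  expect_warning(cmp2 <- composite_scores(sc, roster, case_group = "case"),
                 "p4")
  expect_equal(nrow(cmp2), 3L)

  expect_equal(evaluate_accuracy(cmp), 1.0)
  flipped <- cmp
  flipped$predicted_group[1] <- setdiff(c("case", "ctrl"),
                                        cmp$predicted_group[1])
  expect_equal(evaluate_accuracy(flipped), 2 / 3)
})

test_that("permutation test boundary arithmetic and label-preserving null", {
  set.seed(4)
  # strongly separated cohort: observed accuracy beats every permutation
  tab <- tiny_table(c(rnorm(6, -6), rnorm(6, 6)),
                    rep(c("case", "ctrl"), each = 6),
                    participant = rep(paste0("p", 1:6), each = 2))
  pt <- permutation_test(tab, n_permutations = 60, seed = 8,
                         case_group = "case")
  expect_equal(pt$observed_accuracy, 1.0)
  expect_equal(pt$permutation_p, sum(pt$null_accuracies > 1) / 60)
  expect_equal(pt$permutation_p_smoothed,
               (sum(pt$null_accuracies >= 1) + 1) / 61)
  expect_true(pt$permutation_p_smoothed > 0)
  expect_length(pt$null_accuracies, 60L)
})

test_that("Monte-Carlo permutation p matches the exhaustive relabeling null", {
  # 4 participants, one conversation each: only 6 distinct balanced
  # relabelings exist; enumerate them as the oracle
  vals <- c(-1.1, 0.4, -0.3, 0.9)
  tab <- tiny_table(vals, c("a", "a", "b", "b"))
  acc_for <- function(groups) {
    t2 <- tab
    t2$group <- groups
    evaluate_accuracy(composite_scores(loo_classify(t2, case_group = "a"),
                                       case_group = "a"))
  }
  obs <- acc_for(tab$group)
  null_ex <- apply(combn(4, 2), 2, function(ii) {
    g <- rep("b", 4); g[ii] <- "a"; acc_for(g)
  })
  p_ex <- mean(null_ex > obs)
  pt <- permutation_test(tab, n_permutations = 600, seed = 13,
                         case_group = "a")
  expect_equal(pt$permutation_p, p_ex, tolerance = 0.05)
  # every null accuracy must be attainable from the 6 relabelings
  expect_true(all(pt$null_accuracies %in% null_ex))
})

test_that("severity validation reproduces hand-worked rank correlations", {
  cmp <- data.frame(participant_id = paste0("p", 1:5),
                    composite = c(0.1, 0.2, 0.3, 0.4, 0.45),
                    true_group = "case")
  # strictly decreasing severity: rho exactly -1
  sev <- data.frame(participant_id = paste0("p", 1:5),
                    severity = c(14, 12, 11, 9, 7))
  out <- validate_severity(cmp, sev)
  expect_equal(out$rho, -1)
  expect_equal(out$p_value, stats::cor.test(cmp$composite, sev$severity,
                                            method = "spearman",
                                            exact = TRUE)$p.value)

  # one tie, average ranks: oracle is the Pearson correlation of
  # hand-assigned ranks (severity 10,9,9,8,7 -> ranks 5, 3.5, 3.5, 2, 1)
  sev2 <- data.frame(participant_id = paste0("p", 1:5),
                     severity = c(10, 9, 9, 8, 7))
  out2 <- validate_severity(cmp, sev2)
  expect_equal(out2$rho, cor(1:5, c(5, 3.5, 3.5, 2, 1)), tolerance = 1e-12)

  # monotone relabeling of severity leaves rho unchanged
  sev3 <- sev2
  sev3$severity <- sev2$severity^3 + 2
  expect_equal(validate_severity(cmp, sev3)$rho, out2$rho)

  expect_error(validate_severity(cmp[1:3, ], sev),
               class = "phenoconn_validation_error")
})

test_that("ROC points and AUC match the exhaustive pair-counting oracle", {
  mk <- function(comp, groups) {
    d <- data.frame(participant_id = paste0("p", seq_along(comp)),
                    composite = comp, true_group = groups)
    attr(d, "case_group") <- "case"
    d
  }
  perfect <- mk(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                rep(c("case", "ctrl"), each = 3))
  expect_equal(roc_analysis(perfect)$auc, 1.0)
  same <- mk(rep(c(0.3, 0.6, 0.9), 2), rep(c("case", "ctrl"), each = 3))
  expect_equal(roc_analysis(same)$auc, 0.5)
  # 3 vs 3 with a tied pair: all 9 pairs enumerated by the oracle
  tied <- mk(c(0.2, 0.5, 0.6, 0.5, 0.7, 0.9),
             rep(c("case", "ctrl"), each = 3))
  expect_equal(roc_analysis(tied)$auc,
               bf_auc(c(0.2, 0.5, 0.6), c(0.5, 0.7, 0.9)))
  # cross-check against pROC on random scores
  skip_if_not_installed("pROC")
  set.seed(6)
  rnd <- mk(runif(14), rep(c("case", "ctrl"), 7))
  ref <- pROC::auc(pROC::roc(rnd$true_group, rnd$composite,
                             levels = c("case", "ctrl"),
                             direction = "<", quiet = TRUE))
  expect_equal(roc_analysis(rnd)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("the partner-speech control runs the identical chain", {
  st <- simulate_study(simulation_config(seed = 31, n_case = 6,
                                         n_control = 6, n_features = 8,
                                         n_informative = 4),
                       timeseries = FALSE)
  cfg <- run_config(seed = 31, n_permutations = 19, case_group = "autism")
  # partner table identical to participant table reproduces the results
  ev_main <- evaluate_classifier(st$features, cfg)
  ev_ctrl <- control_classifier(st$features, st$features, cfg)
  expect_equal(ev_ctrl$accuracy, ev_main$accuracy)
  expect_equal(ev_ctrl$permutation_p, ev_main$permutation_p)
  expect_equal(ev_ctrl$roc_auc, ev_main$roc_auc)
  # missing conversation: validation error
  expect_error(control_classifier(st$features[-1, ], st$features, cfg),
               class = "phenoconn_validation_error")
})
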