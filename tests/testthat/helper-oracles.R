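# Independent oracles and small fixture builders used across the suite.

# Brute-force soft-margin linear SVM: minimize the convex primal
# objective 0.5*||w||^2 + C*sum(hinge) over (w, b) directly, via a
# sequence of smoothed-hinge problems (softplus smoothing mu -> 0) solved
# by BFGS with warm starts.  Independent of the package's dual SMO solver.
bf_svm <- function(X, y, C = 1) {
  d <- ncol(X) + 1L
  hinge_obj <- function(par) {
    z <- 1 - y * (X %*% par[-d] + par[d])
    0.5 * sum(par[-d]^2) + C * sum(pmax(z, 0))
  }
  par <- rep(0, d)
  for (mu in c(0.5, 0.1, 0.02, 0.004, 5e-4, 5e-5, 5e-6)) {
    obj <- function(par) {
      z <- drop(1 - y * (X %*% par[-d] + par[d])) / mu
      0.5 * sum(par[-d]^2) +
        C * mu * sum(pmax(z, 0) + log1p(exp(-abs(z))))
    }
    grad <- function(par) {
      z <- drop(1 - y * (X %*% par[-d] + par[d])) / mu
      s <- plogis(z)  # d/dz of softplus
      gw <- par[-d] - C * drop(t(X) %*% (y * s))
      c(gw, -C * sum(y * s))
    }
    par <- optim(par, obj, grad, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))$par
  }
  list(w = par[-d], b = par[d], obj = hinge_obj(par))
}

bf_svm_decision <- function(Xtr, ytr, Xte, C = 1) {
  fit <- bf_svm(Xtr, ytr, C)
  drop(Xte %*% fit$w + fit$b)
}

# Brute-force connectedness: full correlation matrix, off-diagonal row
# means.
bf_connectedness <- function(mat) {
  R <- cor(t(mat))
  diag(R) <- NA
  rowMeans(R, na.rm = TRUE)
}

# Exhaustive pair-counting AUC: P(control score > case score) + 0.5 ties.
bf_auc <- function(case_scores, control_scores) {
  s <- 0
  for (a in control_scores)
    for (b in case_scores)
      s <- s + (a > b) + 0.5 * (a == b)
  s / (length(case_scores) * length(control_scores))
}

# Minimal hand-built feature table.
tiny_table <- function(values, groups,
                       participant = paste0("p", seq_along(values)),
                       extra = NULL) {
  df <- data.frame(conversation_id = paste0("c", seq_along(values)),
                   participant_id = participant,
                   group = groups, f1 = values,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  as_feature_table(df)
}

# Random scan with given dimensions.
random_scan <- function(n_nodes, n_time, scan_id = "s1",
                        participant_id = "p1", seed = 1) {
  set.seed(seed)
  nodes <- data.frame(node_id = sprintf("n%02d", seq_len(n_nodes)),
                      hemisphere = rep_len(c("L", "R"), n_nodes),
                      x = as.numeric(seq_len(n_nodes)), y = 0, z = 0)
  scan_timeseries(scan_id, participant_id,
                  matrix(rnorm(n_nodes * n_time), n_nodes, n_time),
                  nodes, age = 20, motion = 0.1)
}

# Map set built directly from a node x scan value matrix (one scan per
# participant unless stated), bypassing time series.
synthetic_map_set <- function(values, groups,
                              participant = paste0("p", seq_len(ncol(values))),
                              age = NULL, motion = NULL) {
  n <- ncol(values)
  ids <- sprintf("n%02d", seq_len(nrow(values)))
  if (is.null(age)) age <- rep(20, n)
  if (is.null(motion)) motion <- rep(0.1, n)
  maps <- lapply(seq_len(n), function(j) {
    m <- data.frame(node_id = ids, value = values[, j],
                    stringsAsFactors = FALSE)
    attr(m, "scan_id") <- paste0("scan", j)
    attr(m, "participant_id") <- participant[j]
    attr(m, "age") <- age[j]
    attr(m, "motion") <- motion[j]
    attr(m, "scale") <- "r"
    class(m) <- c("connectedness_map", "data.frame")
    m
  })
  roster <- unique(data.frame(participant_id = participant, group = groups,
                              stringsAsFactors = FALSE))
  as_map_set(maps, roster)
}
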