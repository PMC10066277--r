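# Whole-brain connectedness mapping: per-scan node-wise mean correlation
# maps, node-wise mixed-effects group contrasts, permutation-calibrated
# cluster-extent thresholds, the multi-threshold robustness map, and ROI
# selection.

#' Compute the whole-brain connectedness map of one scan
#'
#' Correlates every node's time series with every other node's, averages
#' those correlations, and stores the average back at the node: node i's
#' connectedness is `mean_{j != i} r(i, j)` (a weighted-degree-like
#' measure of global functional involvement).  With `fisher_z = TRUE` the
#' average is taken over `atanh(r)` and reported on the z scale (never
#' back-transformed).  Constant nodes get `NA` and are excluded from the
#' other nodes' averages.
#'
#' @param scan a `scan_timeseries`.
#' @param fisher_z average Fisher z-transformed correlations.
#' @return data.frame `node_id`, `value` with attributes `scan_id`,
#'   `participant_id`, `age`, `motion` and `scale` (`"r"` or `"z"`).
#' @export
compute_connectedness <- function(scan, fisher_z = FALSE) {
  if (ncol(scan$mat) < 3L)
    err_validation(sprintf("scan %s has fewer than 3 timepoints",
                           scan$scan_id))
  sds <- apply(scan$mat, 1L, stats::sd)
  ok <- sds > 0
  if (!any(ok)) err_validation(sprintf("scan %s: all nodes constant",
                                       scan$scan_id))
  R <- suppressWarnings(stats::cor(t(scan$mat[ok, , drop = FALSE])))
  if (fisher_z) R <- fisher_z(R)
  diag(R) <- NA_real_
  vals <- rep(NA_real_, nrow(scan$mat))
  vals[ok] <- rowMeans(R, na.rm = TRUE)
  out <- data.frame(node_id = scan$nodes$node_id, value = vals,
                    stringsAsFactors = FALSE)
  attr(out, "scan_id") <- scan$scan_id
  attr(out, "participant_id") <- scan$participant_id
  attr(out, "age") <- scan$age
  attr(out, "motion") <- scan$motion
  attr(out, "scale") <- if (fisher_z) "z" else "r"
  class(out) <- c("connectedness_map", "data.frame")
  out
}

#' Collect per-scan maps into a map set
#'
#' A map set holds the node-by-scan value matrix plus scan covariates and
#' node metadata; it is the input of the group-contrast, calibration and
#' compensation stages.  All maps must share the node panel and value
#' scale (raw-r and Fisher-z maps must not be mixed in one contrast).
#'
#' @param maps list of `connectedness_map` (or per-scan seed-correlation
#'   maps from [seed_connectivity_map()]).
#' @param roster data.frame `participant_id`, `group`.
#' @param nodes optional node metadata (`node_id`, `hemisphere`, coords).
#' @return A `map_set`: list with `values` (nodes x scans matrix),
#'   `scans` (scan_id, participant_id, group, age, motion), `nodes`,
#'   `scale`.
#' @export
as_map_set <- function(maps, roster, nodes = NULL) {
  if (!length(maps)) err_validation("empty map list")
  scales <- vapply(maps, function(m) attr(m, "scale") %||% "r", character(1))
  if (length(unique(scales)) != 1L)
    err_validation("cannot mix raw-r and Fisher-z maps in one map set")
  ids <- maps[[1L]]$node_id
  for (m in maps)
    if (!identical(m$node_id, ids))
      err_validation("maps do not share an identical node panel")
  values <- vapply(maps, function(m) m$value, numeric(length(ids)))
  if (is.null(dim(values))) values <- matrix(values, nrow = length(ids))
  rownames(values) <- ids
  scans <- data.frame(
    scan_id = vapply(maps, function(m) attr(m, "scan_id"), character(1)),
    participant_id = vapply(maps, function(m) attr(m, "participant_id"),
                            character(1)),
    age = vapply(maps, function(m) attr(m, "age") %||% NA_real_, numeric(1)),
    motion = vapply(maps, function(m) attr(m, "motion") %||% NA_real_,
                    numeric(1)),
    stringsAsFactors = FALSE)
  colnames(values) <- scans$scan_id
  scans$group <- roster$group[match(scans$participant_id,
                                    roster$participant_id)]
  if (anyNA(scans$group))
    err_validation("scan participant(s) missing from roster")
  structure(list(values = values, scans = scans, nodes = nodes,
                 scale = scales[1L]),
            class = "map_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Connectedness maps for a whole scan collection
#'
#' @param scans list of `scan_timeseries`.
#' @param roster data.frame `participant_id`, `group`.
#' @param fisher_z passed to [compute_connectedness()].
#' @return A `map_set`.
#' @export
connectedness_map_set <- function(scans, roster, fisher_z = FALSE) {
  maps <- lapply(scans, compute_connectedness, fisher_z = fisher_z)
  as_map_set(maps, roster, nodes = scans[[1L]]$nodes)
}

# Participant-level design and averaged response matrix for the OLS
# engine and the permutation null: scans are averaged within participant.
.participant_average <- function(mapset) {
  sc <- mapset$scans
  pid <- unique(sc$participant_id)
  idx <- split(seq_len(nrow(sc)), factor(sc$participant_id, levels = pid))
  Y <- vapply(idx, function(ii)
    rowMeans(mapset$values[, ii, drop = FALSE]), numeric(nrow(mapset$values)))
  cov <- data.frame(
    participant_id = pid,
    group = sc$group[match(pid, sc$participant_id)],
    age = vapply(idx, function(ii) mean(sc$age[ii]), numeric(1)),
    motion = vapply(idx, function(ii) mean(sc$motion[ii]), numeric(1)),
    stringsAsFactors = FALSE)
  list(Y = Y, cov = cov)  # Y: nodes x participants
}

# Node-wise OLS contrast of case vs control on participant-averaged maps.
# Returns estimate, t, df for the case indicator, vectorized over nodes.
# Constant covariates (aliased with the intercept) are tolerated via the
# pivoted QR; only the group indicator must stay estimable.
.ols_contrast <- function(Y, cov, case_group, covariates = TRUE) {
  case <- as.numeric(cov$group == case_group)
  X <- if (covariates) cbind(1, case, cov$age, cov$motion) else cbind(1, case)
  qrX <- qr(X)
  n <- nrow(X); r <- qrX$rank
  piv <- qrX$pivot[seq_len(r)]
  ci <- match(2L, piv)
  if (is.na(ci))
    err_validation("group indicator is collinear with the covariates")
  resid <- qr.resid(qrX, t(Y))
  sigma2 <- colSums(resid^2) / (n - r)
  R1 <- qr.R(qrX)[seq_len(r), seq_len(r), drop = FALSE]
  xtx_inv <- chol2inv(R1)
  se <- sqrt(sigma2 * xtx_inv[ci, ci])
  est <- qr.coef(qrX, t(Y))[2L, ]
  list(estimate = est, t = est / se, df = n - r)
}

#' Node-wise mixed-effects group contrast of connectedness maps
#'
#' For every node, fits `value ~ group + age + motion + (1 | participant)`
#' across scans by REML (multiple scans per participant share a random
#' intercept) and reports the group fixed effect signed case-minus-
#' control with its t statistic, degrees of freedom, two-sided p and
#' one-sided (case > control) p.  Degrees of freedom use the Satterthwaite
#' approximation by default (`df_method = "residual"` uses the residual
#' count `n_scans - n_fixed` instead).  Nodes with a singular mixed fit
#' fall back to ordinary regression on participant-averaged values and
#' are flagged.  `engine = "ols"` uses the participant-averaged ordinary
#' regression everywhere.
#'
#' @param mapset a `map_set`.
#' @param case_group case-group label.
#' @param engine `"lmm"` (default) or `"ols"`.
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @param covariates include age and motion (default `TRUE`).
#' @return A `group_contrast`: data.frame `node_id`, `estimate`, `t`,
#'   `df`, `p`, `p_one`, `fallback`; attribute `model` describes the fit.
#' @export
fit_group_contrast <- function(mapset, case_group,
                               engine = c("lmm", "ols"),
                               df_method = c("satterthwaite", "residual"),
                               covariates = TRUE) {
  engine <- match.arg(engine)
  df_method <- match.arg(df_method)
  sc <- mapset$scans
  if (length(unique(sc$group)) != 2L)
    err_validation("group contrast needs exactly two groups")
  if (!case_group %in% sc$group)
    err_validation(sprintf("case_group '%s' not present", case_group))
  if (covariates && (anyNA(sc$age) || anyNA(sc$motion)))
    err_validation("age/motion covariates contain missing values")
  nodes <- rownames(mapset$values)

  if (engine == "ols") {
    pa <- .participant_average(mapset)
    o <- .ols_contrast(pa$Y, pa$cov, case_group, covariates)
    res <- data.frame(node_id = nodes, estimate = o$estimate, t = o$t,
                      df = o$df, p = t_pvalue(o$t, o$df),
                      p_one = t_pvalue_upper(o$t, o$df),
                      fallback = FALSE, stringsAsFactors = FALSE)
    attr(res, "model") <- "participant-mean OLS: value ~ group (+ age + motion)"
    class(res) <- c("group_contrast", "data.frame")
    return(res)
  }

  dat <- data.frame(case = as.numeric(sc$group == case_group),
                    age = sc$age, motion = sc$motion,
                    participant = sc$participant_id,
                    value = mapset$values[1L, ])
  form <- if (covariates)
    value ~ case + age + motion + (1 | participant)
  else value ~ case + (1 | participant)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  base_fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE, control = ctrl))),
    error = function(e) NULL)
  pa <- NULL
  if (is.null(base_fit)) {
    # random intercept unidentifiable (e.g. one scan per participant):
    # every node falls back to the participant-averaged OLS, flagged
    pa <- .participant_average(mapset)
    o <- .ols_contrast(pa$Y, pa$cov, case_group, covariates)
    res <- data.frame(node_id = nodes, estimate = o$estimate, t = o$t,
                      df = o$df, p = t_pvalue(o$t, o$df),
                      p_one = t_pvalue_upper(o$t, o$df),
                      fallback = TRUE, stringsAsFactors = FALSE)
    attr(res, "model") <-
      "participant-mean OLS fallback: value ~ group (+ age + motion)"
    class(res) <- c("group_contrast", "data.frame")
    return(res)
  }
  n_fixed <- length(lme4::fixef(base_fit))

  one_node <- function(vals) {
    fm <- tryCatch(suppressMessages(suppressWarnings(
      lme4::refit(base_fit, newresp = vals))), error = function(e) NULL)
    if (is.null(fm) || lme4::isSingular(fm, tol = 1e-5)) return(NULL)
    if (df_method == "satterthwaite") {
      fmt <- tryCatch(suppressMessages(suppressWarnings(
        lmerTest::as_lmerModLmerTest(fm))), error = function(e) NULL)
      if (is.null(fmt)) return(NULL)
      co <- tryCatch(suppressWarnings(stats::coef(summary(fmt))),
                     error = function(e) NULL)
      if (is.null(co) || !is.finite(co["case", "df"])) return(NULL)
      c(co["case", "Estimate"], co["case", "t value"], co["case", "df"])
    } else {
      co <- stats::coef(summary(fm))
      c(co["case", "Estimate"], co["case", "t value"],
        nrow(dat) - n_fixed)
    }
  }

  out <- matrix(NA_real_, length(nodes), 3L)
  fallback <- logical(length(nodes))
  for (k in seq_along(nodes)) {
    r <- one_node(mapset$values[k, ])
    if (is.null(r)) {
      # singular or failed mixed fit: participant-averaged OLS, flagged
      if (is.null(pa)) pa <- .participant_average(mapset)
      o <- .ols_contrast(pa$Y[k, , drop = FALSE], pa$cov, case_group,
                         covariates)
      r <- c(o$estimate, o$t, o$df)
      fallback[k] <- TRUE
    }
    out[k, ] <- r
  }
  res <- data.frame(node_id = nodes, estimate = out[, 1L], t = out[, 2L],
                    df = out[, 3L], p = t_pvalue(out[, 2L], out[, 3L]),
                    p_one = t_pvalue_upper(out[, 2L], out[, 3L]),
                    fallback = fallback, stringsAsFactors = FALSE)
  attr(res, "model") <- paste0(
    "LMM (REML, ", df_method, " df): value ~ group",
    if (covariates) " + age + motion", " + (1 | participant)")
  class(res) <- c("group_contrast", "data.frame")
  res
}

#' Node adjacency from an edge list or coordinate proximity
#'
#' @param nodes node metadata (`node_id`, optional `x`,`y`,`z`).
#' @param radius connect nodes whose Euclidean coordinate distance is
#'   `<= radius` (requires coordinates).
#' @param edges data.frame `node_a`, `node_b` of undirected edges
#'   (alternative to `radius`).
#' @return A `node_adjacency`: list with `node_id` and `neighbors`
#'   (integer index lists).  With neither `radius` nor `edges`, every
#'   node is isolated.
#' @export
node_adjacency <- function(nodes, radius = NULL, edges = NULL) {
  ids <- as.character(nodes$node_id)
  n <- length(ids)
  nb <- rep(list(integer(0)), n)
  if (!is.null(edges)) {
    ia <- match(as.character(edges$node_a), ids)
    ib <- match(as.character(edges$node_b), ids)
    if (anyNA(ia) || anyNA(ib))
      err_validation("edge list refers to unknown node id(s)")
    for (k in seq_along(ia)) {
      if (ia[k] == ib[k]) next
      nb[[ia[k]]] <- c(nb[[ia[k]]], ib[k])
      nb[[ib[k]]] <- c(nb[[ib[k]]], ia[k])
    }
    nb <- lapply(nb, function(v) sort(unique(v)))
  } else if (!is.null(radius)) {
    cc <- intersect(c("x", "y", "z"), names(nodes))
    if (!length(cc))
      err_validation("radius adjacency requires node coordinates")
    M <- as.matrix(nodes[, cc, drop = FALSE])
    D <- as.matrix(stats::dist(M))
    for (k in seq_len(n))
      nb[[k]] <- setdiff(which(D[k, ] <= radius), k)
  }
  structure(list(node_id = ids, neighbors = nb), class = "node_adjacency")
}

#' Connected components of a supra-threshold node set
#'
#' Breadth-first search over the adjacency restricted to significant
#' nodes; isolated significant nodes form singleton clusters.
#'
#' @param significant logical vector over the adjacency's nodes (or a
#'   character vector of significant node ids).
#' @param adjacency a `node_adjacency`.
#' @return List of clusters, each a character vector of node ids, ordered
#'   by decreasing size.
#' @export
find_clusters <- function(significant, adjacency) {
  ids <- adjacency$node_id
  sig <- if (is.character(significant)) ids %in% significant
         else as.logical(significant)
  if (length(sig) != length(ids))
    err_validation("significance vector does not match adjacency nodes")
  sig[is.na(sig)] <- FALSE
  seen <- !sig
  clusters <- list()
  for (s in which(sig)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, v)
      for (w in adjacency$neighbors[[v]]) {
        if (!seen[w] && sig[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    clusters[[length(clusters) + 1L]] <- ids[sort(members)]
  }
  clusters[order(-vapply(clusters, length, integer(1)))]
}

#' Calibrate cluster-extent thresholds by group-label permutation
#'
#' For each voxelwise threshold, repeatedly permutes the group labels at
#' the participant level, recomputes the node-wise one-sided contrast on
#' the permuted labels (participant-averaged ordinary regression — the
#' fast permutation-null engine), records the largest supra-threshold
#' cluster, and returns the 95th percentile of that maximum-cluster-size
#' distribution as the minimum extent `k`.  Because supra-threshold maps
#' are nested across the descending threshold ladder, the returned `k`
#' values are non-increasing with stringency.
#'
#' @param mapset a `map_set`.
#' @param case_group case-group label.
#' @param adjacency a `node_adjacency`.
#' @param thresholds descending voxelwise significance levels.
#' @param n_iter number of permutations (>= 100).
#' @param seed seed for the calibration stream.
#' @param percentile percentile of the max-cluster-size null (default
#'   0.95, i.e. familywise alpha 0.05 per threshold).
#' @param covariates include age and motion in the null model.
#' @return A `cluster_extent_table`: data.frame `threshold`, `k`.
#' @export
calibrate_cluster_extent <- function(mapset, case_group, adjacency,
                                     thresholds = c(0.005, 0.001, 0.0005,
                                                    0.0001, 0.00005, 0.00001),
                                     n_iter = 1000, seed = 1,
                                     percentile = 0.95, covariates = TRUE) {
  if (n_iter < 100) err_validation("extent calibration needs n_iter >= 100")
  if (n_iter * (1 - percentile) < 1)
    err_validation("n_iter too small for the requested percentile")
  if (length(thresholds) > 1L && any(diff(thresholds) >= 0))
    err_validation("thresholds must be strictly decreasing")
  pa <- .participant_average(mapset)
  n_part <- nrow(pa$cov)
  maxsize <- matrix(0L, n_iter, length(thresholds))
  with_seed(substream_seed(seed, "extent_calibration"), {
    for (b in seq_len(n_iter)) {
      cov_b <- pa$cov
      cov_b$group <- sample(cov_b$group)
      o <- .ols_contrast(pa$Y, cov_b, case_group, covariates)
      p_one <- t_pvalue_upper(o$t, o$df)
      for (ti in seq_along(thresholds)) {
        cl <- find_clusters(p_one < thresholds[ti], adjacency)
        maxsize[b, ti] <- if (length(cl)) length(cl[[1L]]) else 0L
      }
    }
  })
  k <- vapply(seq_along(thresholds), function(ti)
    max(1, stats::quantile(maxsize[, ti], percentile, type = 1L,
                           names = FALSE)), numeric(1))
  res <- data.frame(threshold = thresholds, k = as.integer(k))
  class(res) <- c("cluster_extent_table", "data.frame")
  res
}

#' Combine thresholded contrasts into a robustness map
#'
#' Thresholds the one-sided (case > control) contrast at each level of
#' the descending ladder, applies the matching cluster extent, binarizes,
#' and records per node the most stringent level at which the node lies
#' in a surviving cluster (0 = none).
#'
#' @param contrast a `group_contrast`.
#' @param extents a `cluster_extent_table` (thresholds must match; pass
#'   an externally supplied table — e.g. a reference `k` ladder — to skip
#'   calibration).
#' @param adjacency a `node_adjacency`.
#' @return A `robustness_map`: data.frame `node_id`, `max_threshold_index`
#'   (attribute `n_thresholds`).
#' @export
build_robustness_map <- function(contrast, extents, adjacency) {
  thresholds <- extents$threshold
  if (length(thresholds) > 1L && any(diff(thresholds) >= 0))
    err_validation("extent table thresholds must be strictly decreasing")
  if (anyNA(extents$k))
    err_validation("extent table is missing a k value")
  idx <- integer(nrow(contrast))
  for (ti in seq_along(thresholds)) {
    sig <- contrast$p_one < thresholds[ti]
    cl <- find_clusters(sig, adjacency)
    surv <- unlist(cl[vapply(cl, length, integer(1)) >= extents$k[ti]])
    idx[contrast$node_id %in% surv] <- ti
  }
  res <- data.frame(node_id = contrast$node_id, max_threshold_index = idx,
                    stringsAsFactors = FALSE)
  attr(res, "n_thresholds") <- length(thresholds)
  class(res) <- c("robustness_map", "data.frame")
  res
}

#' Select regions of interest from a robustness map
#'
#' Keeps the nodes that survived every threshold of the ladder, groups
#' them into clusters, and returns clusters of at least `min_size` nodes
#' (default 10) as named ROIs with selection provenance.
#'
#' @param robustness a `robustness_map`.
#' @param adjacency a `node_adjacency`.
#' @param min_size minimum cluster size.
#' @param min_index required `max_threshold_index` (default: the full
#'   ladder, i.e. survived every threshold).
#' @return An `roi_set`: named list of ROIs, each `list(name, nodes,
#'   size, min_index)`; empty list if nothing qualifies.
#' @export
select_rois <- function(robustness, adjacency, min_size = 10,
                        min_index = attr(robustness, "n_thresholds")) {
  keep <- robustness$max_threshold_index >= min_index
  cl <- find_clusters(robustness$node_id[keep], adjacency)
  cl <- cl[vapply(cl, length, integer(1)) >= min_size]
  rois <- lapply(seq_along(cl), function(i)
    list(name = sprintf("ROI%d", i), nodes = cl[[i]],
         size = length(cl[[i]]), min_index = min_index))
  names(rois) <- vapply(rois, `[[`, character(1), "name")
  class(rois) <- "roi_set"
  rois
}

#' @exportS3Method base::print
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: %d region(s)\n", length(x)))
  for (r in x)
    cat(sprintf("  %s: %d nodes (%s%s)\n", r$name, r$size,
                paste(utils::head(r$nodes, 6), collapse = ", "),
                if (r$size > 6) ", ..." else ""))
  invisible(x)
}
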