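# Compensation testing: per-ROI group-by-score interaction on whole-brain
# connectedness, per-group correlations, Bonferroni correction, and the
# seed-based follow-up contrast with hemisphere counts.

#' Mean connectedness of an ROI per scan or participant
#'
#' @param mapset a `map_set`.
#' @param roi character vector of node ids (or an element of an
#'   [select_rois()] `roi_set`).
#' @param aggregate_participant average a participant's scan values into
#'   one participant-level value (the level at which the per-group
#'   correlations are reported).
#' @return data.frame with `value` keyed by `scan_id` (plus
#'   `participant_id`) or by `participant_id`.
#' @export
roi_connectedness <- function(mapset, roi, aggregate_participant = FALSE) {
  if (is.list(roi)) roi <- roi$nodes
  if (!length(roi)) err_validation("empty ROI")
  missing <- setdiff(roi, rownames(mapset$values))
  if (length(missing))
    err_validation(sprintf("ROI node(s) missing from maps: %s",
                           paste(missing, collapse = ", ")))
  vals <- colMeans(mapset$values[roi, , drop = FALSE])
  bad <- which(is.na(vals))
  if (length(bad))
    err_validation(sprintf("ROI value undefined (constant node?) in scan %s",
                           mapset$scans$scan_id[bad[1L]]))
  per_scan <- data.frame(scan_id = mapset$scans$scan_id,
                         participant_id = mapset$scans$participant_id,
                         value = as.numeric(vals),
                         stringsAsFactors = FALSE)
  if (!aggregate_participant) return(per_scan)
  agg <- tapply(per_scan$value, per_scan$participant_id, mean)
  data.frame(participant_id = names(agg), value = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Group-by-score interaction test on ROI connectedness
#'
#' The compensation test: fits `Connectivity ~ Score + Group +
#' Score:Group` (optionally plus age and motion) and reports the
#' interaction term.  A compensation signature is a significantly more
#' positive score slope in the case group than in the control group.  The
#' interaction is signed as (case slope - control slope).
#'
#' Two observation levels are supported: `level = "scan"` (default) fits
#' all scans with a per-participant random intercept (REML, Satterthwaite
#' df); `level = "participant"` averages scans within participant and
#' fits ordinary least squares, whose residual df with no covariates is
#' `n - 4`.
#'
#' @param roi_values per-scan ROI values from [roi_connectedness()]
#'   (`aggregate_participant = FALSE`).
#' @param composites `participant_composites` (or any data.frame
#'   `participant_id`, `composite`).
#' @param roster data.frame `participant_id`, `group`.
#' @param covariates data.frame `scan_id`/`participant_id`, `age`,
#'   `motion`, or `NULL` to omit covariates.
#' @param case_group case-group label.
#' @param level `"scan"` or `"participant"`.
#' @param bonferroni_alpha corrected alpha the result is judged against.
#' @param roi_name label carried into the result.
#' @return A `compensation_result`: list with `roi`, `interaction`
#'   (estimate, t, df, p), `group_correlations` (per group: r, df, p, n),
#'   `slopes` (per-group fitted score slopes), `bonferroni_alpha`,
#'   `passes_bonferroni`, `model`.
#' @export
fit_interaction <- function(roi_values, composites, roster,
                            covariates = NULL, case_group = NULL,
                            level = c("scan", "participant"),
                            bonferroni_alpha = 0.05 / 3,
                            roi_name = "ROI") {
  level <- match.arg(level)
  case_group <- .resolve_case_group(roster$group, case_group)
  comp <- as.data.frame(composites)[, c("participant_id", "composite")]
  d <- merge(roi_values, comp, by = "participant_id")
  d$group <- roster$group[match(d$participant_id, roster$participant_id)]
  if (anyNA(d$group)) err_validation("participant(s) missing from roster")
  for (g in unique(d$group)) {
    dg <- d[d$group == g, ]
    if (length(unique(dg$participant_id)) < 3L)
      err_validation("each group needs at least 3 participants")
    if (stats::sd(dg$composite) == 0)
      err_validation(sprintf("classifier score constant in group '%s'", g))
  }
  d$case <- as.numeric(d$group == case_group)
  use_cov <- !is.null(covariates)
  if (use_cov) {
    key <- if ("scan_id" %in% names(covariates) && "scan_id" %in% names(d))
      "scan_id" else "participant_id"
    d <- merge(d, covariates[, c(key, "age", "motion")], by = key)
  }

  if (level == "participant" || !"scan_id" %in% names(d)) {
    agg <- stats::aggregate(
      d[, c("value", "composite", "case",
            if (use_cov) c("age", "motion"))],
      by = list(participant_id = d$participant_id), FUN = mean)
    form <- if (use_cov)
      value ~ composite * case + age + motion else value ~ composite * case
    fm <- stats::lm(form, data = agg)
    co <- stats::coef(summary(fm))["composite:case", ]
    est <- co[1L]; tstat <- co[3L]; df <- fm$df.residual
    p <- t_pvalue(tstat, df)
    model <- paste0("participant-mean OLS: value ~ score * group",
                    if (use_cov) " + age + motion")
  } else {
    form <- if (use_cov)
      value ~ composite * case + age + motion + (1 | participant_id)
    else value ~ composite * case + (1 | participant_id)
    fm <- suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = d, REML = TRUE)))
    co <- stats::coef(summary(fm))
    if (lme4::isSingular(fm, tol = 1e-5) ||
        !is.finite(co["composite:case", "df"])) {
      return(fit_interaction(roi_values, composites, roster, covariates,
                             case_group, level = "participant",
                             bonferroni_alpha = bonferroni_alpha,
                             roi_name = roi_name))
    }
    est <- co["composite:case", "Estimate"]
    tstat <- co["composite:case", "t value"]
    df <- co["composite:case", "df"]
    p <- co["composite:case", "Pr(>|t|)"]
    model <- paste0("LMM (REML, Satterthwaite): value ~ score * group",
                    if (use_cov) " + age + motion",
                    " + (1 | participant)")
  }

  # per-group score slopes and participant-level correlations
  slopes <- list(); cors <- list()
  for (g in unique(roster$group)) {
    dg <- d[d$group == g, ]
    ag <- stats::aggregate(dg[, c("value", "composite")],
                           by = list(participant_id = dg$participant_id),
                           FUN = mean)
    slopes[[g]] <- unname(stats::coef(stats::lm(value ~ composite,
                                                data = ag))[2L])
    cors[[g]] <- per_group_correlation(ag$value, ag$composite)
  }

  structure(list(roi = roi_name,
                 interaction = list(estimate = unname(est),
                                    t = unname(tstat), df = unname(df),
                                    p = unname(p)),
                 group_correlations = cors,
                 slopes = slopes,
                 case_group = case_group,
                 bonferroni_alpha = bonferroni_alpha,
                 passes_bonferroni = unname(p) < bonferroni_alpha,
                 model = model),
            class = "compensation_result")
}

#' @exportS3Method base::print
print.compensation_result <- function(x, ...) {
  cat(sprintf("Compensation test for %s\n", x$roi))
  cat(sprintf("  interaction: estimate %.4g, t(%.1f) = %.2f, p = %.4g%s\n",
              x$interaction$estimate, x$interaction$df, x$interaction$t,
              x$interaction$p,
              if (x$passes_bonferroni) " *" else ""))
  for (g in names(x$group_correlations)) {
    gc <- x$group_correlations[[g]]
    cat(sprintf("  %s: r(%d) = %.2f, p = %.4g\n", g, gc$df, gc$r, gc$p))
  }
  cat(sprintf("  Bonferroni alpha: %.4f (pass: %s)\n",
              x$bonferroni_alpha, x$passes_bonferroni))
  invisible(x)
}

#' Participant-level Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (participant-level values).
#' @return List `r`, `df` (`n - 2`), `p` (two-sided), `n`.
#' @export
per_group_correlation <- function(x, y) {
  n <- length(x)
  if (n < 4L) err_validation("correlation needs >= 4 participants")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    err_validation("zero variance in correlation input")
  r <- stats::cor(x, y)
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else t_pvalue(r * sqrt(df / (1 - r^2)), df)
  list(r = r, df = df, p = p, n = n)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha familywise alpha in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests` (unrounded; round only for display).
#' @export
#' @examples
#' bonferroni(0.05, 3)  # 0.016666...
bonferroni <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    err_validation("alpha must lie in (0, 1)")
  if (!is.numeric(n_tests) || n_tests < 1)
    err_validation("n_tests must be >= 1")
  alpha / n_tests
}

#' Seed-based connectivity map of one scan
#'
#' Averages the time series of the seed nodes and correlates that seed
#' signal with every non-seed node.
#'
#' @param scan a `scan_timeseries`.
#' @param seed_roi character vector of seed node ids (or an ROI from
#'   [select_rois()]).
#' @return data.frame `node_id`, `value` over non-seed nodes, with the
#'   same attributes as a connectedness map (`scale = "r"`).
#' @export
seed_connectivity_map <- function(scan, seed_roi) {
  if (is.list(seed_roi)) seed_roi <- seed_roi$nodes
  missing <- setdiff(seed_roi, scan$nodes$node_id)
  if (length(missing))
    err_validation(sprintf("seed node(s) missing from scan %s: %s",
                           scan$scan_id, paste(missing, collapse = ", ")))
  sidx <- scan$nodes$node_id %in% seed_roi
  seed_sig <- colMeans(scan$mat[sidx, , drop = FALSE])
  if (stats::sd(seed_sig) == 0)
    err_validation(sprintf("constant seed signal in scan %s", scan$scan_id))
  others <- scan$mat[!sidx, , drop = FALSE]
  r <- suppressWarnings(as.numeric(stats::cor(seed_sig, t(others))))
  out <- data.frame(node_id = scan$nodes$node_id[!sidx], value = r,
                    stringsAsFactors = FALSE)
  attr(out, "scan_id") <- scan$scan_id
  attr(out, "participant_id") <- scan$participant_id
  attr(out, "age") <- scan$age
  attr(out, "motion") <- scan$motion
  attr(out, "scale") <- "r"
  class(out) <- c("connectedness_map", "data.frame")
  out
}

#' Seed-map group contrast with hemisphere counts
#'
#' Computes per-scan seed-correlation maps, Fisher z-transforms them for
#' variance stabilization, fits the node-wise mixed-effects group
#' contrast (`value ~ group + age + motion + (1 | participant)`), applies
#' the voxelwise + cluster-extent significance scheme one-sided in the
#' case > control direction, and counts significant nodes per hemisphere.
#' Nodes without a hemisphere label are excluded from the counts (with a
#' warning) but remain in the significant set.
#'
#' @param scans list of `scan_timeseries`.
#' @param seed_roi seed node ids (or ROI).
#' @param roster data.frame `participant_id`, `group`.
#' @param case_group case-group label.
#' @param threshold voxelwise one-sided significance level (reference
#'   analysis: 0.001, corrected).
#' @param adjacency a `node_adjacency` over the non-seed nodes; `NULL`
#'   derives a radius-1 coordinate adjacency when coordinates exist, else
#'   leaves every node isolated.
#' @param extent_k minimum cluster size; `NULL` calibrates it by
#'   permutation via [calibrate_cluster_extent()].
#' @param n_iter,seed calibration settings (used when `extent_k` is NULL).
#' @param engine,covariates passed to [fit_group_contrast()].
#' @return A `seed_contrast_result`: list with `contrast` (per-node
#'   stats), `significant_nodes`, `left_count`, `right_count`, `ratio`
#'   (left/right; `Inf` flagged via `ratio_undefined` when no significant
#'   right-hemisphere node exists), `threshold`, `extent_k`.
#' @export
seed_group_contrast <- function(scans, seed_roi, roster, case_group,
                                threshold = 0.001, adjacency = NULL,
                                extent_k = NULL, n_iter = 1000, seed = 1,
                                engine = "lmm", covariates = TRUE) {
  maps <- lapply(scans, seed_connectivity_map, seed_roi = seed_roi)
  zmaps <- lapply(maps, function(m) {
    m$value <- fisher_z(m$value)
    attr(m, "scale") <- "z"
    m
  })
  nonseed <- scans[[1L]]$nodes[
    scans[[1L]]$nodes$node_id %in% maps[[1L]]$node_id, , drop = FALSE]
  mapset <- as_map_set(zmaps, roster, nodes = nonseed)
  if (is.null(adjacency)) {
    adjacency <- if (all(c("x", "y", "z") %in% names(nonseed)))
      node_adjacency(nonseed, radius = 1) else node_adjacency(nonseed)
  }
  contrast <- fit_group_contrast(mapset, case_group, engine = engine,
                                 covariates = covariates)
  if (is.null(extent_k)) {
    ext <- calibrate_cluster_extent(mapset, case_group, adjacency,
                                    thresholds = threshold,
                                    n_iter = n_iter, seed = seed,
                                    covariates = covariates)
    extent_k <- ext$k[1L]
  }
  cl <- find_clusters(contrast$p_one < threshold, adjacency)
  surv <- unlist(cl[vapply(cl, length, integer(1)) >= extent_k])
  surv <- as.character(surv %||% character(0))
  hemi <- nonseed$hemisphere[match(surv, nonseed$node_id)]
  if (length(surv) && anyNA(hemi))
    warning(sprintf("%d significant node(s) lack hemisphere labels",
                    sum(is.na(hemi))), call. = FALSE)
  left <- sum(hemi == "L", na.rm = TRUE)
  right <- sum(hemi == "R", na.rm = TRUE)
  structure(list(contrast = contrast,
                 significant_nodes = surv,
                 left_count = left, right_count = right,
                 ratio = if (right > 0) left / right else Inf,
                 ratio_undefined = right == 0,
                 threshold = threshold, extent_k = as.integer(extent_k)),
            class = "seed_contrast_result")
}

#' @exportS3Method base::print
print.seed_contrast_result <- function(x, ...) {
  cat(sprintf(
    "Seed-map group contrast (p < %g, k >= %d): %d significant node(s)\n",
    x$threshold, x$extent_k, length(x$significant_nodes)))
  cat(sprintf("  left: %d, right: %d (ratio %s)\n", x$left_count,
              x$right_count,
              if (x$ratio_undefined) "undefined (no right-hemisphere nodes)"
              else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Compensation tests across an ROI set with Bonferroni correction
#'
#' Runs [fit_interaction()] for every ROI, correcting the interaction
#' alpha over the number of ROIs tested.
#'
#' @param mapset a `map_set` of connectedness maps.
#' @param rois an `roi_set` from [select_rois()] (or named list of node-id
#'   vectors).
#' @param composites `participant_composites`.
#' @param roster data.frame `participant_id`, `group`.
#' @param covariates,case_group,level passed to [fit_interaction()].
#' @param alpha familywise alpha before correction.
#' @return Named list of `compensation_result`, one per ROI.
#' @export
compensation_analysis <- function(mapset, rois, composites, roster,
                                  covariates = NULL, case_group = NULL,
                                  level = "scan", alpha = 0.05) {
  if (!length(rois)) return(structure(list(), class = "compensation_set"))
  alpha_corr <- bonferroni(alpha, length(rois))
  out <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    vals <- roi_connectedness(mapset, roi)
    fit_interaction(vals, composites, roster, covariates = covariates,
                    case_group = case_group, level = level,
                    bonferroni_alpha = alpha_corr, roi_name = nm)
  })
  names(out) <- names(rois)
  structure(out, class = "compensation_set")
}
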