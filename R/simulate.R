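# Synthetic cohort generator.  Plants the structure the analysis assumes:
# a latent language-typicality trait separating the groups, linguistic
# features loading on that trait, severity scores for the case group tied
# to it, and parcellated scan time series built from a factor model in
# which a region set's coupling increases with typicality in the case
# group only (the planted compensation effect).

#' Simulation configuration
#'
#' Defaults mirror the reference study conditions: 19 case and 20 control
#' participants, 3 conversations each (117 conversations), 81 linguistic
#' features, 6-minute scans of 180 timepoints at a 2-s sampling interval.
#'
#' The time-series generator is a factor model: every node loads
#' `sqrt(baseline_connectivity)` on a global factor, giving a uniform
#' background correlation of `baseline_connectivity`; the compensation
#' node set and its partner node set additionally share a region factor
#' whose loading is `member_loading` for controls and `member_loading +
#' group_connectivity_delta + compensation_slope * theta` for case
#' participants (clipped to keep every implied covariance matrix positive
#' definite).  Optional `extra_regions` each get their own factor with the
#' same control/case loadings but no typicality slope.  Unit node
#' variances are enforced through the residual term, so planted pairwise
#' correlations are `baseline + c_i * c_j` within a region and `baseline`
#' elsewhere.
#'
#' @param n_case,n_control participants per group.
#' @param n_conversations conversations (and scans) per participant.
#' @param n_features total feature columns.
#' @param n_informative features loading on the latent trait.
#' @param feature_effect_size half-separation delta of the latent trait:
#'   case mean `-delta`, control mean `+delta`, unit variance.
#' @param feature_loading loading of each informative feature on the trait.
#' @param within_participant_sd SD of the participant-level random effect
#'   added to each informative feature.
#' @param noise_sd SD of conversation-level feature noise.
#' @param severity_link_strength rank-link in `[0, 1]` between the latent
#'   trait and the case-group severity score (1 = deterministic).
#' @param severity_range inclusive integer severity range (ordinal scale
#'   with a diagnostic floor).
#' @param n_nodes,n_timepoints scan dimensions.
#' @param baseline_connectivity background pairwise correlation in (0, 1).
#' @param member_loading control-group loading of region-factor members.
#' @param group_connectivity_delta case-group loading increment.
#' @param compensation_slope case-group loading slope on the latent trait.
#' @param compensation_node_set,partner_node_set node ids sharing the
#'   compensation factor (defaults: a right-hemisphere block of 10, and a
#'   12 left / 6 right partner block mirroring a 2:1 hemispheric split).
#' @param extra_regions optional list of node-id vectors, each sharing its
#'   own group-shifted factor.
#' @param age_range uniform age range in years.
#' @param motion_meanlog,motion_sdlog log-normal parameters of the
#'   participant-level motion summary; `motion_scan_jitter_sdlog` adds
#'   scan-level jitter on the log scale.
#' @param seed master seed; every generator stage uses a named substream.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_case = 19L, n_control = 20L,
                              n_conversations = 3L,
                              n_features = 81L, n_informative = 20L,
                              feature_effect_size = 0.7,
                              feature_loading = 0.5,
                              within_participant_sd = 0.5,
                              noise_sd = 1.0,
                              severity_link_strength = 0.6,
                              severity_range = c(7L, 14L),
                              n_nodes = 60L, n_timepoints = 180L,
                              baseline_connectivity = 0.10,
                              member_loading = 0.30,
                              group_connectivity_delta = 0.30,
                              compensation_slope = 0.10,
                              compensation_node_set = NULL,
                              partner_node_set = NULL,
                              extra_regions = list(),
                              age_range = c(14.7, 32.0),
                              motion_meanlog = log(0.10),
                              motion_sdlog = 0.40,
                              motion_scan_jitter_sdlog = 0.10,
                              seed = 1L) {
  if (n_case < 2L || n_control < 2L)
    err_validation("each group needs at least 2 participants")
  if (n_informative > n_features)
    err_validation("n_informative must not exceed n_features")
  if (severity_link_strength < 0 || severity_link_strength > 1)
    err_validation("severity_link_strength must lie in [0, 1]")
  if (baseline_connectivity <= 0 || baseline_connectivity >= 1)
    err_validation("baseline_connectivity must lie in (0, 1)")
  if (n_nodes < 2L) err_validation("n_nodes must be >= 2")

  nodes <- .default_nodes(n_nodes)
  if (is.null(compensation_node_set))
    compensation_node_set <- nodes$node_id[nodes$hemisphere == "R"][
      seq_len(min(10L, sum(nodes$hemisphere == "R")))]
  if (is.null(partner_node_set)) {
    ln <- setdiff(nodes$node_id[nodes$hemisphere == "L"], compensation_node_set)
    rn <- setdiff(nodes$node_id[nodes$hemisphere == "R"], compensation_node_set)
    partner_node_set <- c(ln[seq_len(min(12L, length(ln)))],
                          rn[seq_len(min(6L, length(rn)))])
  }
  all_sets <- c(list(compensation_node_set, partner_node_set), extra_regions)
  ids <- unlist(all_sets)
  if (anyDuplicated(ids))
    err_validation("compensation, partner and extra region node sets must be disjoint")
  if (!all(ids %in% nodes$node_id))
    err_validation("region node set refers to unknown node id(s)")

  # positive definiteness: unit variances need a^2 + c^2 < 1 for every
  # realizable member loading (case loadings are additionally clipped at
  # generation time, so only the control/base values are checked here).
  a2 <- baseline_connectivity
  cmax <- member_loading + max(0, group_connectivity_delta)
  if (a2 + cmax^2 >= 1)
    err_validation(sprintf(
      paste0("implied covariance not positive definite: baseline_connectivity",
             " = %.3f with member loading %.3f gives a^2 + c^2 = %.3f >= 1"),
      baseline_connectivity, cmax, a2 + cmax^2))

  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_conversations = as.integer(n_conversations),
    n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    feature_effect_size = feature_effect_size,
    feature_loading = feature_loading,
    within_participant_sd = within_participant_sd,
    noise_sd = noise_sd,
    severity_link_strength = severity_link_strength,
    severity_range = as.integer(severity_range),
    n_nodes = as.integer(n_nodes), n_timepoints = as.integer(n_timepoints),
    baseline_connectivity = baseline_connectivity,
    member_loading = member_loading,
    group_connectivity_delta = group_connectivity_delta,
    compensation_slope = compensation_slope,
    compensation_node_set = compensation_node_set,
    partner_node_set = partner_node_set,
    extra_regions = extra_regions,
    age_range = age_range,
    motion_meanlog = motion_meanlog, motion_sdlog = motion_sdlog,
    motion_scan_jitter_sdlog = motion_scan_jitter_sdlog,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Node table: first half left hemisphere, second half right, unit-spaced
# 1-D coordinates so that radius-1 adjacency is a chain and contiguous
# region sets form spatial clusters.
.default_nodes <- function(n_nodes) {
  nl <- ceiling(n_nodes / 2)
  hemi <- rep(c("L", "R"), c(nl, n_nodes - nl))
  idx <- c(seq_len(nl), seq_len(n_nodes - nl))
  data.frame(node_id = sprintf("%s%02d", hemi, idx),
             hemisphere = hemi,
             x = as.numeric(seq_len(n_nodes)), y = 0, z = 0,
             stringsAsFactors = FALSE)
}

#' Simulate a two-group participant cohort
#'
#' Draws group, age, motion, and the latent language-typicality trait
#' theta for each participant: standard-normal, shifted by group (case
#' mean `-delta`, control mean `+delta`, with delta =
#' `feature_effect_size`).  Higher theta means more control-like behavior.
#'
#' @param config a `simulation_config`.
#' @return List with `participants` (data.frame `participant_id`, `group`,
#'   `age`, `motion`) and `ground_truth` (see details; consumed only by
#'   tests and calibration, never by pipeline stages).
#' @export
simulate_cohort <- function(config) {
  n <- config$n_case + config$n_control
  with_seed(substream_seed(config$seed, "cohort"), {
    participants <- data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      group = rep(c("autism", "typical"), c(config$n_case, config$n_control)),
      age = stats::runif(n, config$age_range[1], config$age_range[2]),
      motion = stats::rlnorm(n, config$motion_meanlog, config$motion_sdlog),
      stringsAsFactors = FALSE)
    delta <- config$feature_effect_size
    theta <- stats::rnorm(n) + ifelse(participants$group == "autism",
                                      -delta, delta)
    gt <- list(participant_id = participants$participant_id,
               group = participants$group,
               theta = theta,
               member_loading = .member_loadings(theta, participants$group,
                                                 config),
               informative_features = seq_len(config$n_informative),
               feature_loading = config$feature_loading,
               config = config)
    list(participants = participants, ground_truth = gt)
  })
}

# Per-participant loading on the compensation factor, clipped so that
# a^2 + c^2 stays strictly below 1.
.member_loadings <- function(theta, group, config) {
  a2 <- config$baseline_connectivity
  cmax <- sqrt(0.98 - a2)
  c_case <- config$member_loading + config$group_connectivity_delta +
    config$compensation_slope * theta
  c_all <- ifelse(group == "autism", c_case, config$member_loading)
  pmin(pmax(c_all, 0.02), cmax)
}

#' Simulate per-conversation linguistic features
#'
#' Informative feature j of participant i has conversation-level mean
#' `feature_loading * theta_i + u_ij`, where `u_ij` is a participant-level
#' random effect (SD `within_participant_sd`), plus i.i.d. conversation
#' noise (SD `noise_sd`).  Non-informative features are pure noise.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config a `simulation_config`.
#' @return A `feature_table` with one row per conversation.
#' @export
simulate_features <- function(cohort, config) {
  p <- cohort$participants
  gt <- cohort$ground_truth
  n <- nrow(p)
  nc <- config$n_conversations
  nf <- config$n_features
  ni <- config$n_informative
  with_seed(substream_seed(config$seed, "features"), {
    u <- matrix(stats::rnorm(n * nf, sd = config$within_participant_sd),
                n, nf)
    u[, setdiff(seq_len(nf), seq_len(ni))] <- 0
    mu <- matrix(0, n, nf)
    if (ni > 0)
      mu[, seq_len(ni)] <- config$feature_loading * gt$theta
    prow <- rep(seq_len(n), each = nc)
    M <- (mu + u)[prow, , drop = FALSE] +
      matrix(stats::rnorm(n * nc * nf, sd = config$noise_sd), n * nc, nf)
    colnames(M) <- sprintf("feature_%02d", seq_len(nf))
    df <- cbind(
      data.frame(conversation_id = sprintf("%s_conv%d",
                                           p$participant_id[prow],
                                           rep(seq_len(nc), n)),
                 participant_id = p$participant_id[prow],
                 group = p$group[prow],
                 stringsAsFactors = FALSE),
      as.data.frame(M))
    as_feature_table(df)
  })
}

#' Simulate case-group severity scores
#'
#' Case participants receive an ordinal severity score on
#' `severity_range` (default 7-14, an ADOS-2 Social Communication-like
#' scale whose minimum is the diagnostic floor), built by ranking a
#' latent `-(lambda * theta_z + sqrt(1 - lambda^2) * noise)` and mapping
#' ranks onto the integer range, so severity decreases with typicality
#' and `lambda = severity_link_strength` controls the rank-correlation
#' magnitude.  Control participants get no score.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config a `simulation_config`.
#' @return data.frame `participant_id`, `severity` (case group only).
#' @export
simulate_severity <- function(cohort, config) {
  p <- cohort$participants
  gt <- cohort$ground_truth
  case <- p$group == "autism"
  n <- sum(case)
  lam <- config$severity_link_strength
  with_seed(substream_seed(config$seed, "severity"), {
    th <- gt$theta[case]
    th_z <- if (stats::sd(th) > 0) (th - mean(th)) / stats::sd(th) else th * 0
    latent <- -(lam * th_z + sqrt(1 - lam^2) * stats::rnorm(n))
    lo <- config$severity_range[1]; hi <- config$severity_range[2]
    nlev <- hi - lo + 1L
    sev <- lo + floor((rank(latent, ties.method = "first") - 1) * nlev / n)
    data.frame(participant_id = p$participant_id[case],
               severity = as.integer(pmin(sev, hi)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate parcellated scan time series
#'
#' One scan per conversation.  Node signals follow the factor model
#' described in [simulation_config()]; residual variances are set so that
#' every node has unit marginal variance, which guarantees a valid joint
#' covariance.  The scan-level motion covariate is the participant's
#' motion value with log-normal scan jitter.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config a `simulation_config`.
#' @return List of `scan_timeseries`, one per conversation, with scan ids
#'   equal to the conversation ids used by [simulate_features()].
#' @export
simulate_timeseries <- function(cohort, config) {
  p <- cohort$participants
  gt <- cohort$ground_truth
  nodes <- .default_nodes(config$n_nodes)
  N <- config$n_nodes
  Tt <- config$n_timepoints
  a <- sqrt(config$baseline_connectivity)

  member <- nodes$node_id %in% c(config$compensation_node_set,
                                 config$partner_node_set)
  extra_idx <- lapply(config$extra_regions,
                      function(s) which(nodes$node_id %in% s))
  n_extra <- length(extra_idx)

  with_seed(substream_seed(config$seed, "timeseries"), {
    scans <- vector("list", nrow(p) * config$n_conversations)
    k <- 0L
    for (i in seq_len(nrow(p))) {
      c_i <- gt$member_loading[i]
      c_extra <- if (p$group[i] == "autism")
        config$member_loading + config$group_connectivity_delta
      else config$member_loading
      c_extra <- min(max(c_extra, 0.02), sqrt(0.98 - a^2))
      load <- matrix(0, N, 1L + 1L + n_extra)
      load[, 1L] <- a
      load[member, 2L] <- c_i
      if (n_extra > 0)
        for (r in seq_len(n_extra)) load[extra_idx[[r]], 2L + r] <- c_extra
      resid_sd <- sqrt(pmax(1 - rowSums(load^2), 1e-6))
      for (j in seq_len(config$n_conversations)) {
        k <- k + 1L
        Fmat <- matrix(stats::rnorm((2L + n_extra) * Tt), 2L + n_extra, Tt)
        E <- matrix(stats::rnorm(N * Tt), N, Tt) * resid_sd
        Y <- load %*% Fmat + E
        motion <- p$motion[i] *
          exp(stats::rnorm(1, sd = config$motion_scan_jitter_sdlog))
        scans[[k]] <- scan_timeseries(
          scan_id = sprintf("%s_conv%d", p$participant_id[i], j),
          participant_id = p$participant_id[i],
          mat = Y, nodes = nodes,
          age = p$age[i], motion = motion)
      }
    }
    scans
  })
}

#' Simulate a complete study
#'
#' Runs [simulate_cohort()], [simulate_features()], [simulate_severity()]
#' and [simulate_timeseries()] under one master seed.
#'
#' @param config a `simulation_config`.
#' @param timeseries set `FALSE` to skip scan generation (behavioral-only
#'   experiments).
#' @return List of class `simulated_study`: `participants`, `features`,
#'   `severity`, `scans`, `nodes`, `ground_truth`, `config`.
#' @export
simulate_study <- function(config = simulation_config(), timeseries = TRUE) {
  cohort <- simulate_cohort(config)
  structure(list(
    participants = cohort$participants,
    features = simulate_features(cohort, config),
    severity = simulate_severity(cohort, config),
    scans = if (timeseries) simulate_timeseries(cohort, config) else NULL,
    nodes = .default_nodes(config$n_nodes),
    ground_truth = cohort$ground_truth,
    config = config
  ), class = "simulated_study")
}

#' @exportS3Method base::print
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study: %d participants (%d case / %d control), %d conversations\n",
              nrow(x$participants), x$config$n_case, x$config$n_control,
              nrow(x$features)))
  if (!is.null(x$scans))
    cat(sprintf("  %d scans of %d nodes x %d timepoints\n",
                length(x$scans), x$config$n_nodes, x$config$n_timepoints))
  invisible(x)
}

#' Planted expected connectedness of compensation-region nodes
#'
#' Analytic oracle for parameter-recovery experiments: under the factor
#' model, the population correlation of two compensation/partner members
#' of participant i is `baseline + c_i^2` and every other pairing is
#' `baseline`, so a member node's expected connectedness is
#' `((m - 1) * (baseline + c_i^2) + (N - m) * baseline) / (N - 1)`.
#'
#' @param ground_truth the `ground_truth` element of a simulated study.
#' @return data.frame `participant_id`, `group`, `theta`, `loading`,
#'   `expected_connectedness`.
#' @export
planted_expected_connectedness <- function(ground_truth) {
  cfg <- ground_truth$config
  N <- cfg$n_nodes
  m <- length(cfg$compensation_node_set) + length(cfg$partner_node_set)
  a2 <- cfg$baseline_connectivity
  c2 <- ground_truth$member_loading^2
  ec <- ((m - 1) * (a2 + c2) + (N - m) * a2) / (N - 1)
  data.frame(participant_id = ground_truth$participant_id,
             group = ground_truth$group,
             theta = ground_truth$theta,
             loading = ground_truth$member_loading,
             expected_connectedness = ec,
             stringsAsFactors = FALSE)
}

#' Write a simulated study to a directory of plain-text files
#'
#' Writes `features.tsv`, `severity.tsv`, `covariates.tsv`, `nodes.tsv`,
#' `scans/<scan_id>.tsv`, `ground_truth.json` and a manifest.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return Invisible `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "scans"), showWarnings = FALSE, recursive = TRUE)
  write_feature_table(study$features, file.path(dir, "features.tsv"))
  .write_tsv(study$severity, file.path(dir, "severity.tsv"))
  .write_tsv(study$participants, file.path(dir, "covariates.tsv"))
  .write_tsv(study$nodes, file.path(dir, "nodes.tsv"))
  if (!is.null(study$scans)) {
    scan_meta <- data.frame(
      scan_id = vapply(study$scans, `[[`, character(1), "scan_id"),
      participant_id = vapply(study$scans, `[[`, character(1),
                              "participant_id"),
      age = vapply(study$scans, `[[`, numeric(1), "age"),
      motion = vapply(study$scans, `[[`, numeric(1), "motion"),
      stringsAsFactors = FALSE)
    .write_tsv(scan_meta, file.path(dir, "scan_covariates.tsv"))
    for (s in study$scans)
      write_scan_timeseries(s, file.path(dir, "scans",
                                         paste0(s$scan_id, ".tsv")))
  }
  gt <- study$ground_truth
  gt$config <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- run_config(seed = study$config$seed)
  write_manifest(dir, cfg, file.path(dir, "features.tsv"))
  invisible(dir)
}
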