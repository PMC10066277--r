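test_that("connectedness equals off-diagonal row means of the correlation matrix", {
  # 2 nodes: both values are the single pairwise correlation
  scan2 <- random_scan(2, 50, seed = 1)
  m2 <- compute_connectedness(scan2)
  r12 <- cor(scan2$mat[1, ], scan2$mat[2, ])
  expect_equal(m2$value, c(r12, r12), tolerance = 1e-12)

  # duplicated node + independent third node: brute-force oracle
  set.seed(2)
  base <- rnorm(80)
  mat <- rbind(base, base + 0, rnorm(80))
  scan3 <- scan_timeseries("s", "p", mat,
                           data.frame(node_id = c("a", "b", "c")))
  expect_equal(compute_connectedness(scan3)$value, unname(bf_connectedness(mat)),
               tolerance = 1e-12)

  # random scans against the brute-force oracle, raw-r and Fisher-z
  for (s in 1:5) {
    scan <- random_scan(sample(3:12, 1), sample(20:60, 1), seed = 100 + s)
    expect_equal(compute_connectedness(scan)$value,
                 unname(bf_connectedness(scan$mat)), tolerance = 1e-12)
    Rz <- fisher_z(cor(t(scan$mat)))
    diag(Rz) <- NA
    expect_equal(compute_connectedness(scan, fisher_z = TRUE)$value,
                 unname(rowMeans(Rz, na.rm = TRUE)), tolerance = 1e-12)
  }
})

test_that("connectedness is invariant to per-node affine rescaling", {
  scan <- random_scan(6, 40, seed = 9)
  scaled <- scan
  scaled$mat <- scan$mat * c(2, 0.5, 10, 1, 3, 7) + c(-1, 0, 5, 2, 0, -3)
  expect_equal(compute_connectedness(scaled)$value,
               compute_connectedness(scan)$value, tolerance = 1e-12)
})

test_that("constant nodes are excluded, short scans refused", {
  mat <- rbind(rnorm(30), rep(1, 30), rnorm(30))
  scan <- suppressMessages(scan_timeseries("s", "p", mat,
                           data.frame(node_id = c("a", "b", "c"))))
  m <- suppressMessages(compute_connectedness(scan))
  expect_true(is.na(m$value[2]))
  expect_equal(m$value[1], cor(mat[1, ], mat[3, ]), tolerance = 1e-12)
  short <- scan_timeseries("s", "p", matrix(rnorm(4), 2, 2),
                           data.frame(node_id = c("a", "b")))
  expect_error(compute_connectedness(short),
               class = "phenoconn_validation_error")
})

test_that("map sets refuse mixed scales and mismatched node panels", {
  st <- simulate_study(simulation_config(seed = 16, n_case = 2,
                                         n_control = 2,
                                         n_conversations = 1, n_nodes = 6,
                                         n_timepoints = 20))
  rost <- participant_roster(st$features)
  maps_r <- lapply(st$scans, compute_connectedness)
  maps_z <- lapply(st$scans, compute_connectedness, fisher_z = TRUE)
  expect_error(as_map_set(c(maps_r[1], maps_z[2]), rost),
               "mix", class = "phenoconn_validation_error")
  clipped <- maps_r
  clipped[[2]] <- clipped[[2]][-1, ]
  expect_error(as_map_set(clipped, rost),
               class = "phenoconn_validation_error")
})

test_that("group contrast collapses to the OLS closed forms in degenerate limits", {
  # one scan per participant: the mixed model is degenerate and the
  # estimates must equal plain OLS on group + age + motion
  set.seed(21)
  n <- 16
  vals <- matrix(rnorm(3 * n), 3, n)
  groups <- rep(c("aut", "td"), each = n / 2)
  age <- runif(n, 15, 30)
  motion <- runif(n, 0.05, 0.3)
  ms <- synthetic_map_set(vals, groups, age = age, motion = motion)
  ct <- fit_group_contrast(ms, "aut")
  for (k in 1:3) {
    fm <- lm(vals[k, ] ~ I(groups == "aut") + age + motion)
    co <- coef(summary(fm))[2, ]
    expect_equal(ct$estimate[k], unname(co[1]), tolerance = 1e-8)
    expect_equal(ct$t[k], unname(co[3]), tolerance = 1e-8)
    expect_equal(ct$df[k], unname(fm$df.residual))
  }
  expect_true(all(ct$fallback))

  # balanced groups, no covariates: estimate equals the difference of
  # group means of participant-mean connectedness
  ct0 <- fit_group_contrast(ms, "aut", engine = "ols", covariates = FALSE)
  dm <- rowMeans(vals[, groups == "aut"]) - rowMeans(vals[, groups == "td"])
  expect_equal(ct0$estimate, unname(dm), tolerance = 1e-8)
})

test_that("mixed-model contrast recovers a planted group shift across scans", {
  set.seed(22)
  n_part <- 20
  groups <- rep(c("aut", "td"), each = n_part / 2)
  delta <- 0.5
  part_eff <- rnorm(n_part, sd = 0.3)
  vals <- sapply(rep(seq_len(n_part), each = 3), function(i)
    c(part_eff[i] + delta * (groups[i] == "aut"), part_eff[i]) + rnorm(2, sd = 0.2))
  ms <- synthetic_map_set(vals, groups[rep(seq_len(n_part), each = 3)],
                          participant = rep(paste0("p", 1:n_part), each = 3))
  ct <- fit_group_contrast(ms, "aut", covariates = FALSE)
  # planted effect within 3 simulation SEs (participant noise 0.3, n=10/group)
  expect_lt(abs(ct$estimate[1] - delta), 0.45)
  expect_lt(abs(ct$estimate[2]), 0.45)
  expect_lt(ct$p[1], 0.05)
  # Satterthwaite df for a between-participant effect stays near the
  # participant-level residual df, far below the scan count
  expect_lt(ct$df[1], n_part + 5)
})

test_that("cluster finding matches an independent graph-components oracle", {
  nodes <- data.frame(node_id = paste0("n", 1:5), x = 1:5, y = 0, z = 0)
  chain <- node_adjacency(nodes, radius = 1)
  cl <- find_clusters(c(TRUE, TRUE, FALSE, TRUE, TRUE), chain)
  expect_equal(length(cl), 2L)
  expect_equal(sort(vapply(cl, length, integer(1))), c(2L, 2L))
  expect_equal(find_clusters(rep(FALSE, 5), chain), list())

  skip_if_not_installed("igraph")
  set.seed(30)
  for (rep in 1:5) {
    nn <- 25
    nd <- data.frame(node_id = sprintf("n%02d", 1:nn))
    edges <- data.frame(node_a = sample(nd$node_id, 40, TRUE),
                        node_b = sample(nd$node_id, 40, TRUE))
    edges <- edges[edges$node_a != edges$node_b, ]
    adj <- node_adjacency(nd, edges = edges)
    sig <- runif(nn) < 0.5
    cl <- find_clusters(sig, adj)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nd$node_id)
    sub <- igraph::induced_subgraph(g, nd$node_id[sig])
    comp <- igraph::components(sub)
    sizes_oracle <- sort(as.integer(comp$csize), decreasing = TRUE)
    expect_equal(vapply(cl, length, integer(1)), sizes_oracle)
    members_oracle <- lapply(split(names(comp$membership), comp$membership),
                             sort)
    expect_setequal(lapply(cl, sort), unname(members_oracle))
  }
})

test_that("extent calibration honors its degenerate limits and the null oracle", {
  set.seed(33)
  nn <- 20
  vals <- matrix(rnorm(nn * 30), nn, 30)
  groups <- rep(c("aut", "td"), each = 15)
  ms <- synthetic_map_set(vals, groups)
  nodes <- data.frame(node_id = rownames(ms$values), x = 1:nn, y = 0, z = 0)

  # no adjacency: every node is its own cluster, k = 1 everywhere
  iso <- node_adjacency(nodes)
  ext_iso <- calibrate_cluster_extent(ms, "aut", iso, n_iter = 200, seed = 2)
  expect_true(all(ext_iso$k == 1L))

  # fully connected adjacency at threshold 1: k equals the node count
  full_edges <- subset(expand.grid(node_a = nodes$node_id,
                                   node_b = nodes$node_id),
                       node_a != node_b)
  full <- node_adjacency(nodes, edges = full_edges)
  ext_full <- calibrate_cluster_extent(ms, "aut", full, thresholds = 1,
                                       n_iter = 200, seed = 2)
  expect_equal(ext_full$k, nn)

  # chain graph at alpha = 0.05: matches a 10x-oversampled oracle within 1
  chain <- node_adjacency(nodes, radius = 1)
  ext <- calibrate_cluster_extent(ms, "aut", chain, thresholds = 0.05,
                                  n_iter = 400, seed = 7)
  ext_big <- calibrate_cluster_extent(ms, "aut", chain, thresholds = 0.05,
                                      n_iter = 4000, seed = 8)
  expect_lte(abs(ext$k - ext_big$k), 1L)

  # k is non-increasing along the descending threshold ladder
  ext_lad <- calibrate_cluster_extent(ms, "aut", chain,
                                      thresholds = c(0.2, 0.05, 0.01),
                                      n_iter = 300, seed = 3)
  expect_true(all(diff(ext_lad$k) <= 0))
  expect_error(calibrate_cluster_extent(ms, "aut", chain, n_iter = 50),
               class = "phenoconn_validation_error")
})

test_that("robustness map indexes the most stringent surviving threshold", {
  nodes <- data.frame(node_id = sprintf("n%02d", 1:12), x = 1:12, y = 0, z = 0)
  adj <- node_adjacency(nodes, radius = 1)
  thresholds <- c(0.05, 0.01, 0.001)
  # hand-built contrast: nodes 1-4 extremely significant, node 6
  # marginal, rest null; node 9 significant but isolated below extent
  p_one <- c(1e-6, 1e-6, 1e-6, 1e-6, 0.5, 0.005, 0.9, 0.9, 0.02, 0.9,
             0.9, 0.9)
  contrast <- data.frame(node_id = nodes$node_id,
                         estimate = 1, t = 5, df = 30, p = p_one,
                         p_one = p_one, fallback = FALSE)
  class(contrast) <- c("group_contrast", "data.frame")
  extents <- data.frame(threshold = thresholds, k = c(2L, 2L, 2L))
  rob <- build_robustness_map(contrast, extents, adj)
  expect_equal(rob$max_threshold_index[1:4], rep(3L, 4))  # full ladder
  expect_equal(rob$max_threshold_index[6], 0L)            # cluster too small
  expect_equal(rob$max_threshold_index[9], 0L)            # isolated
  # binarized maps are nested: surviving at level i+1 implies level i
  for (i in 2:3) {
    hi <- rob$max_threshold_index >= i
    lo <- rob$max_threshold_index >= i - 1
    expect_true(all(!hi | lo))
  }

  rois <- select_rois(rob, adj, min_size = 4)
  expect_equal(length(rois), 1L)
  expect_equal(rois$ROI1$nodes, nodes$node_id[1:4])
  # min_size 1 returns every surviving cluster; nothing surviving -> empty
  expect_equal(length(select_rois(rob, adj, min_size = 1)), 1L)
  rob0 <- rob
  rob0$max_threshold_index <- 0L
  expect_equal(length(select_rois(rob0, adj, min_size = 1)), 0L)
})
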