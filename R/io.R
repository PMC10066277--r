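# Readers/writers.  Canonical table format: UTF-8, tab-delimited, header
# row, reals printed at full precision (17 significant digits) so that
# read -> write -> read round-trips are lossless to within 1e-9.

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.read_delim <- function(path) {
  if (!file.exists(path)) err_format(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
}

#' Read a per-conversation linguistic feature table
#'
#' Expects delimited text (tab or comma) with a header row and columns
#' `conversation_id`, `participant_id`, `group`, followed by one or more
#' numeric feature columns (e.g. the 81 word-category variables produced
#' by a dictionary-based text analysis of each conversation transcript).
#'
#' @param path file path.
#' @return A `feature_table`: a data.frame with the three id columns and
#'   numeric feature columns; feature names are available through
#'   [feature_names()].
#' @export
read_feature_table <- function(path) {
  raw <- .read_delim(path)
  req <- c("conversation_id", "participant_id", "group")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    err_format(sprintf("feature table %s is missing required column(s): %s",
                       path, paste(miss, collapse = ", ")))
  feat <- setdiff(names(raw), req)
  if (length(feat) < 1L)
    err_format(sprintf("feature table %s has no feature columns", path))
  for (fc in feat) {
    v <- suppressWarnings(as.numeric(raw[[fc]]))
    bad <- which(is.na(v) & !(raw[[fc]] %in% c("NA", "")))
    if (length(bad))
      err_parse(sprintf(
        "non-numeric value '%s' in feature column '%s', row %d of %s",
        raw[[fc]][bad[1]], fc, bad[1], path))
    raw[[fc]] <- v
  }
  tab <- as_feature_table(raw)
  pc_log(sprintf("read %d conversations x %d features from %s",
                 nrow(tab), length(feat), path))
  tab
}

#' Construct a feature table from a data.frame
#'
#' @param df data.frame with columns `conversation_id`, `participant_id`,
#'   `group` and numeric feature columns.
#' @return A validated `feature_table`.
#' @export
as_feature_table <- function(df) {
  req <- c("conversation_id", "participant_id", "group")
  if (!all(req %in% names(df)))
    err_format("feature table needs conversation_id, participant_id, group")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$conversation_id <- as.character(df$conversation_id)
  df$participant_id <- as.character(df$participant_id)
  df$group <- as.character(df$group)
  if (length(unique(df$group)) != 2L)
    err_validation(sprintf("feature table must contain exactly 2 groups, found %d",
                           length(unique(df$group))))
  pg <- unique(df[, c("participant_id", "group")])
  dup <- pg$participant_id[duplicated(pg$participant_id)]
  if (length(dup))
    err_validation(sprintf("participant(s) mapped to more than one group: %s",
                           paste(unique(dup), collapse = ", ")))
  df <- df[, c(req, setdiff(names(df), req))]
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Feature column names of a feature table
#' @param table a `feature_table`.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("conversation_id", "participant_id", "group"))
}

#' Numeric feature matrix of a feature table
#' @param table a `feature_table`.
#' @return Matrix (conversations x features) with conversation ids as rownames.
#' @export
feature_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table)[, feature_names(table), drop = FALSE])
  rownames(m) <- table$conversation_id
  m
}

#' Write a feature table as lossless TSV
#' @param table a `feature_table`.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) .write_tsv(table, path)

#' Participant roster of a feature table
#' @param table a `feature_table`.
#' @return data.frame with one row per participant: `participant_id`, `group`.
#' @export
participant_roster <- function(table) {
  r <- unique(as.data.frame(table)[, c("participant_id", "group")])
  rownames(r) <- NULL
  r
}

#' Remove excluded conversations from a dataset
#'
#' Conversations whose recordings are unusable are removed from the
#' behavioral table and, with the same id list, from the corresponding
#' scan collection ("along with their brain data").  Unknown ids warn but
#' do not fail.
#'
#' @param x a `feature_table`, or a list of `scan_timeseries` whose
#'   `scan_id`s are conversation ids.
#' @param excluded_ids character vector of conversation ids to drop.
#' @return Object of the same type with the listed conversations removed.
#' @export
#' @examples
#' tab <- as_feature_table(data.frame(
#'   conversation_id = c("c1", "c2", "c3"),
#'   participant_id = c("p1", "p1", "p2"),
#'   group = c("aut", "aut", "td"), f1 = 1:3))
#' nrow(apply_exclusions(tab, "c2"))
apply_exclusions <- function(x, excluded_ids) {
  UseMethod("apply_exclusions")
}

.check_exclusion_ids <- function(present, excluded_ids, what) {
  unknown <- setdiff(excluded_ids, present)
  if (length(unknown))
    warning(sprintf("exclusion id(s) not present in %s: %s",
                    what, paste(unknown, collapse = ", ")), call. = FALSE)
}

#' @export
apply_exclusions.feature_table <- function(x, excluded_ids) {
  excluded_ids <- as.character(excluded_ids)
  .check_exclusion_ids(x$conversation_id, excluded_ids, "feature table")
  keep <- !(x$conversation_id %in% excluded_ids)
  out <- x[keep, , drop = FALSE]
  if (length(unique(out$group)) < 2L)
    err_validation("exclusions removed all conversations of a group")
  pc_log(sprintf("excluded %d conversation(s); %d remain",
                 sum(!keep), sum(keep)))
  rownames(out) <- NULL
  out
}

#' @export
apply_exclusions.list <- function(x, excluded_ids) {
  excluded_ids <- as.character(excluded_ids)
  ids <- vapply(x, function(s) s$scan_id, character(1))
  .check_exclusion_ids(ids, excluded_ids, "scan collection")
  keep <- !(ids %in% excluded_ids)
  pc_log(sprintf("excluded %d scan(s); %d remain", sum(!keep), sum(keep)))
  x[keep]
}

#' Construct a parcellated scan time-series object
#'
#' @param scan_id scan (conversation) id.
#' @param participant_id participant id.
#' @param mat numeric matrix, nodes x timepoints.
#' @param nodes data.frame of node metadata: `node_id`, `hemisphere`
#'   (`"L"`/`"R"`, may be `NA`), optional `x`, `y`, `z` coordinates.
#' @param age participant age in years.
#' @param motion scan-level motion summary (positive scalar).
#' @return A `scan_timeseries` object.
#' @export
scan_timeseries <- function(scan_id, participant_id, mat, nodes,
                            age = NA_real_, motion = NA_real_) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) err_validation("scan needs at least 2 nodes")
  if (ncol(mat) < 2L) err_validation("scan needs at least 2 timepoints")
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"node_id" %in% names(nodes))
    err_format("node metadata needs a node_id column")
  if (nrow(nodes) != nrow(mat))
    err_format(sprintf(
      "node metadata has %d rows but the matrix has %d nodes",
      nrow(nodes), nrow(mat)))
  nodes$node_id <- as.character(nodes$node_id)
  if (!"hemisphere" %in% names(nodes)) nodes$hemisphere <- NA_character_
  rownames(mat) <- nodes$node_id
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0))
    pc_log(sprintf("scan %s: %d constant node(s) flagged: %s", scan_id,
                   sum(sds == 0),
                   paste(nodes$node_id[sds == 0], collapse = ", ")))
  structure(list(scan_id = as.character(scan_id),
                 participant_id = as.character(participant_id),
                 mat = mat, nodes = nodes,
                 age = as.numeric(age), motion = as.numeric(motion)),
            class = "scan_timeseries")
}

#' @exportS3Method base::print
print.scan_timeseries <- function(x, ...) {
  cat(sprintf("scan_timeseries %s (participant %s): %d nodes x %d timepoints\n",
              x$scan_id, x$participant_id, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Read one parcellated scan from matrix + metadata files
#'
#' The matrix file is delimited text, nodes x timepoints, with a header
#' row of timepoint labels and a leading `node_id` column.  The metadata
#' file has columns `node_id`, `hemisphere`, optional `x`,`y`,`z`, and the
#' reader checks that both agree on the node count and order.
#'
#' @param path matrix file.
#' @param metadata_path node metadata file.
#' @param scan_id,participant_id,age,motion scan annotations (default:
#'   scan_id from the file name).
#' @return A `scan_timeseries`.
#' @export
read_scan_timeseries <- function(path, metadata_path,
                                 scan_id = sub("\\.[^.]*$", "", basename(path)),
                                 participant_id = NA_character_,
                                 age = NA_real_, motion = NA_real_) {
  raw <- .read_delim(path)
  if (!"node_id" %in% names(raw))
    err_format(sprintf("matrix file %s needs a leading node_id column", path))
  ids <- raw$node_id
  mat <- as.matrix(raw[, setdiff(names(raw), "node_id"), drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat))
    err_parse(sprintf("non-numeric value in matrix file %s", path))
  meta <- .read_delim(metadata_path)
  if (!"node_id" %in% names(meta))
    err_format(sprintf("metadata file %s needs a node_id column", metadata_path))
  if (nrow(meta) != nrow(mat))
    err_format(sprintf(
      "metadata %s has %d rows but matrix %s has %d nodes",
      metadata_path, nrow(meta), path, nrow(mat)))
  if (!identical(as.character(meta$node_id), as.character(ids)))
    err_format("node_id order differs between matrix and metadata files")
  for (cc in intersect(c("x", "y", "z"), names(meta)))
    meta[[cc]] <- as.numeric(meta[[cc]])
  if (ncol(mat) < 2L)
    err_validation(sprintf("scan %s has fewer than 2 timepoints", scan_id))
  scan_timeseries(scan_id, participant_id, mat, meta,
                  age = age, motion = motion)
}

#' Write a scan time-series matrix (and optionally metadata) as TSV
#' @param scan a `scan_timeseries`.
#' @param path matrix output path.
#' @param metadata_path optional node metadata output path.
#' @export
write_scan_timeseries <- function(scan, path, metadata_path = NULL) {
  df <- data.frame(node_id = scan$nodes$node_id, stringsAsFactors = FALSE)
  m <- as.data.frame(scan$mat)
  names(m) <- sprintf("t%03d", seq_len(ncol(scan$mat)))
  .write_tsv(cbind(df, m), path)
  if (!is.null(metadata_path)) .write_tsv(scan$nodes, metadata_path)
  invisible(path)
}

#' Write a per-node map as TSV or NIfTI
#'
#' The canonical representation of every map (connectedness, contrast,
#' robustness) is a node table; NIfTI export is available when node
#' coordinates lie on a regular grid.
#'
#' @param map data.frame with `node_id` plus value column(s), e.g. the
#'   output of [compute_connectedness()] or [fit_group_contrast()].
#' @param path output path.
#' @param format `"tsv"` or `"nifti"`.
#' @param nodes node metadata with `x`,`y`,`z` (required for NIfTI).
#' @param value column written into the NIfTI volume.
#' @export
write_map <- function(map, path, format = c("tsv", "nifti"),
                      nodes = NULL, value = "value") {
  format <- match.arg(format)
  map <- as.data.frame(map)
  if (format == "tsv") return(.write_tsv(map, path))
  if (is.null(nodes) || !all(c("x", "y", "z") %in% names(nodes)))
    err_capability("NIfTI export requires node coordinates (x, y, z)")
  if (!requireNamespace("RNifti", quietly = TRUE))
    err_capability("NIfTI export requires the 'RNifti' package")
  nodes <- nodes[match(map$node_id, nodes$node_id), ]
  if (anyNA(nodes$node_id))
    err_validation("map contains node_id(s) absent from node metadata")
  axes <- lapply(c("x", "y", "z"), function(a) sort(unique(nodes[[a]])))
  step <- vapply(axes, function(u) if (length(u) > 1) min(diff(u)) else 1,
                 numeric(1))
  dims <- vapply(seq_along(axes), function(i) {
    rng <- range(axes[[i]])
    as.integer(round((rng[2] - rng[1]) / step[i])) + 1L
  }, integer(1))
  idx <- vapply(seq_along(axes), function(i) {
    u <- nodes[[c("x", "y", "z")[i]]]
    as.integer(round((u - min(axes[[i]])) / step[i])) + 1L
  }, integer(nrow(nodes)))
  arr <- array(0, dim = dims)
  arr[cbind(idx[, 1], idx[, 2], idx[, 3])] <- map[[value]]
  img <- RNifti::asNifti(arr, pixdim = step)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a node map written by [write_map()] (TSV format)
#' @param path file path.
#' @return data.frame with numeric value columns.
#' @export
read_map <- function(path) {
  raw <- .read_delim(path)
  if (!"node_id" %in% names(raw))
    err_format(sprintf("map file %s needs a node_id column", path))
  for (cc in setdiff(names(raw), c("node_id", "hemisphere")))
    raw[[cc]] <- as.numeric(raw[[cc]])
  raw
}

#' Write a run manifest
#'
#' Every pipeline run records its configuration, master seed, input file
#' hashes and package version so that results can be reproduced
#' bit-identically.
#'
#' @param dir output directory.
#' @param config a `phenoconn_config`.
#' @param inputs character vector of input file paths to hash.
#' @return Invisible path of the manifest file.
#' @export
write_manifest <- function(dir, config, inputs = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  man <- list(
    package = "phenoconn",
    version = as.character(utils::packageVersion("phenoconn")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "paths")],
    input_md5 = hashes
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
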