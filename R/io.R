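## Tab-separated interchange formats. Matrices are serialized with 6
## significant digits and validated on read (symmetry to 1e-9, range checks
## by matrix kind); all writer/reader pairs round-trip losslessly at that
## precision.

fmt_num <- function(x) {
  out <- vapply(signif(x, 6L), function(v) format(v, scientific = FALSE,
                                                  trim = TRUE, digits = 15),
                "")
  out
}

read_tsv <- function(path, required, what) {
  if (!file.exists(path)) stop_mfc(what, " file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_mfc(what, " file ", path, " is missing columns: ",
             paste(miss, collapse = ", "), class = "mfc_parse_error")
  df
}

#' Read voxel-level gray-matter samples
#'
#' Reads a long-format TSV with columns `subject_id`, `region_index`
#' (1-based) and `value`, and returns one [voxel_samples()] object per
#' subject with regions ordered by index.
#'
#' @param path Path to the TSV file.
#' @return Named list of `voxel_samples` objects.
#' @export
read_voxel_samples <- function(path) {
  df <- read_tsv(path, c("subject_id", "region_index", "value"), "voxel sample")
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))[1]
    stop_mfc("non-numeric value near line ", bad + 1L, " of ", path,
             class = "mfc_parse_error")
  }
  if (anyNA(df$value)) {
    stop_mfc("missing value near line ", which(is.na(df$value))[1] + 1L,
             " of ", path, class = "mfc_parse_error")
  }
  ri <- df$region_index
  if (anyNA(ri) || any(ri != as.integer(ri)) || any(ri < 1))
    stop_mfc("region_index must be a 1-based integer (offending line ",
             which(is.na(ri) | ri != as.integer(ri) | ri < 1)[1] + 1L, ")",
             class = "mfc_parse_error")
  n_regions <- max(ri)
  labs <- region_labels(n_regions)
  out <- lapply(split(df, df$subject_id), function(d) {
    got <- sort(unique(d$region_index))
    if (!identical(got, seq_len(n_regions)))
      stop_mfc("subject ", d$subject_id[1], " is missing regions: ",
               paste(setdiff(seq_len(n_regions), got), collapse = ", "),
               class = "mfc_parse_error")
    samp <- split(d$value, d$region_index)
    names(samp) <- labs[as.integer(names(samp))]
    voxel_samples(d$subject_id[1], samp[labs])
  })
  out[unique(df$subject_id)]
}

#' Write voxel-level gray-matter samples
#'
#' Inverse of [read_voxel_samples()].
#'
#' @param subjects List of [voxel_samples()] objects (or a single one).
#' @param path Output TSV path.
#' @export
write_voxel_samples <- function(subjects, path) {
  if (inherits(subjects, "voxel_samples")) subjects <- list(subjects)
  rows <- lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               region_index = rep(seq_along(s$samples), lengths(s$samples)),
               value = unlist(s$samples, use.names = FALSE))
  })
  df <- do.call(rbind, rows)
  df$value <- fmt_num(df$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled similarity / connectivity matrix
#'
#' Reads a square labeled TSV matrix and validates it by kind: symmetric to
#' `1e-9`, unit diagonal, entries in `(0, 1]` for a morphological similarity
#' network (`kind = "msn"`) or `[-1, 1]` for a functional network
#' (`kind = "fcn"`).
#'
#' @param path Path to the TSV file.
#' @param kind `"msn"`, `"fcn"`, or `"any"` (no range check).
#' @return Numeric matrix with region dimnames.
#' @export
read_matrix <- function(path, kind = c("msn", "fcn", "any")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labs <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stop_mfc("matrix in ", path, " is not square",
                                   class = "mfc_parse_error")
  if (!identical(labs, colnames(m)))
    stop_mfc("row and column labels disagree in ", path, class = "mfc_parse_error")
  rownames(m) <- labs
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_mfc("non-numeric entries in ", path, class = "mfc_parse_error")
  check_symmetric(m, tol = 1e-9, what = paste0("matrix in ", path))
  if (max(abs(diag(m) - 1)) > 1e-9)
    stop_mfc("matrix in ", path, " must have unit diagonal")
  if (kind == "msn" && (any(m <= 0) || any(m > 1 + 1e-12)))
    stop_mfc("similarity entries outside (0, 1] in ", path,
             class = "mfc_range_error")
  if (kind == "fcn" && any(abs(m) > 1 + 1e-12))
    stop_mfc("correlation entries outside [-1, 1] in ", path,
             class = "mfc_range_error")
  m
}

#' Write a labeled matrix as TSV
#'
#' Inverse of [read_matrix()]; values are serialized with 6 significant
#' digits.
#'
#' @param m Labeled square numeric matrix.
#' @param path Output TSV path.
#' @export
write_matrix <- function(m, path) {
  check_square_labeled(m, "matrix")
  labs <- rownames(m) %||% region_labels(nrow(m))
  lines <- c(paste(c("region", labs), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(labs[i], fmt_num(m[i, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-subject regional time-series matrix
#'
#' @param path TSV with T rows and R labeled columns.
#' @return Numeric T x R matrix.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_mfc("missing or non-numeric entries in ", path,
                         class = "mfc_parse_error")
  m
}

#' Write a regional time-series matrix
#' @param ts Numeric T x R matrix with region column names.
#' @param path Output TSV path.
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(apply(ts, 2L, fmt_num), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort covariate table
#' @param path TSV with columns subject_id, group, site, age, sex, education,
#'   mean_fd, symptom_score.
#' @return Data frame.
#' @export
read_cohort_table <- function(path) {
  df <- read_tsv(path, c("subject_id", "group", "site"), "cohort")
  if ("symptom_score" %in% names(df)) {
    s <- df$symptom_score[!is.na(df$symptom_score)]
    if (length(s) && (any(s < 0) || any(s > 52)))
      stop_mfc("symptom_score outside [0, 52] in ", path,
               class = "mfc_range_error")
  }
  df
}

#' Read a region-to-network partition table
#' @param path TSV with columns region_index, network.
#' @return Data frame.
#' @export
read_partition <- function(path) {
  read_tsv(path, c("region_index", "network"), "partition")
}

#' Read region centroid coordinates
#' @param path TSV with columns region_index, hemisphere, x, y, z.
#' @return Data frame.
#' @export
read_centroids <- function(path) {
  read_tsv(path, c("region_index", "hemisphere", "x", "y", "z"), "centroid")
}

#' Write the input files of a synthetic cohort
#'
#' Serializes a [simulate_cohort()] result to the tabular interchange
#' formats: voxel samples, per-subject time series, the cohort table, the
#' partition and centroid tables, and the ground-truth similarity matrix and
#' fidelity vector.
#'
#' @param cohort An `mfc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_inputs <- function(cohort, dir) {
  if (!inherits(cohort, "mfc_cohort")) stop_mfc("cohort must be an mfc_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  write_voxel_samples(cohort$voxels, file.path(dir, "voxel_samples.tsv"))
  for (sid in names(cohort$timeseries))
    write_timeseries(cohort$timeseries[[sid]], file.path(ts_dir, paste0(sid, ".tsv")))
  cdf <- cohort$cohort
  for (cc in c("age", "education", "mean_fd")) cdf[[cc]] <- fmt_num(cdf[[cc]])
  utils::write.table(cdf, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$partition, file.path(dir, "partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cent <- cohort$centroids
  for (cc in c("x", "y", "z")) cent[[cc]] <- fmt_num(cent[[cc]])
  utils::write.table(cent, file.path(dir, "centroids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(cohort$s_true, file.path(dir, "s_true.tsv"))
  utils::write.table(
    data.frame(region = region_labels(length(cohort$gamma)),
               gamma = fmt_num(cohort$gamma)),
    file.path(dir, "gamma.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
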