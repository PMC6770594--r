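# Readers and writers for the standard expression formats. Dense CSV/TSV
# dialect is fixed (not sniffed): header row of sample ids, first column of
# gene ids, UTF-8, '.' decimal separator. MatrixMarket uses the common
# triplet convention (matrix.mtx + features.tsv + barcodes.tsv in one
# directory). GCT version #1.2; the Description column is preserved but
# unused.

#' Read an expression matrix
#'
#' @param path For `dense_csv`/`dense_tsv`/`gct`: the file. For `mtx`: the
#'   directory holding `matrix.mtx`, `features.tsv` and `barcodes.tsv`.
#' @param format `"auto"` (by extension; a directory means `mtx`) or one of
#'   `"dense_csv"`, `"dense_tsv"`, `"mtx"`, `"gct"`.
#' @param value_kind What the values are; `"raw_count"`, `"normalized"` or
#'   `"tpm"` (GCT defaults to TPM, the others to raw counts).
#' @return An [expression_matrix()] (genes x samples).
#' @export
read_expression_matrix <- function(path,
                                   format = c("auto", "dense_csv", "dense_tsv",
                                              "mtx", "gct"),
                                   value_kind = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
    else switch(tolower(tools::file_ext(path)),
                csv = "dense_csv", tsv = "dense_tsv", txt = "dense_tsv",
                gct = "gct",
                stop2("cannot infer format from '%s'; pass format=", path))
  }
  if (format != "mtx" && !file.exists(path)) stop2("file not found: %s", path)
  out <- switch(format,
    dense_csv = read_dense(path, sep = ","),
    dense_tsv = read_dense(path, sep = "\t"),
    mtx = read_mtx_triplet(path),
    gct = read_gct(path))
  value_kind <- value_kind %||% if (format == "gct") "tpm" else "raw_count"
  expression_matrix(out, value_kind = value_kind)
}

read_dense <- function(path, sep) {
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop2("failed to parse %s: %s", path,
                              conditionMessage(e)))
  if (ncol(df) < 2L)
    stop2("%s: need a gene-id column plus at least one sample column", path)
  gene_ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  non_numeric <- !vapply(vals, is.numeric, logical(1))
  if (any(non_numeric)) {
    bad_rows <- which(!grepl("^[0-9eE+.\\-]*$",
                             as.character(vals[[which(non_numeric)[1]]])))
    stop2("%s: non-numeric expression values (e.g. near data line %d)",
          path, if (length(bad_rows)) bad_rows[1] else 1L)
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  m
}

read_mtx_triplet <- function(dir_path) {
  paths <- file.path(dir_path, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop2("MatrixMarket triplet incomplete; missing: %s",
          paste(basename(missing_files), collapse = ", "))
  m <- as.matrix(Matrix::readMM(paths[1]))
  features <- read.delim(paths[2], header = FALSE, stringsAsFactors = FALSE)
  barcodes <- read.delim(paths[3], header = FALSE, stringsAsFactors = FALSE)
  if (nrow(features) != nrow(m))
    stop2("features.tsv has %d rows but the matrix has %d", nrow(features),
          nrow(m))
  if (nrow(barcodes) != ncol(m))
    stop2("barcodes.tsv has %d rows but the matrix has %d columns",
          nrow(barcodes), ncol(m))
  dimnames(m) <- list(features[[1L]], barcodes[[1L]])
  m
}

read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || !startsWith(header[1], "#1.2"))
    stop2("%s: not a GCT 1.2 file (line 1 must start with '#1.2')", path)
  dims <- suppressWarnings(as.integer(strsplit(header[2], "\t")[[1]][1:2]))
  if (any(is.na(dims)))
    stop2("%s: line 2 must carry '<n_genes>\\t<n_samples>'", path)
  df <- read.delim(path, skip = 2L, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) != dims[2] + 2L)
    stop2("%s: header declares %d samples but found %d data columns", path,
          dims[2], ncol(df) - 2L)
  if (nrow(df) != dims[1])
    stop2("%s: header declares %d genes but found %d rows", path, dims[1],
          nrow(df))
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  attr(m, "description") <- setNames(as.character(df[[2L]]),
                                     as.character(df[[1L]]))
  m
}

#' Write an expression matrix
#'
#' Writers produce exactly the layouts [read_expression_matrix()] accepts, so
#' matrices round-trip across formats.
#'
#' @param m Expression matrix (genes x samples).
#' @param path File path (or directory path for `mtx`).
#' @param format `"dense_csv"`, `"dense_tsv"`, `"mtx"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path,
                                    format = c("dense_csv", "dense_tsv",
                                               "mtx", "gct")) {
  format <- match.arg(format)
  mm <- unclass(m)
  attr(mm, "value_kind") <- NULL
  switch(format,
    dense_csv = write_dense(mm, path, ","),
    dense_tsv = write_dense(mm, path, "\t"),
    mtx = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      Matrix::writeMM(Matrix::Matrix(mm, sparse = TRUE),
                      file.path(path, "matrix.mtx"))
      writeLines(rownames(mm), file.path(path, "features.tsv"))
      writeLines(colnames(mm), file.path(path, "barcodes.tsv"))
    },
    gct = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("#1.2", paste(nrow(mm), ncol(mm), sep = "\t")), con)
      df <- data.frame(Name = rownames(mm), Description = rownames(mm),
                       mm, check.names = FALSE, stringsAsFactors = FALSE)
      colnames(df) <- c("Name", "Description", colnames(mm))
      write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                  con, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  invisible(path)
}

write_dense <- function(mm, path, sep) {
  df <- data.frame(gene_id = rownames(mm), mm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mm))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group label table
#'
#' Two-column TSV `sample_id<TAB>group` with a header line; duplicate sample
#' ids are rejected.
#'
#' @param path File path.
#' @return Named factor of group labels keyed by sample id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop2("%s: expected 2 columns (sample_id, group)", path)
  if (anyDuplicated(df[[1L]]))
    stop2("%s: duplicate sample id(s): %s", path,
          paste(head(unique(df[[1L]][duplicated(df[[1L]])]), 5L),
                collapse = ", "))
  as_group_labels(setNames(as.character(df[[2L]]), as.character(df[[1L]])))
}

#' Check that labels and matrix describe the same samples
#'
#' Errors with an explicit diff when any matrix sample lacks a label or any
#' labeled sample is absent from the matrix.
#'
#' @param labels Named group labels.
#' @param m Expression matrix (samples as columns).
#' @return The labels, reordered to the matrix columns, invisibly.
#' @export
validate_labels <- function(labels, m) {
  extra <- setdiff(names(labels), colnames(m))
  if (length(extra))
    stop2("labeled sample(s) absent from the matrix: %s",
          paste(head(extra, 5L), collapse = ", "))
  invisible(as_group_labels(labels, colnames(m)))
}

#' Write a sample-to-group label table
#'
#' @param labels Named group labels.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample_id = names(labels), group = as.character(labels),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene panel as annotated TSV
#'
#' Two columns (`gene_id`, `sign` — blank except for DE panels) preceded by a
#' `# mode=, group=, k=` comment line.
#'
#' @param panel A [gene_panel()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gene_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s, group=%s, k=%d", panel$mode, panel$group,
                     panel$k_requested), con)
  signs <- if (is.null(panel$signs)) rep("", length(panel$genes))
           else as.character(panel$signs)
  writeLines("gene_id\tsign", con)
  writeLines(paste(panel$genes, signs, sep = "\t"), con)
  invisible(path)
}

#' Read a gene panel written by [write_gene_panel()]
#'
#' @param path File path.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  first <- readLines(path, n = 1L)
  meta <- regmatches(first,
                     regexec("# mode=([^,]+), group=([^,]+), k=([0-9]+)",
                             first))[[1]]
  if (length(meta) != 4L)
    stop2("%s: missing '# mode=, group=, k=' header line", path)
  df <- read.delim(path, skip = 1L, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character"))
  signs <- if (meta[2] == "de") as.integer(df$sign) else NULL
  gene_panel(df$gene_id, group = meta[3], mode = meta[2], signs = signs,
             k_requested = as.integer(meta[4]))
}

#' Write / read a score matrix as CSV
#'
#' Samples as rows (first column `sample_id`), one group-named score column
#' per panel.
#'
#' @param s Score matrix from [build_score_matrix()].
#' @param path File path.
#' @return `path` (writer) or the score matrix (reader).
#' @export
write_score_matrix <- function(s, path) {
  df <- data.frame(sample_id = rownames(s), unclass(s), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(s))
  kind <- attr(s, "score_kind", exact = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(kind)) writeLines(sprintf("# score_kind=%s", kind), con)
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_kind <- startsWith(first, "# score_kind=")
  df <- read.delim(path, sep = ",", header = TRUE, check.names = FALSE,
                   skip = if (has_kind) 1L else 0L, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (has_kind) attr(m, "score_kind") <- sub("^# score_kind=", "", first)
  m
}

#' Write a classification report (without model objects) as JSON
#'
#' @param report A `classification_report` or `evaluation_summary`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(report, path) {
  if (inherits(report, "classification_report")) {
    payload <- list(
      mode = report$mode, score_kind = report$score_kind, k = report$k,
      seed = report$seed,
      split = list(n_train = length(report$plan$train_ids),
                   n_test = length(report$plan$test_ids),
                   fraction = report$plan$fraction, seed = report$plan$seed),
      panels = lapply(report$panels, function(p)
        list(group = p$group, mode = p$mode, k_requested = p$k_requested,
             genes = p$genes,
             signs = if (!is.null(p$signs)) unname(p$signs))),
      algorithms = lapply(report$algorithms, function(a)
        list(algorithm = a$algorithm, auc = a$auc,
             best_params = a$best_params, cv_accuracy = a$cv_accuracy,
             confusion = as.data.frame(a$confusion))))
  } else if (inherits(report, "evaluation_summary")) {
    payload <- list(mode = report$mode, k = report$k,
                    fraction = report$fraction, base_seed = report$base_seed,
                    auc = report$auc, summary = report$summary)
  } else stop2("unsupported report type")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- run configuration -----------------------------------------------------

run_config_defaults <- function() {
  list(input = NULL, labels = NULL, format = "auto", value_kind = NULL,
       mode = "high_mae", k = 200L, alpha = 0.05, min_nonzero = 10L,
       min_nonzero_fraction = 0, fraction = 0.8, n_repeats = 10L,
       algorithms = algorithm_names(), cv_folds = 10L, seed = 1L,
       out_dir = ".")
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Unknown keys are rejected; numeric fields are range-checked against the
#' contracts of the functions they feed. Values not present fall back to the
#' package defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Validated named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop2("config must be .yaml/.yml or .json, got .%s", ext))
  if (is.null(cfg)) cfg <- list()
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop2("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, cfg)
  cfg$mode <- match.arg(cfg$mode, panel_modes())
  cfg$algorithms <- match.arg(cfg$algorithms, algorithm_names(),
                              several.ok = TRUE)
  check_range <- function(name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    v <- cfg[[name]]
    ok <- length(v) == 1L && is.numeric(v) && is.finite(v) &&
      (if (lo_open) v > lo else v >= lo) && (if (hi_open) v < hi else v <= hi)
    if (!ok) stop2("config '%s' out of range: %s", name, format(v))
  }
  check_range("k", 1, Inf)
  check_range("alpha", 0, 1, lo_open = TRUE)
  check_range("min_nonzero", 1, Inf)
  check_range("min_nonzero_fraction", 0, 1)
  check_range("fraction", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_range("n_repeats", 1, Inf)
  check_range("cv_folds", 2, Inf)
  check_range("seed", -2^31, 2^31, lo_open = TRUE, hi_open = TRUE)
  for (nm in c("k", "min_nonzero", "n_repeats", "cv_folds", "seed"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg
}
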