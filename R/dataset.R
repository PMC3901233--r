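## Dataset container, validation, selection and delimited-text IO.
##
## Conventions (documented in the vignette):
##  * a zero abundance means "measured but not detected";
##  * NA (an empty CSV cell) means "not measured for this sample", e.g. the
##    feature belongs to a platform that was not run on that sample;
##  * matrices are always keyed by feature_id (rows) and sample_id (columns);
##    metadata tables are kept in axis order.

PLATFORM_LEVELS <- c("amino_acid", "surface_lipid", "fatty_acid", "non_targeted")
STAGE_LEVELS <- c("young", "immature", "mature", "unspecified")

SAMPLE_COLS <- c("sample_id", "species", "accession", "organ", "stage", "replicate")
FEATURE_COLS <- c("feature_id", "platform", "chemical_class", "mass",
                  "retention_time", "identified")

#' Assemble a fingerprinting dataset
#'
#' Bundles a features x samples relative-abundance matrix with its sample and
#' feature annotation tables into a single keyed object. Rows of `samples` and
#' `features` are reordered to match the matrix axes; by default the triple is
#' validated and assembly fails on any violation.
#'
#' @param abund numeric matrix, features in rows (rownames = feature_id),
#'   samples in columns (colnames = sample_id). Values are non-negative
#'   relative abundances; `NA` marks a value that was not measured (as opposed
#'   to a measured zero).
#' @param samples data.frame with columns sample_id, species, accession,
#'   organ, stage, replicate.
#' @param features data.frame with columns feature_id, platform,
#'   chemical_class, mass, retention_time, identified.
#' @param validate if `TRUE` (default), stop with a structured error listing
#'   every violation found by [validate_dataset()].
#' @return an object of class `mfp_dataset`: a list with elements `abund`,
#'   `samples`, `features`.
#' @seealso [read_dataset()], [validate_dataset()], [select_samples()]
#' @export
mfp_dataset <- function(abund, samples, features, validate = TRUE) {
  if (!is.matrix(abund)) abund <- as.matrix(abund)
  storage.mode(abund) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)

  missing_s <- setdiff(SAMPLE_COLS, names(samples))
  missing_f <- setdiff(FEATURE_COLS, names(features))
  if (length(missing_s) || length(missing_f)) {
    mfp_stop("mfp_bad_metadata", sprintf(
      "metadata columns missing: %s",
      paste(c(missing_s, missing_f), collapse = ", ")))
  }

  ## align metadata row order with the matrix axes where keys permit
  if (!is.null(rownames(abund)) && !anyDuplicated(features$feature_id) &&
      setequal(rownames(abund), features$feature_id)) {
    features <- features[match(rownames(abund), features$feature_id), ,
                         drop = FALSE]
  }
  if (!is.null(colnames(abund)) && !anyDuplicated(samples$sample_id) &&
      setequal(colnames(abund), samples$sample_id)) {
    samples <- samples[match(colnames(abund), samples$sample_id), , drop = FALSE]
  }
  rownames(samples) <- NULL
  rownames(features) <- NULL

  x <- structure(list(abund = abund, samples = samples, features = features),
                 class = "mfp_dataset")
  if (validate) {
    rep <- validate_dataset(x)
    if (nrow(rep) > 0L) {
      mfp_stop("mfp_validation_error",
               paste0("invalid dataset:\n", paste0("  - ", rep$message,
                                                   collapse = "\n")),
               report = rep)
    }
  }
  x
}

#' @export
print.mfp_dataset <- function(x, ...) {
  cat(sprintf("<mfp_dataset> %d features x %d samples\n",
              nrow(x$abund), ncol(x$abund)))
  pl <- table(x$features$platform)
  if (length(pl)) {
    cat("  platforms: ",
        paste(sprintf("%s (%d)", names(pl), as.integer(pl)), collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("  accessions: %s\n",
              paste(unique(x$samples$accession), collapse = ", ")))
  cat(sprintf("  organs: %s\n", paste(unique(x$samples$organ), collapse = ", ")))
  n_na <- sum(is.na(x$abund))
  cat(sprintf("  missing (unmeasured) cells: %d; zeros: %d\n",
              n_na, sum(x$abund == 0, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.mfp_dataset <- function(x) dim(x$abund)

## one validation-report row
viol <- function(kind, message, offending_id) {
  data.frame(kind = kind, message = message,
             offending_id = as.character(offending_id),
             stringsAsFactors = FALSE)
}

#' Validate a dataset triple
#'
#' Report-based validation: every violation found (duplicate keys, orphan
#' keys between matrix and metadata, negative abundances, out-of-range
#' annotation values) is listed; an empty report means the dataset is valid.
#' The function never throws and has no side effects.
#'
#' @param x an [mfp_dataset] (possibly built with `validate = FALSE`).
#' @return a data.frame of class `mfp_validation` with columns
#'   `kind`, `message`, `offending_id`.
#' @export
validate_dataset <- function(x) {
  reps <- list()
  abund <- x$abund
  samples <- x$samples
  features <- x$features

  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  for (id in dup) {
    reps[[length(reps) + 1L]] <-
      viol("duplicate_sample", sprintf("sample_id '%s' duplicated", id), id)
  }
  dup <- unique(features$feature_id[duplicated(features$feature_id)])
  for (id in dup) {
    reps[[length(reps) + 1L]] <-
      viol("duplicate_feature", sprintf("feature_id '%s' duplicated", id), id)
  }
  key <- paste(samples$accession, samples$organ, samples$stage,
               samples$replicate, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    ids <- samples$sample_id[key == k]
    reps[[length(reps) + 1L]] <- viol(
      "duplicate_design",
      sprintf("samples %s share one (accession, organ, stage, replicate) cell",
              paste(ids, collapse = ", ")),
      ids[2L])
  }

  for (id in setdiff(rownames(abund), features$feature_id)) {
    reps[[length(reps) + 1L]] <- viol(
      "orphan_feature",
      sprintf("feature '%s' present in matrix but absent from feature table", id),
      id)
  }
  for (id in setdiff(features$feature_id, rownames(abund))) {
    reps[[length(reps) + 1L]] <- viol(
      "unknown_feature",
      sprintf("feature '%s' in feature table but absent from matrix", id), id)
  }
  for (id in setdiff(colnames(abund), samples$sample_id)) {
    reps[[length(reps) + 1L]] <- viol(
      "orphan_sample",
      sprintf("sample '%s' present in matrix but absent from sample table", id),
      id)
  }
  for (id in setdiff(samples$sample_id, colnames(abund))) {
    reps[[length(reps) + 1L]] <- viol(
      "unknown_sample",
      sprintf("sample '%s' in sample table but absent from matrix", id), id)
  }

  neg <- which(abund < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    for (i in seq_len(nrow(neg))) {
      fid <- rownames(abund)[neg[i, 1L]] %||% as.character(neg[i, 1L])
      sid <- colnames(abund)[neg[i, 2L]] %||% as.character(neg[i, 2L])
      reps[[length(reps) + 1L]] <- viol(
        "negative_value",
        sprintf("negative abundance %g at feature '%s', sample '%s'",
                abund[neg[i, 1L], neg[i, 2L]], fid, sid),
        paste(fid, sid, sep = ":"))
    }
  }

  bad <- !is.na(features$platform) & !(features$platform %in% PLATFORM_LEVELS)
  for (id in features$feature_id[bad]) {
    reps[[length(reps) + 1L]] <- viol(
      "bad_platform", sprintf("feature '%s' has unknown platform", id), id)
  }
  bad <- !is.na(features$mass) & features$mass <= 0
  for (id in features$feature_id[bad]) {
    reps[[length(reps) + 1L]] <- viol(
      "bad_mass", sprintf("feature '%s' has non-positive mass", id), id)
  }
  bad <- !is.na(features$retention_time) & features$retention_time < 0
  for (id in features$feature_id[bad]) {
    reps[[length(reps) + 1L]] <- viol(
      "bad_retention_time",
      sprintf("feature '%s' has negative retention time", id), id)
  }
  bad <- !is.na(samples$stage) & !(samples$stage %in% STAGE_LEVELS)
  for (id in samples$sample_id[bad]) {
    reps[[length(reps) + 1L]] <- viol(
      "bad_stage", sprintf("sample '%s' has unknown stage", id), id)
  }

  out <- if (length(reps)) do.call(rbind, reps) else
    data.frame(kind = character(), message = character(),
               offending_id = character(), stringsAsFactors = FALSE)
  class(out) <- c("mfp_validation", "data.frame")
  out
}

#' Write a validation report as JSON
#'
#' @param report result of [validate_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(report)), function(i) {
      list(kind = report$kind[i], message = report$message[i],
           offending_id = report$offending_id[i])
    }),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Subset samples of a dataset
#'
#' Restricts the sample axis by a predicate on the sample table; the feature
#' axis and all abundance values are untouched and sample order is preserved.
#'
#' @param x an [mfp_dataset].
#' @param keep one of: a logical vector over samples, a character vector of
#'   sample_ids, or a function taking the sample data.frame and returning a
#'   logical vector.
#' @param ... alternatively, named equality filters on sample table columns,
#'   e.g. `organ = "flowers"`; several names are combined with AND, several
#'   values per name with OR.
#' @return the restricted `mfp_dataset`.
#' @export
select_samples <- function(x, keep = NULL, ...) {
  idx <- resolve_sample_filter(x$samples, keep, ...)
  if (!any(idx)) {
    mfp_stop("mfp_empty_selection", "sample selection matched no samples")
  }
  mfp_dataset(x$abund[, idx, drop = FALSE],
              x$samples[idx, , drop = FALSE],
              x$features, validate = FALSE)
}

resolve_sample_filter <- function(samples, keep = NULL, ...) {
  filters <- list(...)
  if (!is.null(keep)) {
    if (is.function(keep)) {
      idx <- keep(samples)
    } else if (is.character(keep)) {
      idx <- samples$sample_id %in% keep
    } else if (is.logical(keep)) {
      if (length(keep) != nrow(samples)) {
        mfp_stop("mfp_bad_selector",
                 "logical selector length does not match sample count")
      }
      idx <- keep
    } else {
      mfp_stop("mfp_bad_selector", "unsupported selector type")
    }
  } else {
    idx <- rep(TRUE, nrow(samples))
  }
  for (nm in names(filters)) {
    if (!nm %in% names(samples)) {
      mfp_stop("mfp_bad_selector",
               sprintf("unknown sample metadata column '%s'", nm))
    }
    idx <- idx & (samples[[nm]] %in% filters[[nm]])
  }
  idx & !is.na(idx)
}

#' Resolve sample ids by metadata filters
#'
#' Convenience wrapper used to build the two groups of a [volcano()] contrast.
#'
#' @inheritParams select_samples
#' @return character vector of matching sample_ids (possibly empty).
#' @export
samples_where <- function(x, ...) {
  x$samples$sample_id[resolve_sample_filter(x$samples, NULL, ...)]
}

#' Subset features of a dataset
#'
#' @param x an [mfp_dataset].
#' @param ... named equality filters on feature table columns, e.g.
#'   `platform = "surface_lipid"`.
#' @return the restricted `mfp_dataset`.
#' @export
select_features <- function(x, ...) {
  filters <- list(...)
  idx <- rep(TRUE, nrow(x$features))
  for (nm in names(filters)) {
    if (!nm %in% names(x$features)) {
      mfp_stop("mfp_bad_selector",
               sprintf("unknown feature metadata column '%s'", nm))
    }
    idx <- idx & (x$features[[nm]] %in% filters[[nm]])
  }
  idx <- idx & !is.na(idx)
  if (!any(idx)) {
    mfp_stop("mfp_empty_selection", "feature selection matched no features")
  }
  mfp_dataset(x$abund[idx, , drop = FALSE], x$samples,
              x$features[idx, , drop = FALSE], validate = FALSE)
}

## IO -------------------------------------------------------------------------

#' Write a dataset to three CSV files
#'
#' Emits `abundance.csv` (first column `feature_id`, one column per sample,
#' empty cell = unmeasured), `samples.csv` and `features.csv` into `dir`.
#' Numerics are written with 17 significant digits so that
#' `read_dataset(write_dataset(x))` reproduces every value exactly.
#'
#' @param x an [mfp_dataset].
#' @param dir output directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(x, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) mfp_stop("mfp_io_error", sprintf("cannot create directory '%s'", dir))
  }
  paths <- c(abundance = file.path(dir, "abundance.csv"),
             samples = file.path(dir, "samples.csv"),
             features = file.path(dir, "features.csv"))

  mat <- x$abund
  df <- data.frame(feature_id = rownames(mat) %||% character(0),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- format_num(mat[, j])
  write_csv_utf8(df, paths[["abundance"]], quote = 1L)

  write_csv_utf8(x$samples[SAMPLE_COLS], paths[["samples"]], quote = 1:5)

  fd <- x$features[FEATURE_COLS]
  fd$mass <- format_num(fd$mass)
  fd$retention_time <- format_num(fd$retention_time)
  write_csv_utf8(fd, paths[["features"]], quote = 1:3)

  invisible(paths)
}

write_csv_utf8 <- function(df, path, quote = TRUE) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = quote,
                     qmethod = "double", na = "")
}

#' Read a dataset from three CSV files
#'
#' Inverse of [write_dataset()]. Empty abundance cells are parsed as missing
#' (unmeasured), never as zero. The triple is validated on read; key
#' mismatches or negative values raise a structured error naming the
#' offending ids.
#'
#' @param matrix_path path to the abundance CSV (header = sample ids, first
#'   column = feature ids). Alternatively a directory holding
#'   `abundance.csv`, `samples.csv`, `features.csv`.
#' @param samples_path,features_path paths to the metadata CSVs; derived from
#'   the directory when `matrix_path` is a directory.
#' @return an [mfp_dataset].
#' @export
read_dataset <- function(matrix_path, samples_path = NULL, features_path = NULL) {
  if (dir.exists(matrix_path)) {
    samples_path <- samples_path %||% file.path(matrix_path, "samples.csv")
    features_path <- features_path %||% file.path(matrix_path, "features.csv")
    matrix_path <- file.path(matrix_path, "abundance.csv")
  }
  for (p in c(matrix_path, samples_path, features_path)) {
    if (!file.exists(p)) mfp_stop("mfp_io_error", sprintf("file not found: '%s'", p))
  }

  raw <- utils::read.csv(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) < 1L) mfp_stop("mfp_io_error", "abundance file has no columns")
  ids <- raw[[1L]]
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  mat <- matrix(as.numeric(mat), nrow = nrow(raw), ncol = ncol(raw) - 1L,
                dimnames = list(ids, colnames(raw)[-1L]))

  samples <- utils::read.csv(samples_path, check.names = FALSE,
                             stringsAsFactors = FALSE, na.strings = "",
                             fileEncoding = "UTF-8")
  samples$sample_id <- as.character(samples$sample_id)
  features <- utils::read.csv(features_path, check.names = FALSE,
                              stringsAsFactors = FALSE, na.strings = "",
                              fileEncoding = "UTF-8")
  features$feature_id <- as.character(features$feature_id)
  if (!"identified" %in% names(features)) features$identified <- NA
  features$identified <- as.logical(features$identified)
  for (col in c("mass", "retention_time")) {
    if (!col %in% names(features)) features[[col]] <- NA_real_
    features[[col]] <- as.numeric(features[[col]])
  }
  if (!"chemical_class" %in% names(features)) {
    features$chemical_class <- NA_character_
  }
  features$chemical_class <- as.character(features$chemical_class)

  mfp_dataset(mat, samples, features, validate = TRUE)
}
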