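## Deterministic pipeline driver: simulate (or read) -> validate -> qc ->
## volcano / ratio panels -> distance -> mds -> cluster, with a provenance
## manifest. All numeric outputs are plain CSV/JSON; nothing timestamped, so
## identical configs yield byte-identical artifact directories.

PIPELINE_STAGES <- c("simulate", "validate", "qc", "volcano", "ratio_panels",
                     "distance", "mds", "cluster")

default_config <- function() {
  list(
    seed = 1L,
    design = "prunella",
    stages = PIPELINE_STAGES,
    volcano = list(group_a = list(organ = "cauline leaves"),
                   group_b = list(organ = "flowers")),
    ratio_panels = list(organ_a = "cauline leaves", organ_b = "flowers"),
    ## the classic single-organ, single-platform fingerprint slice:
    ## cuticular lipids of the vegetative organs of shoots (25 samples)
    distance = list(organ = "vegetative organs of shoots",
                    platform = "surface_lipid", strict = FALSE),
    mds = list(dims = 2L),
    cluster = list(k = 3L, linkage = "average", n_init = 10L),
    qc = list(threshold = 0.7)
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults and checks types/ranges; all offending keys are collected
#' into one `mfp_config_error`.
#'
#' @param config a named list, or path to a JSON file holding one.
#' @return the completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      mfp_stop("mfp_config_error", sprintf("config file not found: '%s'", config),
               keys = "config")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    mfp_stop("mfp_config_error", "config must be a named list or JSON path",
             keys = "config")
  }
  bad <- character(0)
  known <- c(names(default_config()), "dataset_dir")
  bad <- c(bad, setdiff(names(config), known))
  cfg <- utils::modifyList(default_config(), config)

  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    bad <- c(bad, "seed")
  }
  if (!all(cfg$stages %in% PIPELINE_STAGES)) bad <- c(bad, "stages")
  k <- cfg$cluster$k
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) bad <- c(bad, "cluster.k")
  if (!cfg$cluster$linkage %in% c("average", "complete", "single")) {
    bad <- c(bad, "cluster.linkage")
  }
  dims <- cfg$mds$dims
  if (!is.numeric(dims) || dims < 1) bad <- c(bad, "mds.dims")
  if (!is.character(cfg$design) && !is.list(cfg$design)) bad <- c(bad, "design")
  if (is.character(cfg$design) && !identical(cfg$design, "prunella")) {
    bad <- c(bad, "design")
  }
  if (length(bad)) {
    mfp_stop("mfp_config_error",
             sprintf("invalid configuration keys: %s",
                     paste(unique(bad), collapse = ", ")),
             keys = unique(bad))
  }
  cfg
}

write_df_csv <- function(df, path, digits17 = NULL) {
  for (col in digits17 %||% character(0)) df[[col]] <- format_num(df[[col]])
  write_csv_utf8(df, path)
  path
}

#' Run the fingerprinting pipeline
#'
#' Executes the configured stages in order and writes every artifact plus a
#' `manifest.json` (package version, seed, full configuration, md5 of every
#' output) into `out_dir`. Given identical configurations the artifact
#' directory is byte-identical across runs, so any output is reproducible
#' from the manifest alone.
#'
#' @param config named list or JSON path, see [validate_config()]. The
#'   default simulates the five-accession preset design and runs every
#'   stage.
#' @param out_dir artifact directory (created if needed).
#' @return named list of the produced objects, invisibly; component `paths`
#'   maps artifact names to files.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    mfp_stop("mfp_io_error", sprintf("cannot create directory '%s'", out_dir))
  }
  paths <- character(0)
  res <- list()
  emit <- function(name, path) paths[[name]] <<- path

  run_stage <- function(name, code) {
    tryCatch(code, mfp_config_error = function(e) stop(e), error = function(e) {
      mfp_stop("mfp_stage_error",
               sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               stage = name)
    })
  }

  ## --- data ---
  if ("simulate" %in% cfg$stages) {
    sim <- run_stage("simulate", {
      design <- if (identical(cfg$design, "prunella")) prunella_preset() else
        do.call(simulation_design, cfg$design)
      simulate_dataset(design, seed = cfg$seed)
    })
    dataset <- sim$dataset
    res$sim <- sim
    ps <- write_dataset(dataset, file.path(out_dir, "dataset"))
    for (nm in names(ps)) emit(paste0("dataset_", nm), ps[[nm]])
  } else {
    if (is.null(cfg$dataset_dir)) {
      mfp_stop("mfp_config_error",
               "either the simulate stage or `dataset_dir` is required",
               keys = "dataset_dir")
    }
    dataset <- run_stage("read", read_dataset(cfg$dataset_dir))
  }
  res$dataset <- dataset

  if ("validate" %in% cfg$stages) {
    rep <- run_stage("validate", validate_dataset(dataset))
    if (nrow(rep) > 0L) {
      mfp_stop("mfp_validation_error",
               sprintf("dataset failed validation (%d violations)", nrow(rep)),
               report = rep)
    }
    emit("validation", write_validation_report(rep, file.path(out_dir, "validation.json")))
    res$validation <- rep
  }

  if ("qc" %in% cfg$stages) {
    qc <- run_stage("qc", replicate_correlations(dataset))
    flags <- flag_outlier_replicates(qc, threshold = cfg$qc$threshold)
    emit("qc_pairs", write_df_csv(qc$pairs, file.path(out_dir, "qc_pairs.csv"),
                                  digits17 = "rho"))
    jsonlite::write_json(
      list(threshold = cfg$qc$threshold,
           flags = if (nrow(flags)) flags else list(),
           skipped_groups = qc$skipped),
      file.path(out_dir, "qc_flags.json"), auto_unbox = TRUE, pretty = TRUE)
    emit("qc_flags", file.path(out_dir, "qc_flags.json"))
    res$qc <- qc
    res$qc_flags <- flags
  }

  if ("volcano" %in% cfg$stages) {
    volc <- run_stage("volcano", {
      ga <- do.call(samples_where, c(list(dataset), cfg$volcano$group_a))
      gb <- do.call(samples_where, c(list(dataset), cfg$volcano$group_b))
      volcano(dataset, ga, gb)
    })
    emit("volcano", write_df_csv(
      as.data.frame(volc), file.path(out_dir, "volcano.csv"),
      digits17 = c("mean_a", "mean_b", "ratio", "log2_ratio", "t", "df",
                   "p_value", "neg_log10_p")))
    res$volcano <- volc
  }

  if ("ratio_panels" %in% cfg$stages) {
    rp <- run_stage("ratio_panels",
                    ratio_panels(dataset, cfg$ratio_panels$organ_a,
                                 cfg$ratio_panels$organ_b))
    df <- data.frame(feature_id = rownames(rp$log2_ratio),
                     rp$log2_ratio, check.names = FALSE,
                     stringsAsFactors = FALSE)
    emit("ratio_panels", write_df_csv(df, file.path(out_dir, "ratio_panels.csv"),
                                      digits17 = colnames(rp$log2_ratio)))
    jsonlite::write_json(
      list(organ_a = rp$organ_a, organ_b = rp$organ_b,
           pseudocount = rp$pseudocount, feature_order = rp$feature_order),
      file.path(out_dir, "ratio_panels_order.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    emit("ratio_panels_order", file.path(out_dir, "ratio_panels_order.json"))
    res$ratio_panels <- rp
  }

  slice <- NULL
  if (any(c("distance", "mds", "cluster") %in% cfg$stages)) {
    slice <- run_stage("distance", {
      s <- dataset
      if (!is.null(cfg$distance$organ)) s <- select_samples(s, organ = cfg$distance$organ)
      if (!is.null(cfg$distance$platform)) {
        s <- select_features(s, platform = cfg$distance$platform)
      }
      s
    })
  }

  if ("distance" %in% cfg$stages) {
    d <- run_stage("distance",
                   fingerprint_dist(slice, strict = isTRUE(cfg$distance$strict)))
    emit("distance", write_dist(d, file.path(out_dir, "distance.csv")))
    emit("distance_provenance", file.path(out_dir, "distance.csv.json"))
    res$distance <- d

    if ("mds" %in% cfg$stages) {
      mds <- run_stage("mds", classical_mds(d, dims = cfg$mds$dims))
      df <- data.frame(sample_id = rownames(mds$points), mds$points,
                       check.names = FALSE, stringsAsFactors = FALSE)
      emit("mds", write_df_csv(df, file.path(out_dir, "mds_coordinates.csv"),
                               digits17 = colnames(mds$points)))
      jsonlite::write_json(list(eigenvalues = mds$eig, gof = mds$gof),
                           file.path(out_dir, "mds_eigenvalues.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      emit("mds_eigenvalues", file.path(out_dir, "mds_eigenvalues.json"))
      res$mds <- mds
    }
  }

  if ("cluster" %in% cfg$stages) {
    cl <- run_stage("cluster", {
      std <- suppressWarnings(standardize_max(slice))
      list(std = std,
           kmeans = kmeans_cluster(std, k = cfg$cluster$k,
                                   n_init = cfg$cluster$n_init, seed = cfg$seed),
           hclust = hierarchical_cluster(std, linkage = cfg$cluster$linkage,
                                         k = cfg$cluster$k))
    })
    df <- data.frame(sample_id = names(cl$kmeans$assignments),
                     kmeans = unname(cl$kmeans$assignments),
                     hierarchical = unname(cl$hclust$assignments),
                     stringsAsFactors = FALSE)
    emit("clusters", write_df_csv(df, file.path(out_dir, "clusters.csv")))
    jsonlite::write_json(
      list(k = cfg$cluster$k, linkage = cfg$cluster$linkage,
           merge = cl$hclust$tree$merge, height = cl$hclust$tree$height,
           labels = cl$hclust$tree$labels),
      file.path(out_dir, "cluster_tree.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    emit("cluster_tree", file.path(out_dir, "cluster_tree.json"))
    res$kmeans <- cl$kmeans
    res$hclust <- cl$hclust
  }

  manifest <- list(
    package = "metabofp",
    version = as.character(utils::packageVersion("metabofp")),
    seed = cfg$seed,
    config = cfg,
    outputs = lapply(paths, function(p) {
      list(file = substring(p, nchar(out_dir) + 2L),
           md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths[["manifest"]] <- file.path(out_dir, "manifest.json")
  res$paths <- paths
  invisible(res)
}
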