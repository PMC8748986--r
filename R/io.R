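# CSV dialect everywhere: comma separated, UTF-8, header row, "." decimal.

write_csv_std <- function(x, path) {
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_std <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tibble::as_tibble(read.csv(path, fileEncoding = "UTF-8",
                                  check.names = FALSE))
  miss <- setdiff(required, names(d))
  if (length(miss) > 0) {
    stop("malformed CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  d
}

#' Write / read a shape table CSV
#'
#' Columns: `image_id`, `nucleus_id`, `cx_um`, `cy_um`, `cz_um`,
#' `r000`..`r{n-1}` (all lengths in um).
#'
#' @param shapes Shape table.
#' @param path File path.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @export
write_shapes <- function(shapes, path) write_csv_std(shapes, path)

#' @rdname write_shapes
#' @export
read_shapes <- function(path) {
  d <- read_csv_std(path, c("image_id", "nucleus_id", "cx_um", "cy_um", "cz_um"))
  ray_matrix(d) # validates ray columns and positivity
  d
}

#' Write / read a cohort manifest CSV
#'
#' One row per image: `image_id`, `patient_id`, `diagnosis` and any extra
#' columns (seed, field of view). Diagnosis tokens are validated against
#' the canonical vocabulary, with the offending row reported.
#'
#' @param manifest Manifest tibble.
#' @param path File path.
#' @return The tibble (reader) or the path, invisibly (writer).
#' @export
write_manifest <- function(manifest, path) write_csv_std(manifest, path)

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  d <- read_csv_std(path, c("image_id", "diagnosis"))
  bad <- which(!d$diagnosis %in% DIAGNOSIS_LEVELS)
  if (length(bad) > 0) {
    stop("unknown diagnosis '", d$diagnosis[bad[1]], "' in ", path,
         " at row ", bad[1])
  }
  if (anyDuplicated(d$image_id)) stop("duplicate image_id in manifest ", path)
  d
}

#' Load a dataset from a manifest plus shape tables or label volumes
#'
#' The manifest names the images; shapes come either from a single shape
#' table CSV covering all images, or from per-image multi-page TIFF label
#' volumes referenced in a `path` column of the manifest (with voxel
#' `spacing` supplied).
#'
#' @param manifest_path Manifest CSV path.
#' @param shapes_path Optional shape-table CSV covering the cohort.
#' @param spacing Voxel spacing `(z, y, x)` in um, for the TIFF route.
#' @param dirs A [direction_set()], for the TIFF route.
#' @return List `shapes`, `manifest`.
#' @export
load_dataset <- function(manifest_path, shapes_path = NULL, spacing = NULL,
                         dirs = NULL) {
  manifest <- read_manifest(manifest_path)
  if (!is.null(shapes_path)) {
    shapes <- read_shapes(shapes_path)
  } else {
    if (!"path" %in% names(manifest)) {
      stop("manifest has no 'path' column and no shapes_path was given")
    }
    if (is.null(spacing)) stop("label-volume ingestion requires voxel spacing")
    dirs <- dirs %||% direction_set(96)
    base <- dirname(manifest_path)
    shapes <- dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
      p <- manifest$path[i]
      if (!file.exists(p)) p <- file.path(base, manifest$path[i])
      if (!file.exists(p)) {
        stop("missing file for image ", manifest$image_id[i], " (row ", i,
             "): ", manifest$path[i])
      }
      read_label_volume(p, spacing, dirs, image_id = manifest$image_id[i])
    }))
  }
  extra <- setdiff(unique(shapes$image_id), manifest$image_id)
  if (length(extra) > 0) {
    stop("shape table contains image(s) absent from the manifest: ",
         paste(head(extra, 3), collapse = ", "))
  }
  list(shapes = shapes, manifest = manifest)
}

#' Pipeline configuration
#'
#' Validated bundle of every stage's tunables. Unknown keys are rejected.
#'
#' @param n_rays Ray count of the direction set.
#' @param cutoff_um Neighbor-graph edge cutoff, um.
#' @param thresholds `"calibrated"` or `"fixed"` rule mode.
#' @param tail_fraction Rule calibration tail.
#' @param k Cross-validation fold count.
#' @param seed Master seed.
#' @param methods Scoring methods to run.
#' @param fov_x_mm,fov_y_mm En-face field of view used for densities.
#' @param reference Reference method for report correlations.
#' @param output_dir Where `run_pipeline()` writes artifacts (`NULL` for
#'   none).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(n_rays = 96, cutoff_um = 50,
                            thresholds = "calibrated", tail_fraction = 0.1,
                            k = 5, seed = 1L, methods = ATYPIA_METHODS,
                            fov_x_mm = 0.3, fov_y_mm = 0.2,
                            reference = "gbt", output_dir = NULL) {
  stopifnot(n_rays >= 4, cutoff_um > 0, k >= 2,
            tail_fraction > 0, tail_fraction < 1,
            fov_x_mm > 0, fov_y_mm > 0)
  thresholds <- match.arg(thresholds, c("calibrated", "fixed"))
  stopifnot(all(methods %in% ATYPIA_METHODS))
  if (!is.null(reference) && !reference %in% methods) reference <- NULL
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments;
#'   unknown keys raise an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  unknown <- setdiff(names(obj), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, obj)
}

#' Run the full atypia pipeline on a cohort
#'
#' Composition of the stages: neighbor graph and border distances per
#' image, the 13 cell features, image metrics, cross-validated atypia
#' scores for every requested method, and the evaluation report (AUC per
#' diagnosis subset, correlations to the reference method, image-metric
#' t-tests). Identical config + data give identical outputs. When
#' `config$output_dir` is set, every intermediate table is written as CSV
#' and the report as JSON.
#'
#' @param shapes Cohort shape table.
#' @param manifest Cohort manifest (`image_id`, `diagnosis`, ...).
#' @param config A [pipeline_config()].
#' @return List: `features`, `image_metrics`, `results` (per-method
#'   [cv_scores()] objects), `image_scores` (wide), `report`,
#'   `metric_tests`, `config`, `log` (per-stage counts).
#' @export
run_pipeline <- function(shapes, manifest, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dirs <- direction_set(config$n_rays)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  features <- stage("features", {
    dplyr::bind_rows(lapply(split(shapes, shapes$image_id), function(s) {
      g <- build_graph(s, cutoff = config$cutoff_um,
                       jitter_seed = config$seed)
      g <- edge_geometry(g, s, dirs)
      cell_features(s, g, dirs)
    }))
  })
  metrics <- stage("image_metrics",
                   image_metrics(features, config$fov_x_mm, config$fov_y_mm))
  results <- stage("scoring", {
    score_cohort(features, manifest, methods = config$methods,
                 k = config$k, seed = config$seed,
                 thresholds = config$thresholds,
                 tail_fraction = config$tail_fraction)
  })
  scores <- image_score_table(results)
  report <- stage("evaluation",
                  evaluation_report(scores, reference = config$reference))
  metric_tests <- stage("evaluation", image_metric_ttests(metrics, manifest))

  log <- list(
    n_images = length(unique(shapes$image_id)),
    n_nuclei = nrow(features),
    n_excluded_degree0 = sum(features$n_missing > 0),
    fold_sizes = as.integer(table(results[[1]]$folds$fold)),
    effective_config = unclass(config)
  )
  out <- list(features = features, image_metrics = metrics,
              results = results, image_scores = scores, report = report,
              metric_tests = metric_tests, config = config, log = log)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    write_csv_std(features, file.path(od, "cell_features.csv"))
    write_csv_std(metrics, file.path(od, "image_metrics.csv"))
    cs <- dplyr::bind_rows(lapply(results, function(r) {
      dplyr::mutate(r$cell_scores, method = r$method)
    }))
    write_csv_std(cs, file.path(od, "cell_scores.csv"))
    write_csv_std(scores, file.path(od, "image_scores.csv"))
    write_csv_std(metric_tests, file.path(od, "image_metric_ttests.csv"))
    jsonlite::write_json(
      list(report = report, log = log), file.path(od, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

#' Read a reader-study score sheet CSV
#'
#' Expected columns: `image_id`, `reader_id` and six criterion columns
#' with integer scores 0-4.
#'
#' @param path CSV path.
#' @return Tibble, validated.
#' @export
read_reader_sheet <- function(path) {
  d <- read_csv_std(path, c("image_id", "reader_id"))
  crit <- setdiff(names(d), c("image_id", "reader_id"))
  if (length(crit) != 6) {
    stop("reader sheet ", path, " must have exactly 6 criterion columns, got ",
         length(crit))
  }
  d
}
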