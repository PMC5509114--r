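#' Run configuration for an end-to-end pipeline run
#'
#' Assembles (and validates) every setting the pipeline needs. Either a
#' synthetic population is simulated from \code{templates}, or tracing
#' images are read from \code{image_dir} (files named
#' \code{<specimen_id>__gold.png} for the expert and
#' \code{<specimen_id>__w<k>.png} for workers, with specimen metadata in
#' \code{metadata}).
#'
#' @param templates list of [shape_class_template()]s (synthetic mode), or
#'   \code{NULL} in image mode.
#' @param image_dir directory of tracing images (image mode), or
#'   \code{NULL}.
#' @param metadata data frame (specimen_id, class_label, tooth_position)
#'   for image mode.
#' @param noise a [worker_noise_model()] (synthetic mode).
#' @param H,K harmonics and landmarks per outline.
#' @param threshold,reference_mode consensus filtering settings, see
#'   [consensus_config()].
#' @param ntree,R forest size and number of single-worker resamples.
#' @param seed integer seed recorded in every artifact.
#' @param out_dir directory for artifacts.
#' @return validated list of class \code{"run_config"}.
#' @export
run_config <- function(templates = lm2_templates(), image_dir = NULL,
                       metadata = NULL, noise = worker_noise_model(),
                       H = 10, K = 150, threshold = 0.2,
                       reference_mode = "worker_mean", ntree = 500, R = 50,
                       seed = 1, out_dir = tempfile("toothtrace_run_")) {
  if (is.null(templates) && is.null(image_dir))
    stop("either 'templates' or 'image_dir' must be provided")
  if (K < 3) stop("'K' must be >= 3")
  if (threshold <= 0) stop("'threshold' must be > 0")
  structure(list(templates = templates, image_dir = image_dir,
                 metadata = metadata, noise = noise, H = H, K = K,
                 threshold = threshold, reference_mode = reference_mode,
                 ntree = ntree, R = R, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may define \code{seed}, \code{H}, \code{K}, \code{threshold},
#' \code{reference_mode}, \code{ntree}, \code{R}, \code{out_dir}, a
#' \code{noise} block (fields of [worker_noise_model()]), and a
#' \code{templates} block: a list of entries with \code{class_label},
#' \code{n_specimens}, \code{coeff_sd_scale}, and a \code{shape} block
#' (fields of [molar_mean_shape()]).
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  templates <- if (!is.null(y$templates)) {
    lapply(y$templates, function(tp) {
      shape <- do.call(molar_mean_shape, as.list(tp$shape %||% list()))
      shape_class_template(tp$class_label, shape,
                           tp$coeff_sd_scale %||% 0.045,
                           tp$n_specimens,
                           tp$tooth_position %||% "LM2")
    })
  } else lm2_templates()
  noise <- do.call(worker_noise_model, as.list(y$noise %||% list()))
  args <- y[intersect(names(y), c("H", "K", "threshold", "reference_mode",
                                  "ntree", "R", "seed", "out_dir"))]
  do.call(run_config, c(list(templates = templates, noise = noise), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute the full pipeline
#'
#' Runs simulate (or ingest) -> grade -> consensus -> classify, writing
#' every intermediate artifact as plain text so each reported number can be
#' audited per specimen: specimen metadata and outlines as CSV, per-tracing
#' distances and keep flags as CSV, consensus outlines as CSV, the
#' condition comparison as JSON, and a manifest with the seed, per-stage
#' timings, warnings, and MD5 checksums of every artifact. Re-running with
#' the same config and seed reproduces identical checksums.
#'
#' @param config a [run_config()].
#' @return the manifest (invisibly also written to
#'   \code{out_dir/manifest.json}), as a list with elements \code{seed},
#'   \code{artifacts} (named checksums), \code{timings_sec},
#'   \code{warnings}, and \code{results} (log-losses and rates per
#'   condition).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c(); warns <- character()
  tic <- function() proc.time()[["elapsed"]]
  note_warn <- function(w) { warns <<- c(warns, conditionMessage(w))
                             invokeRestart("muffleWarning") }

  # --- stage 1: data -----------------------------------------------------
  t0 <- tic()
  if (!is.null(config$image_dir)) {
    dataset <- withCallingHandlers(
      ingest_images(config$image_dir, config$metadata, config$H, config$K),
      warning = note_warn)
  } else {
    dataset <- generate_population(config$templates, seed = config$seed,
                                   K = config$K)
    dataset <- simulate_worker_tracings(dataset, config$noise,
                                        seed = config$seed + 1L)
  }
  write_dataset_csv(dataset, config$out_dir)
  timings["data"] <- tic() - t0

  # --- stage 2: grading --------------------------------------------------
  t0 <- tic()
  cfg <- consensus_config(threshold = config$threshold,
                          reference_mode = config$reference_mode)
  bundles <- lapply(dataset$specimens$specimen_id, function(id) {
    b <- tracing_bundle(id, gold = dataset$landmarks[[id]],
                        tracings = dataset$tracings[[id]])
    if (length(b$tracings) > 0) filter_tracings(b, cfg) else b
  })
  names(bundles) <- dataset$specimens$specimen_id
  dist_df <- do.call(rbind, lapply(bundles, function(b) {
    if (length(b$tracings) == 0) return(NULL)
    data.frame(specimen_id = b$specimen_id,
               tracing_id = vapply(b$tracings, function(t)
                 attr(t, "tracing_id") %||% NA_character_, ""),
               distance = b$distances, kept = b$kept)
  }))
  utils::write.csv(dist_df, file.path(config$out_dir, "distances.csv"),
                   row.names = FALSE)
  es <- error_summary(bundles[lengths(dataset$tracings) > 0],
                      groups = dataset$specimens$class_label[
                        lengths(dataset$tracings) > 0])
  utils::write.csv(es$summary,
                   file.path(config$out_dir, "error_summary.csv"),
                   row.names = FALSE)
  timings["grade"] <- tic() - t0

  # --- stage 3: consensus ------------------------------------------------
  t0 <- tic()
  cons_rows <- list()
  for (b in bundles) {
    if (length(b$tracings) == 0 || b$no_usable) next
    cs <- consensus_shape(b)
    cons_rows[[b$specimen_id]] <-
      data.frame(specimen_id = b$specimen_id,
                 point_index = seq_len(nrow(cs)), x = cs[, 1], y = cs[, 2])
  }
  utils::write.csv(do.call(rbind, cons_rows),
                   file.path(config$out_dir, "consensus_outlines.csv"),
                   row.names = FALSE)
  timings["consensus"] <- tic() - t0

  # --- stage 4: classification -------------------------------------------
  t0 <- tic()
  res <- run_conditions(dataset, seed = config$seed, R = config$R,
                        H = config$H, ntree = config$ntree,
                        threshold = config$threshold)
  report <- list(
    seed = config$seed,
    conditions = lapply(res$reports, function(r) list(
      condition_label = r$condition_label,
      log_loss = r$log_loss,
      classification_rate = r$classification_rate,
      n = r$n,
      confusion = as.data.frame(as.table(r$confusion)))),
    single_worker_logloss = res$single_worker_logloss,
    single_worker_mean = res$single_worker_mean,
    dropped = as.list(res$dropped))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  timings["classify"] <- tic() - t0

  artifacts <- list.files(config$out_dir, full.names = TRUE)
  artifacts <- artifacts[!basename(artifacts) %in% "manifest.json"]
  manifest <- list(
    seed = config$seed,
    settings = list(H = config$H, K = config$K,
                    threshold = config$threshold,
                    reference_mode = config$reference_mode,
                    ntree = config$ntree, R = config$R),
    artifacts = as.list(tools::md5sum(sort(artifacts))),
    timings_sec = as.list(round(timings, 3)),
    warnings = warns,
    results = list(
      expert_log_loss = res$reports$expert$log_loss,
      worker_consensus_log_loss = res$reports$worker_consensus$log_loss,
      consensus_plus_expert_log_loss =
        res$reports$consensus_plus_expert$log_loss,
      single_worker_mean_log_loss = res$single_worker_mean,
      expert_rate = res$reports$expert$classification_rate,
      worker_consensus_rate =
        res$reports$worker_consensus$classification_rate))
  names(manifest$artifacts) <- basename(names(manifest$artifacts))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

write_dataset_csv <- function(dataset, out_dir) {
  utils::write.csv(dataset$specimens,
                   file.path(out_dir, "specimens.csv"), row.names = FALSE)
  pts <- function(id, tracing_id, m)
    data.frame(specimen_id = id, tracing_id = tracing_id,
               point_index = seq_len(nrow(m)), x = m[, 1], y = m[, 2])
  truth <- do.call(rbind, lapply(names(dataset$landmarks), function(id)
    pts(id, "truth", dataset$landmarks[[id]])))
  utils::write.csv(truth, file.path(out_dir, "true_outlines.csv"),
                   row.names = FALSE)
  tr <- do.call(rbind, unlist(lapply(names(dataset$tracings), function(id)
    lapply(dataset$tracings[[id]], function(t)
      pts(id, attr(t, "tracing_id") %||% "w", t))), recursive = FALSE))
  if (!is.null(tr))
    utils::write.csv(tr, file.path(out_dir, "worker_outlines.csv"),
                     row.names = FALSE)
  invisible(NULL)
}

# image-mode ingest: masks -> contours -> canonical landmark outlines
ingest_images <- function(image_dir, metadata, H, K) {
  if (is.null(metadata)) stop("image mode requires a metadata table")
  files <- list.files(image_dir, pattern = "\\.(png|jpe?g)$",
                      ignore.case = TRUE)
  parse <- regmatches(files,
                      regexec("^(.*)__((gold)|w([0-9]+))\\.[^.]+$", files))
  ok <- lengths(parse) > 0
  if (any(!ok))
    warning("ignoring files without the <id>__gold/<id>__w<k> pattern: ",
            paste(files[!ok], collapse = ", "))
  lms <- list(); trs <- list()
  for (p in parse[ok]) {
    id <- p[2]; role <- p[3]
    mask <- read_mask(file.path(image_dir, p[1]))
    lm <- efa_inverse(efa_normalize(efa_forward(extract_contour(mask),
                                                H = H)), K = K)
    if (role == "gold") {
      lms[[id]] <- lm
    } else {
      attr(lm, "tracing_id") <- sub("\\.[^.]+$", "", p[1])
      trs[[id]] <- c(trs[[id]] %||% list(), list(lm))
    }
  }
  spec <- metadata[metadata$specimen_id %in% names(lms), , drop = FALSE]
  missing_meta <- setdiff(names(lms), metadata$specimen_id)
  if (length(missing_meta) > 0)
    warning("specimens missing from metadata: ",
            paste(missing_meta, collapse = ", "))
  structure(list(specimens = spec, landmarks = lms[spec$specimen_id],
                 tracings = stats::setNames(
                   lapply(spec$specimen_id, function(id)
                     trs[[id]] %||% list()), spec$specimen_id),
                 seed = NA_integer_, K = K),
            class = "tooth_dataset")
}

#' Validate a directory of tracing images against a metadata table
#'
#' Ingest-time quality report: lists unreadable or wrongly formatted files,
#' masks with no foreground ("no tracing found"), masks whose foreground
#' touches the image border (possibly clipped tracings), and specimens
#' absent from the metadata table. Nothing is silently dropped; every
#' reject carries a reason.
#'
#' @param image_dir directory of tracing images.
#' @param metadata data frame with at least \code{specimen_id}.
#' @return data frame (file, status, reason) with one row per file; status
#'   is \code{"ok"} or \code{"reject"} (border contact is a warning-level
#'   reason but reported as \code{"ok"} with the reason noted).
#' @export
validate_inputs <- function(image_dir, metadata = NULL) {
  files <- list.files(image_dir)
  if (length(files) == 0)
    return(data.frame(file = character(), status = character(),
                      reason = character()))
  rows <- lapply(files, function(f) {
    path <- file.path(image_dir, f)
    mask <- tryCatch(read_mask(path), error = function(e) e)
    if (inherits(mask, "error"))
      return(data.frame(file = f, status = "reject",
                        reason = conditionMessage(mask)))
    if (!any(mask$pixels))
      return(data.frame(file = f, status = "reject",
                        reason = "no tracing found (empty mask)"))
    reason <- ""
    px <- mask$pixels
    if (any(px[1, ]) || any(px[nrow(px), ]) || any(px[, 1]) ||
        any(px[, ncol(px)]))
      reason <- "foreground touches image border (possible clipped tracing)"
    id <- sub("__.*$", "", f)
    if (!is.null(metadata) && !id %in% metadata$specimen_id)
      return(data.frame(file = f, status = "reject",
                        reason = paste0("specimen '", id,
                                        "' missing from metadata")))
    data.frame(file = f, status = "ok", reason = reason)
  })
  do.call(rbind, rows)
}
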