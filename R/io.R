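# Plain-text set container.
#
# A set is stored as a directory:
#   <path>/meta.json : axis attributes (dwell_s, f0_mhz, ref_ppm),
#                      n_points, n_signals, format version
#   <path>/data.csv  : one row per transient; columns label, split,
#                      true_freq_hz, true_phase_deg, snr_nominal,
#                      re_1..re_n, im_1..im_n (full 64-bit round-trip)

SET_FORMAT_VERSION <- 1L

#' Write a transient set to a text container
#'
#' @param s an [mrs_set()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_set <- function(s, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "mrsfpc-set", version = SET_FORMAT_VERSION,
               n_points = s$axis$n_points, n_signals = length(s),
               dwell_s = s$axis$dwell_s, f0_mhz = s$axis$f0_mhz,
               ref_ppm = s$axis$ref_ppm)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  re <- t(Re(s$samples)); im <- t(Im(s$samples))
  colnames(re) <- paste0("re_", seq_len(ncol(re)))
  colnames(im) <- paste0("im_", seq_len(ncol(im)))
  d <- data.table::data.table(label = s$label, split = s$split,
                              true_freq_hz = s$true_freq_hz,
                              true_phase_deg = s$true_phase_deg,
                              snr_nominal = s$snr_nominal)
  d <- cbind(d, data.table::as.data.table(re), data.table::as.data.table(im))
  data.table::fwrite(d, file.path(path, "data.csv"))
  invisible(path)
}

#' Read a transient set from a text container
#'
#' @param path directory written by [write_set()].
#' @return an [mrs_set()].
#' @export
read_set <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a set container (missing meta.json): ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (field in c("dwell_s", "f0_mhz", "ref_ppm", "n_points", "n_signals"))
    if (is.null(meta[[field]]))
      stop("set container is missing required attribute `", field, "`")
  axis <- mrs_axis(meta$n_points, meta$dwell_s, meta$f0_mhz, meta$ref_ppm)
  d <- data.table::fread(file.path(path, "data.csv"))
  for (col in c("label", "split", "true_freq_hz", "true_phase_deg",
                "snr_nominal"))
    if (!col %in% names(d))
      stop("set container is missing required dataset `", col, "`")
  np <- meta$n_points
  re_cols <- paste0("re_", seq_len(np)); im_cols <- paste0("im_", seq_len(np))
  if (!all(c(re_cols, im_cols) %in% names(d)))
    stop("set container is missing sample columns (re_*/im_*)")
  samples <- t(as.matrix(d[, re_cols, with = FALSE])) +
    1i * t(as.matrix(d[, im_cols, with = FALSE]))
  mrs_set(samples, axis, label = d$label, split = d$split,
          true_freq_hz = d$true_freq_hz, true_phase_deg = d$true_phase_deg,
          snr_nominal = d$snr_nominal)
}

#' Write an estimates table next to a corrected set
#'
#' @param estimates list of [shift_estimate()]s.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  data.table::fwrite(estimates_df(estimates), path)
  invisible(path)
}

#' Run a staged FPC pipeline from a config
#'
#' Stages (any contiguous subset, in this order): `simulate` ->
#' `reference` -> `train` -> `correct` -> `evaluate`.  The config is a
#' JSON file or an equivalent R list:
#'
#' ```
#' {
#'   "seed": 1,
#'   "out_dir": "runs/demo",
#'   "simulate": {"preset": "invivo", "n": 200},
#'   "reference": {},
#'   "train": {"variant": "dSR", "max_epochs": 5},
#'   "correct": {"method": "SR"},
#'   "evaluate": {}
#' }
#' ```
#'
#' `correct$method` may be a classical method (SR/SRF/Corr/CorrF/CrR) or
#' `"dae"` (requires the train stage).  Each stage writes its artifact
#' under `out_dir`; a `manifest.json` records the config, seeds, package
#' version and a config hash, so re-running the same config reproduces the
#' same manifest hash.
#'
#' @param config path to a JSON config or a named list.
#' @return list with the manifest and the in-memory artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$out_dir)) stop("config needs `out_dir`")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # fail fast on inconsistent stage combinations
  if (!is.null(config$train) &&
      config$train$variant %in% c("dSR", "dSRF") &&
      is.null(config$reference))
    stop("config error: variant ", config$train$variant,
         " requires a `reference` stage")
  if (!is.null(config$correct) && identical(config$correct$method, "dae") &&
      is.null(config$train))
    stop("config error: correct method `dae` requires a `train` stage")

  cfg_file <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = seed, config_hash = unname(tools::md5sum(cfg_file)),
                   package_version = as.character(utils::packageVersion("mrsfpc")),
                   stages = list())
  art <- list()
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      wall_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  if (!is.null(config$simulate)) {
    art$set <- run_stage("simulate", function() {
      sc <- config$simulate
      preset <- if (is.null(sc$preset)) "invivo" else sc$preset
      n <- if (is.null(sc$n)) 1000L else as.integer(sc$n)
      if (preset == "invivo") {
        cfg <- aug_config(n_signals = n, seed = seed)
        set <- make_simulated_set(make_basis_signal(), cfg)
      } else {
        cfg <- aug_config(snr_range = c(7, 70), seed = seed)
        set <- make_phantom_set(make_basis_signal(phantom_peak_table()),
                                n = n, cfg = cfg)
      }
      write_set(set, file.path(config$out_dir, "set"))
      set
    })
  }
  if (is.null(art$set)) stop("pipeline needs a simulate stage (or a set)")

  if (!is.null(config$reference)) {
    art$reference <- run_stage("reference", function() {
      sel <- select_reference(art$set, seed = seed)
      jsonlite::write_json(list(index = sel$index,
                                sizes = sel$diagnostics$cluster_sizes),
                           file.path(config$out_dir, "reference.json"),
                           auto_unbox = TRUE)
      sel
    })
  }

  if (!is.null(config$train)) {
    art$model <- run_stage("train", function() {
      tc <- config$train
      variant <- if (is.null(tc$variant)) "dCrR" else tc$variant
      cfg <- train_config(
        max_epochs = if (is.null(tc$max_epochs)) 150L else tc$max_epochs,
        seed = seed)
      tr <- set_subset(art$set, art$set$split == "train")
      va <- set_subset(art$set, art$set$split == "val")
      if (length(va) < 1) va <- tr
      ref <- if (!is.null(art$reference))
        set_transient(art$set, art$reference$index) else NULL
      train_dae(variant, tr, va, cfg, ref = ref)
    })
  }

  if (!is.null(config$correct)) {
    art$corrected <- run_stage("correct", function() {
      method <- config$correct$method
      test <- set_subset(art$set, art$set$split == "test")
      if (length(test) < 2) test <- art$set
      res <- if (identical(method, "dae")) dae_align_set(art$model, test)
        else align_set(test, method = method, seed = seed)
      res$uncorrected <- test
      write_set(res$set, file.path(config$out_dir, "corrected"))
      write_estimates(res$estimates,
                      file.path(config$out_dir, "estimates.csv"))
      res
    })
  }

  if (!is.null(config$evaluate)) {
    art$report <- run_stage("evaluate", function() {
      cr <- art$corrected
      ref_truth <- if (!is.na(cr$ref_index %||% NA)) {
        c(cr$uncorrected$true_freq_hz[cr$ref_index],
          cr$uncorrected$true_phase_deg[cr$ref_index])
      } else NULL
      rep <- evaluation_report(cr$uncorrected, cr$set, cr$estimates,
                               ref_truth = ref_truth)
      jsonlite::write_json(unclass(rep),
                           file.path(config$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    })
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  c(list(manifest = manifest), art)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
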