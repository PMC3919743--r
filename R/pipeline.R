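#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [run_pipeline()].
#' Serializes losslessly through JSON ([read_pipeline_config()] /
#' [write_pipeline_config()]); unknown keys are rejected.
#'
#' @param out_dir output directory (created if needed).
#' @param seed run seed; governs every stochastic stage.
#' @param phantom list of [mouse_phantom_spec()] arguments (`n`,
#'   `voxel_mm`, `noise_sd`, `bias_amplitude`), or `NULL` to load volumes
#'   from `inputs` instead.
#' @param inputs when no phantom stage: named list of scans
#'   (`day1`, `day3_pre`, `day3_post`), each `list(v40 =, v80 =)` NIfTI
#'   paths.
#' @param stages logical toggles: `filter`, `decompose`, `quantify`,
#'   `report`.
#' @param filter [filter_params()] arguments.
#' @param decompose list with `nonneg` mode, see [decompose()].
#' @param quantify [quantify_biomarkers()] arguments (`method`, `lo`,
#'   `hi`, `min_voxels`, `tumor_source`).
#' @param sensitivity path to a sensitivity-matrix JSON, or `NULL` for
#'   [reference_sensitivity_matrix()].
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, phantom = list(),
                            inputs = NULL,
                            stages = list(), filter = list(),
                            decompose = list(), quantify = list(),
                            sensitivity = NULL) {
  defaults <- list(
    stages = list(filter = TRUE, decompose = TRUE, quantify = TRUE,
                  report = TRUE),
    filter = list(sigma_s = 2, sigma_r = 60, radius = 3, passes = 1),
    decompose = list(nonneg = "clamp"),
    quantify = list(method = "both", lo = 0.25, hi = 3, min_voxels = 4,
                    tumor_source = "segment"),
    phantom = list(n = 64, voxel_mm = 0.088, noise_sd = 20,
                   bias_amplitude = 0))
  merge1 <- function(name, user) {
    if (is.null(user)) return(NULL)
    user <- as.list(user)
    def <- defaults[[name]]
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      stop(sprintf("unknown %s config key(s): %s", name,
                   paste(bad, collapse = ", ")), call. = FALSE)
    utils::modifyList(def, user)
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              phantom = merge1("phantom", phantom),
              inputs = inputs,
              stages = merge1("stages", if (length(stages)) stages
                              else list()),
              filter = merge1("filter", filter),
              decompose = merge1("decompose", decompose),
              quantify = merge1("quantify", quantify),
              sensitivity = sensitivity)
  if (is.null(cfg$phantom) && is.null(cfg$inputs))
    stop("config needs either a phantom block or an inputs block",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @param path JSON config path.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file does not exist: %s", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("out_dir", "seed", "phantom", "inputs", "stages", "filter",
             "decompose", "quantify", "sensitivity")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(pipeline_config, x)
}

#' @param config a `pipeline_config`.
#' @rdname pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

scan_needs <- function(method) {
  switch(method,
         single = c("day1", "day3_pre"),
         two = "day3_post",
         both = c("day1", "day3_pre", "day3_post"))
}

#' Run the end-to-end pipeline
#'
#' Executes the configured stages in order — phantom-or-load, joint
#' bilateral filtration, dual-energy decomposition, biomarker
#' quantification, summary report — and writes a run manifest
#' (`manifest.json`) recording the package version, seed, config checksum
#' and every per-stage output path. Deterministic: identical config + seed
#' reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  manifest <- list(package = "demict",
                   version = as.character(utils::packageVersion("demict")),
                   seed = config$seed, stages = list(), warnings = list())
  cfg_path <- file.path(config$out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  manifest$config <- cfg_path
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  m <- stage("calibrate", {
    if (is.null(config$sensitivity)) reference_sensitivity_matrix()
    else read_sensitivity_json(config$sensitivity)
  })
  method <- config$quantify$method %||% "both"
  scans_needed <- scan_needs(method)
  labels <- NULL
  pairs <- list()

  if (!is.null(config$phantom)) {
    out <- stage("phantom", {
      p <- config$phantom
      spec <- mouse_phantom_spec(n = p$n, voxel_mm = p$voxel_mm,
                                 noise_sd = p$noise_sd, seed = config$seed,
                                 misregistration = p$misregistration,
                                 bias_amplitude = p$bias_amplitude)
      ph <- build_phantom(spec, scans_needed, m)
      paths <- character()
      for (tp in scans_needed) {
        for (e in c("v40", "v80")) {
          f <- file.path(config$out_dir, sprintf("%s_%s.nii.gz", tp, e))
          write_volume(ph$scans[[tp]][[e]], f)
          paths <- c(paths, f)
        }
        for (mt in c("iodine", "gold")) {
          f <- file.path(config$out_dir,
                         sprintf("truth_%s_%s.nii.gz", tp, mt))
          write_volume(ph$scans[[tp]]$truth[[mt]], f)
          paths <- c(paths, f)
        }
      }
      f <- file.path(config$out_dir, "labels.nii.gz")
      write_volume(ph$labels, f, dtype = "int16")
      tf <- file.path(config$out_dir, "truth_biomarkers.csv")
      write_biomarkers_csv(ph$truth_biomarkers, tf)
      list(ph = ph, paths = c(paths, f, tf))
    })
    manifest$stages$phantom <- out$paths
    labels <- out$ph$labels
    for (tp in scans_needed)
      pairs[[tp]] <- out$ph$scans[[tp]][c("v40", "v80")]
  } else {
    loaded <- stage("load", {
      prs <- list()
      for (tp in scans_needed) {
        paths <- config$inputs[[tp]]
        if (is.null(paths))
          stop(sprintf("inputs for scan '%s' missing", tp))
        for (p in unlist(paths)) if (!file.exists(p))
          stop(sprintf("input path does not exist: %s", p))
        prs[[tp]] <- read_volume_pair(paths$v40, paths$v80)
      }
      lab <- NULL
      if (!is.null(config$inputs$labels)) {
        lab <- read_volume(config$inputs$labels)
        storage.mode(lab) <- "integer"
      }
      list(pairs = prs, labels = lab)
    })
    pairs <- loaded$pairs
    labels <- loaded$labels
  }

  if (isTRUE(config$stages$filter)) {
    fp <- do.call(filter_params, config$filter)
    paths <- character()
    for (tp in names(pairs)) {
      pairs[[tp]] <- stage("filter",
                           joint_bilateral_filter(pairs[[tp]]$v40,
                                                  pairs[[tp]]$v80, fp))
      for (e in c("v40", "v80")) {
        f <- file.path(config$out_dir,
                       sprintf("%s_%s_filtered.nii.gz", tp, e))
        write_volume(pairs[[tp]][[e]], f)
        paths <- c(paths, f)
      }
    }
    manifest$stages$filter <- paths
  }

  maps <- list()
  if (isTRUE(config$stages$decompose)) {
    paths <- character()
    clamped <- list()
    for (tp in names(pairs)) {
      dec <- stage("decompose",
                   decompose(pairs[[tp]]$v40, pairs[[tp]]$v80, m,
                             nonneg = config$decompose$nonneg))
      maps[[tp]] <- dec[c("iodine", "gold")]
      clamped[[tp]] <- dec$n_clamped
      for (mt in c("iodine", "gold")) {
        f <- file.path(config$out_dir, sprintf("%s_%s.nii.gz", tp, mt))
        write_volume(dec[[mt]], f)
        paths <- c(paths, f)
      }
    }
    manifest$stages$decompose <- paths
    manifest$warnings$n_clamped_negative_voxels <- clamped
  }

  if (isTRUE(config$stages$quantify)) {
    if (is.null(labels))
      stop("pipeline stage 'quantify' failed: no label volume available",
           call. = FALSE)
    q <- config$quantify
    rec <- stage("quantify", quantify_biomarkers(
      labels, day1 = maps$day1, day3_pre = maps$day3_pre,
      day3_post = maps$day3_post, method = q$method,
      tumor_source = q$tumor_source, lo = q$lo, hi = q$hi,
      min_voxels = q$min_voxels))
    f <- file.path(config$out_dir, "biomarkers.csv")
    write_biomarkers_csv(rec, f)
    manifest$stages$quantify <- f
  }

  if (isTRUE(config$stages$report) && isTRUE(config$stages$quantify)) {
    rec <- read_biomarkers_csv(file.path(config$out_dir, "biomarkers.csv"))
    f <- file.path(config$out_dir, "summary.csv")
    stage("report", {
      agg <- do.call(rbind, lapply(
        split(rec, list(rec$roi, rec$method), drop = TRUE),
        function(g) data.frame(roi = g$roi[1], method = g$method[1],
                               n = nrow(g),
                               fbv_mean = mean(g$fbv), fbv_sd = sd(g$fbv),
                               c_au_accum_mean = mean(g$c_au_accum),
                               c_au_accum_sd = sd(g$c_au_accum))))
      rownames(agg) <- NULL
      write.csv(agg, f, row.names = FALSE, fileEncoding = "UTF-8")
    })
    manifest$stages$report <- f
  }

  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
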