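# Config-driven end-to-end pipeline: per-patient quantification (fuse ->
# resample -> muscle mask -> SUVpeak -> threshold -> segment -> PVC -> sum),
# cohort table assembly and the statistical report, with provenance
# sidecars. The YAML config is the reproducible stand-in for every manual
# step of the original procedure (VOI placement, rigid adjustment).

#' Default method parameters
#'
#' @return Named list: `hu_window` (c(0, 250)), `sphere_volume_ml` (1),
#'   `min_component_ml` (1), `threshold_rule` ("mean"), `pvc_fwhm_mm` (6),
#'   `connectivity` (26), `strict_min` (FALSE).
#' @export
default_parameters <- function() {
  list(hu_window = c(0, 250), sphere_volume_ml = 1.0, min_component_ml = 1.0,
       threshold_rule = "mean", pvc_fwhm_mm = 6, connectivity = 26L,
       strict_min = FALSE)
}

merge_parameters <- function(params) {
  p <- default_parameters()
  for (nm in names(params)) p[[nm]] <- params[[nm]]
  if (!p$threshold_rule %in% c("mean", "max", "per_side"))
    stop_gq("unknown threshold_rule '%s'", p$threshold_rule,
            class = "gq_config_error")
  p
}

#' Read and validate a YAML run config
#'
#' @param path Path to the YAML config (see the package vignette for the
#'   schema: global `seed`, `parameters`, `patients` with image paths,
#'   calibration, VOIs and manual rigid adjustment, optional `cohort_csv`).
#' @return The config as a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_gq("config not found: %s", path, class = "gq_io_error")
  cfg <- yaml::read_yaml(path)
  cfg$parameters <- merge_parameters(cfg$parameters %||% list())
  cfg$seed <- cfg$seed %||% 1L
  for (pt in cfg$patients) {
    for (f in c("pet", "ct")) {
      if (!is.null(pt[[f]]) && !file.exists(pt[[f]]))
        stop_gq("patient %s: missing file %s", pt$id %||% "?", pt[[f]],
                class = "gq_config_error")
    }
  }
  cfg
}

voi_from_config <- function(v) {
  cylinder_voi(v$label, unlist(v$center), unlist(v$axis %||% c(0, 0, 1)),
               v$radius_mm, v$height_mm, v$level %||% 1L)
}

transform_from_config <- function(a) {
  if (is.null(a)) return(rigid_transform())
  rigid_transform(unlist(a$rotations_deg %||% c(0, 0, 0)),
                  unlist(a$translations_mm %||% c(0, 0, 0)),
                  unlist(a$center_mm %||% c(0, 0, 0)))
}

calibration_from_config <- function(cl) {
  suv_calibration(cl$injected_dose_mbq, cl$injection_time %||% 0,
                  cl$scan_time %||% 90, cl$body_weight_kg,
                  cl$half_life_min %||% 110)
}

# expand VOI config entries: entries with mirror: true also produce the
# mirrored counterpart across the patient's mid-sagittal plane
expand_vois <- function(voi_cfgs, sagittal_plane_x) {
  out <- list()
  for (v in voi_cfgs) {
    voi <- voi_from_config(v)
    out[[length(out) + 1L]] <- voi
    if (isTRUE(v$mirror)) {
      if (is.null(sagittal_plane_x))
        stop_gq("mirror: true requires sagittal_plane_x",
                class = "gq_config_error")
      out[[length(out) + 1L]] <- mirror_voi(voi, sagittal_plane_x)
    }
  }
  out
}

#' Quantify one patient
#'
#' Executes the full per-patient procedure: PET-to-SUV conversion,
#' header-based PET/CT fusion refined by the configured manual adjustment,
#' resampling of the PET onto the CT grid, HU-windowed muscle masking,
#' muscle SUVpeak, graft threshold segmentation with component filtering,
#' partial volume correction, and summation over levels and sides.
#'
#' @param entry One element of the config's `patients` list. Must carry
#'   either file paths (`pet`, `ct`) or in-memory volumes (`pet_volume`,
#'   `ct_volume`), a `calibration` block, a `vois` list and optionally an
#'   `adjustment` block and `sagittal_plane_x`.
#' @param parameters Method parameters (see [default_parameters()]).
#' @param output_dir If non-`NULL`, per-VOI metrics CSV, graft label map
#'   NIfTI and a JSON provenance sidecar are written there.
#' @return A list: `metrics` (data frame, one row per VOI plus a `total`
#'   row), `segs` (named graft segmentation results), `threshold`,
#'   `provenance`.
#' @export
run_patient <- function(entry, parameters = default_parameters(),
                        output_dir = NULL) {
  p <- merge_parameters(parameters)
  id <- entry$id %||% "patient"
  pet <- entry$pet_volume %||% read_volume(entry$pet, "PET_BQML")
  ct <- entry$ct_volume %||% read_volume(entry$ct, "CT_HU")
  cal <- if (inherits(entry$calibration, "suv_calibration")) entry$calibration
         else calibration_from_config(entry$calibration)
  suv <- to_suv(pet, cal)
  fusion <- fuse_from_metadata(suv, ct)
  fusion <- refine_rigid(fusion, if (inherits(entry$adjustment,
                                              "rigid_transform"))
    entry$adjustment else transform_from_config(entry$adjustment))
  suv_ct <- resample_to_grid(suv, fusion, ct, interpolation = "trilinear")

  vois <- if (all(vapply(entry$vois, inherits, logical(1), "cylinder_voi")))
    entry$vois else expand_vois(entry$vois, entry$sagittal_plane_x)
  labels <- vapply(vois, `[[`, character(1), "label")
  muscle <- vois[grepl("^muscle", labels)]
  graft <- vois[grepl("^graft", labels)]
  if (length(muscle) == 0L || length(graft) == 0L)
    stop_gq("patient %s: need at least one muscle and one graft VOI", id,
            class = "gq_config_error")

  win <- hu_window(p$hu_window[1L], p$hu_window[2L])
  peaks <- list()
  metrics <- list()
  for (mv in muscle) {
    mmask <- hu_mask(ct, rasterize_voi(mv, ct), win)
    pk <- suv_peak(suv_ct, mmask, p$sphere_volume_ml)
    side <- sub(".*_", "", mv$label)
    peaks[[side]] <- max(as.numeric(pk), peaks[[side]] %||% -Inf)
    metrics[[length(metrics) + 1L]] <- data.frame(
      id = id, voi = mv$label, level = mv$level, role = "muscle",
      volume_ml = sum(mmask) * voxel_volume_ml(ct),
      suv_mean = mean(suv_ct$voxels[mmask]), suv_max = max(suv_ct$voxels[mmask]),
      suv_peak = as.numeric(pk), suv_total = NA_real_, c_suv_total = NA_real_)
  }
  thr <- graft_threshold(peaks$L, peaks$R, p$threshold_rule)

  graft_masks <- lapply(graft, rasterize_voi, grid = ct)
  segs <- list()
  for (i in seq_along(graft)) {
    gv <- graft[[i]]
    side <- sub(".*_", "", gv$label)
    thr_i <- if (length(thr) > 1L) thr[[side]] else thr
    seg <- threshold_segment(suv_ct, graft_masks[[i]], thr_i,
                             min_component_ml = p$min_component_ml,
                             connectivity = p$connectivity,
                             strict_min = p$strict_min,
                             sphere_volume_ml = p$sphere_volume_ml)
    others <- Reduce(`|`, lapply(segs, `[[`, "mask"),
                     array(FALSE, dim(ct$voxels)))
    seg <- pvc_correct(seg, suv_ct, p$pvc_fwhm_mm, exclude_mask = others)
    segs[[paste0(gv$label, "_lvl", gv$level)]] <- seg
    metrics[[length(metrics) + 1L]] <- data.frame(
      id = id, voi = gv$label, level = gv$level, role = "graft",
      volume_ml = seg$volume_ml, suv_mean = seg$suv_mean,
      suv_max = seg$suv_max, suv_peak = seg$suv_peak,
      suv_total = seg$suv_total, c_suv_total = seg$c_suv_total)
  }
  total <- patient_graft_uptake(segs)
  metrics[[length(metrics) + 1L]] <- data.frame(
    id = id, voi = "total", level = NA_integer_, role = "total",
    volume_ml = sum(vapply(segs, `[[`, numeric(1), "volume_ml")),
    suv_mean = NA_real_, suv_max = NA_real_, suv_peak = NA_real_,
    suv_total = total$suv_total, c_suv_total = total$c_suv_total)
  metrics <- do.call(rbind, metrics)
  prov <- list(id = id, package_version = as.character(
    utils::packageVersion("graftquant")),
    parameters = p, threshold = unclass(thr),
    muscle_peaks = peaks,
    flags = unlist(lapply(segs, `[[`, "flags")) %||% character(0))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(output_dir, paste0(id, "_metrics.csv")),
              row.names = FALSE)
    labmap <- array(0L, dim(ct$voxels))
    for (i in seq_along(segs)) labmap[segs[[i]]$mask] <- i
    write_volume(image_volume(labmap, ct$spacing, ct$origin, ct$orientation,
                              "PET_SUV"),
                 file.path(output_dir, paste0(id, "_graft_labels.nii.gz")))
    jsonlite::write_json(prov, file.path(output_dir, paste0(id, "_provenance.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(metrics = metrics, segs = segs, threshold = thr, provenance = prov)
}

#' Run the statistics stage over a cohort table
#'
#' Computes the descriptive report ([describe_cohort()]) and the Spearman
#' correlations of each uptake metric with the one-year change of every
#' clinical score present.
#'
#' @param cohort Cohort data frame or path to a cohort CSV.
#' @param uptake_metrics Uptake columns to correlate (default both totals).
#' @param output_dir If non-`NULL`, writes `report.csv`, `report.txt` and
#'   `spearman.csv` there.
#' @return A list: `report` (a [describe_cohort()] table) and `spearman`
#'   (data frame: metric, variable, rho, p, n).
#' @export
run_cohort <- function(cohort, uptake_metrics = c("suv_total", "c_suv_total"),
                       output_dir = NULL) {
  if (is.character(cohort)) {
    if (!file.exists(cohort))
      stop_gq("cohort CSV not found: %s", cohort, class = "gq_io_error")
    cohort <- read.csv(cohort, stringsAsFactors = FALSE)
  }
  if (nrow(cohort) == 0L)
    stop_gq("no usable records", class = "gq_argument_error")
  cohort$fused <- as.logical(cohort$fused)
  report <- describe_cohort(cohort)
  score_vars <- c("wlk_d", "vas_b", "vas_l", "tan", "odi", "eq5d")
  score_vars <- score_vars[vapply(score_vars, function(v)
    !is.null(cohort[[paste0(v, "_bs")]]), logical(1))]
  uptake_metrics <- intersect(uptake_metrics, names(cohort))
  sp <- list()
  for (m in uptake_metrics) for (v in score_vars) {
    res <- tryCatch(spearman_uptake_vs_change(cohort, m, v),
                    graftquant_error = function(e)
                      list(rho = NA_real_, p = NA_real_, n = NA_integer_))
    sp[[length(sp) + 1L]] <- data.frame(uptake_metric = m, variable = v,
                                        rho = res$rho, p = res$p, n = res$n)
  }
  spearman <- do.call(rbind, sp)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(report), file.path(output_dir, "report.csv"),
              row.names = FALSE)
    writeLines(format_cohort_report(report), file.path(output_dir, "report.txt"))
    write.csv(spearman, file.path(output_dir, "spearman.csv"),
              row.names = FALSE)
  }
  list(report = report, spearman = spearman)
}

#' Run a full config: all patients, then the cohort statistics
#'
#' Patients failing at any stage are recorded with the failure reason and
#' skipped; the pipeline continues. The return value carries `n_failed` so
#' callers (e.g. the command-line wrapper) can exit non-zero.
#'
#' @param config A config list ([read_run_config()]) or a path to a YAML
#'   config.
#' @param output_dir Output directory (defaults to `config$output_dir` or
#'   `"."`).
#' @return A list: `patients` (per-patient results), `failed` (data frame of
#'   failures), `cohort` (merged table), `stats`, `n_failed`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config$parameters <- merge_parameters(config$parameters %||% list())
  output_dir <- output_dir %||% config$output_dir %||% "."
  set.seed(config$seed %||% 1L)
  results <- list()
  failed <- data.frame(id = character(0), reason = character(0))
  rows <- list()
  for (entry in config$patients %||% list()) {
    id <- entry$id %||% sprintf("patient%02d", length(results) + 1L)
    res <- tryCatch(
      run_patient(entry, config$parameters, output_dir = output_dir),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("patient ", id, " failed: ", conditionMessage(res))
      failed <- rbind(failed, data.frame(id = id,
                                         reason = conditionMessage(res)))
      next
    }
    results[[id]] <- res
    tot <- res$metrics[res$metrics$role == "total", ]
    rows[[id]] <- data.frame(id = id, suv_total = tot$suv_total,
                             c_suv_total = tot$c_suv_total)
  }
  imaging <- if (length(rows)) do.call(rbind, rows) else NULL
  cohort <- NULL
  if (!is.null(config$cohort_csv)) {
    cohort <- read.csv(config$cohort_csv, stringsAsFactors = FALSE)
    if (!is.null(imaging)) {
      cohort$suv_total <- NULL; cohort$c_suv_total <- NULL
      cohort <- merge(cohort, imaging, by = "id", all.x = TRUE)
    }
  } else if (!is.null(imaging)) cohort <- imaging
  stats <- NULL
  if (!is.null(cohort) && !is.null(cohort$fused))
    stats <- run_cohort(cohort, output_dir = output_dir)
  list(patients = results, failed = failed, cohort = cohort, stats = stats,
       n_failed = nrow(failed))
}

#' Build a ready-to-run patient entry from the default phantom
#'
#' Convenience for demos and end-to-end tests: generates the default
#' bilateral-graft phantom and pairs it with matching muscle and graft VOIs
#' (muscle VOIs coincide with the phantom's muscle cylinders; graft VOIs are
#' 20 cm3 cylinders over the graft beds).
#'
#' @param id Patient id string.
#' @param ... Passed to [default_phantom_spec()] (e.g. `noise_scale`,
#'   `seed`, `misalignment`).
#' @return A list with the patient `entry` (usable in [run_patient()]) and
#'   the phantom `truth`.
#' @export
phantom_patient <- function(id = "phantom01", ...) {
  ph <- generate_phantom(default_phantom_spec(...))
  mid_x <- 79
  vois <- list(
    cylinder_voi("muscle_L", c(mid_x + 30, 78, 85), c(0, 0, 1), 10, 63.662),
    cylinder_voi("muscle_R", c(mid_x - 30, 78, 85), c(0, 0, 1), 10, 63.662),
    cylinder_voi("graft_L", c(mid_x + 32, 75, 30), c(0, 0, 1), 14, 32.5),
    cylinder_voi("graft_R", c(mid_x - 32, 75, 30), c(0, 0, 1), 14, 32.5))
  entry <- list(id = id, pet_volume = ph$pet, ct_volume = ph$ct,
                calibration = ph$calibration, vois = vois,
                sagittal_plane_x = mid_x)
  list(entry = entry, truth = ph$truth, phantom = ph)
}
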