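#' Read / write an analysis mode file
#'
#' Analysis modes (material type, per-material wand calibrations, seeds and
#' slice range) are stored as YAML so calibrations are reusable and auditable
#' across samples.
#'
#' @param path YAML file path.
#' @return `read_analysis_mode` returns an [analysis_mode()].
#' @export
read_analysis_mode <- function(path) {
  lst <- yaml::read_yaml(path)
  targets <- lapply(lst$targets, function(t) {
    list(material = t$material,
         calibration = segmentation_calibration(
           intensity_range(t$core_range[1], t$core_range[2]),
           if (!is.null(t$border_range)) {
             intensity_range(t$border_range[1], t$border_range[2])
           },
           if (is.null(t$border_layers)) 1L else t$border_layers),
         seed = as.integer(t$seed))
  })
  slices <- if (!is.null(lst$slices)) lst$slices[1]:lst$slices[2]
  analysis_mode(lst$material_type, targets, slices = slices,
                method = if (is.null(lst$method)) "wand" else lst$method)
}

#' @rdname read_analysis_mode
#' @param mode an [analysis_mode()].
#' @export
write_analysis_mode <- function(mode, path) {
  stopifnot(inherits(mode, "analysis_mode"))
  lst <- list(
    material_type = mode$material_type,
    method = mode$method,
    slices = if (!is.null(mode$slices)) range(mode$slices),
    targets = lapply(mode$targets, function(t) {
      list(material = t$material,
           core_range = c(t$calibration$core_range$lo, t$calibration$core_range$hi),
           border_range = if (!is.null(t$calibration$border_range)) {
             c(t$calibration$border_range$lo, t$calibration$border_range$hi)
           },
           border_layers = t$calibration$border_layers,
           seed = unname(t$seed))
    })
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Analyze one graft sample end to end
#'
#' Dispatches on the sample's material type:
#' \describe{
#'   \item{PVA}{the bright lumen is segmented directly; luminal metrics are
#'     reported.}
#'   \item{ePTFE}{the bright thrombus is segmented; luminal volume comes from
#'     the caliper-based cylindrical subtraction (a caliper record is
#'     required), normalized by the measured length.}
#'   \item{collagen_ePTFE}{lumen and thrombus are both measured via the
#'     sequential four-material labeling; when a caliper record is present the
#'     per-slice lumen + thrombus conservation residuals are reported.}
#' }
#'
#' @param image a [voxel_image()] (or path readable by [read_volume()]).
#' @param mode an [analysis_mode()] (or YAML path).
#' @param caliper optional [caliper_record()].
#' @param sample_id identifier used in logs and file names.
#' @param output_dir if non-`NULL`, per-sample artifacts (profiles CSV,
#'   metrics JSON, QC CSV) are written there.
#' @param group treatment/material group label, used only for study-level
#'   aggregation; omitted from per-sample logs when `blinded`.
#' @param blinded hide `group` from the per-sample QC log (the analysis itself
#'   never uses it).
#' @return list of class `sample_result`: `sample_id`, `metrics` (named list
#'   of [graft_metrics()]), `profiles` (named list of [slice_profile()]),
#'   `conservation` (or `NULL`), `qc`, `flagged_slices`, `group`.
#' @export
run_sample <- function(image, mode, caliper = NULL, sample_id = "sample",
                       output_dir = NULL, group = NULL, blinded = FALSE) {
  if (is.character(image)) image <- read_volume(image)
  if (is.character(mode)) mode <- read_analysis_mode(mode)
  stopifnot(inherits(image, "voxel_image"), inherits(mode, "analysis_mode"))

  metrics <- list(); profiles <- list(); conservation <- NULL
  flagged <- integer(0)

  if (mode$material_type == "collagen_ePTFE") {
    seg <- segment_four_material(image, mode)
    metrics$lumen <- graft_metrics(seg$labels, "lumen")
    metrics$thrombus <- graft_metrics(seg$labels, "thrombus")
    profiles$lumen <- area_per_slice(seg$labels, "lumen")
    profiles$thrombus <- area_per_slice(seg$labels, "thrombus")
    if (!is.null(caliper)) {
      conservation <- conservation_residuals(profiles$lumen, profiles$thrombus,
                                             caliper)
    }
    qc <- seg$qc
    flagged <- seg$flagged_slices
  } else {
    tg <- mode$targets[[1]]
    seg <- segment_target(image, tg$calibration, tg$seed[2:3],
                          slices = if (is.null(mode$slices)) tg$seed[1]:dim(image$data)[1] else mode$slices,
                          method = mode$method)
    labels <- as_label_volume(seg, image, tg$material)
    metrics[[tg$material]] <- graft_metrics(labels, tg$material)
    profiles[[tg$material]] <- area_per_slice(labels, tg$material)
    qc <- seg$qc
    if (mode$material_type == "ePTFE") {
      if (is.null(caliper)) {
        stop(sprintf("sample '%s': ePTFE mode requires a caliper record for the subtraction lumen",
                     sample_id), call. = FALSE)
      }
      vt <- metrics$thrombus$volume
      lt <- metrics$thrombus$length
      vl <- lumen_from_subtraction(caliper, lt, vt)
      metrics$lumen <- structure(
        list(material = "lumen", volume = vl, length = lt,
             average_area = average_area(vl, lt),
             area_mean = NA_real_, area_sd = NA_real_,
             first_slice = metrics$thrombus$first_slice,
             last_slice = metrics$thrombus$last_slice),
        class = "graft_metrics")
    }
  }

  res <- structure(list(sample_id = sample_id, metrics = metrics,
                        profiles = profiles, conservation = conservation,
                        qc = qc, flagged_slices = flagged,
                        group = group),
                   class = "sample_result")
  if (!is.null(output_dir)) .write_sample_artifacts(res, output_dir, blinded)
  res
}

.write_sample_artifacts <- function(res, output_dir, blinded) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(output_dir, res$sample_id)
  for (m in names(res$profiles)) {
    write_profile_csv(res$profiles[[m]], paste0(base, "_", m, "_areas.csv"))
  }
  meta <- lapply(res$metrics, unclass)
  if (!blinded && !is.null(res$group)) meta$group <- res$group
  if (!is.null(res$conservation)) {
    meta$conservation <- list(max_abs_residual_mm2 = res$conservation$max_abs,
                              mean_residual_mm2 = res$conservation$mean,
                              expected_area_mm2 = res$conservation$expected_area)
  }
  jsonlite::write_json(meta, paste0(base, "_metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(res$qc, paste0(base, "_qc.csv"), row.names = FALSE)
  invisible(res)
}

#' Read per-sample caliper records from CSV
#'
#' Columns: `sample_id`, `length`, `outer_diameter`, `inner_diameter` and
#' optionally `wall_thickness` (mm).
#'
#' @param path CSV path.
#' @return named list of [caliper_record()] keyed by sample id.
#' @export
read_caliper_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "length", "outer_diameter", "inner_diameter")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("caliper table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    if (!is.null(df$wall_thickness)) {
      caliper_record(df$length[i], df$outer_diameter[i], df$inner_diameter[i],
                     df$wall_thickness[i])
    } else {
      caliper_record(df$length[i], df$outer_diameter[i], df$inner_diameter[i])
    }
  })
  names(out) <- df$sample_id
  out
}

#' Run a whole study from a config
#'
#' The study config (YAML file or equivalent list) names the samples (volume
#' path, analysis-mode path, optional group label and caliper reference), an
#' optional caliper CSV and an optional platelet/fibrin accumulation CSV.
#' Every sample is analyzed with [run_sample()]; per-sample metrics are
#' aggregated, and when the inputs allow it the study-level validations are
#' run: the through-origin fit of measured length against caliper length, and
#' the per-group correlation table of luminal area against the accumulation
#' endpoints. The report is deterministic given the inputs. Failing samples
#' are recorded and do not abort the remaining samples.
#'
#' @param config path to a YAML study config, or a list with elements
#'   `samples` (list of `id`, `volume`, `mode`, optional `group`), optional
#'   `caliper_csv`, `accumulation_csv`, `output_dir`, `blinding`.
#' @return list of class `study_report`: `metrics` (data frame), `group_counts`,
#'   `total_samples`, `length_validation` (`fit_result` or `NULL`),
#'   `correlations` (data frame or `NULL`), `conservation` (data frame or
#'   `NULL`), `failed` (named character vector of errors).
#' @export
run_study <- function(config) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
    rel <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
    config$samples <- lapply(config$samples, function(s) {
      s$volume <- rel(s$volume); s$mode <- rel(s$mode); s
    })
    if (!is.null(config$caliper_csv)) config$caliper_csv <- rel(config$caliper_csv)
    if (!is.null(config$accumulation_csv)) config$accumulation_csv <- rel(config$accumulation_csv)
  }
  if (!length(config$samples)) stop("study config names no samples", call. = FALSE)
  blinding <- isTRUE(config$blinding)
  calipers <- if (!is.null(config$caliper_csv)) read_caliper_csv(config$caliper_csv)

  rows <- list(); cons <- list(); failed <- character(0)
  measured_len <- c(); caliper_len <- c()
  results <- list()
  for (s in config$samples) {
    cal <- if (!is.null(calipers) && s$id %in% names(calipers)) calipers[[s$id]]
    res <- tryCatch(
      run_sample(s$volume, s$mode, caliper = cal, sample_id = s$id,
                 output_dir = config$output_dir, group = s$group,
                 blinded = blinding),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[s$id] <- conditionMessage(res)
      next
    }
    results[[s$id]] <- res
    for (m in names(res$metrics)) {
      rows[[length(rows) + 1L]] <- cbind(sample_id = s$id,
                                         group = if (is.null(s$group)) NA_character_ else s$group,
                                         as.data.frame(res$metrics[[m]]))
    }
    if (!is.null(res$conservation)) {
      cons[[length(cons) + 1L]] <- data.frame(
        sample_id = s$id, max_abs_residual_mm2 = res$conservation$max_abs,
        mean_residual_mm2 = res$conservation$mean)
    }
    if (!is.null(cal)) {
      primary <- if (!is.null(res$metrics$lumen) && !is.na(res$metrics$lumen$length)) {
        res$metrics$lumen
      } else {
        res$metrics[[1]]
      }
      measured_len <- c(measured_len, primary$length)
      caliper_len <- c(caliper_len, cal$length)
    }
  }

  metrics_df <- if (length(rows)) do.call(rbind, rows)
  length_fit <- if (length(measured_len) >= 2L) {
    fit_through_origin(caliper_len, measured_len)
  }
  correlations <- if (!is.null(config$accumulation_csv)) {
    correlation_table(read_accumulation_csv(config$accumulation_csv))
  }
  counts <- if (!is.null(metrics_df)) {
    tab <- table(unique(metrics_df[c("sample_id", "group")])$group, useNA = "ifany")
    stats::setNames(as.integer(tab), names(tab))
  }

  report <- structure(list(metrics = metrics_df, group_counts = counts,
                           total_samples = length(results),
                           length_validation = length_fit,
                           correlations = correlations,
                           conservation = if (length(cons)) do.call(rbind, cons),
                           failed = failed, results = results),
                      class = "study_report")
  if (!is.null(config$output_dir)) .write_study_report(report, config$output_dir)
  if (length(failed)) {
    warning(sprintf("%d sample(s) failed: %s", length(failed),
                    paste(names(failed), collapse = ", ")), call. = FALSE)
  }
  report
}

.write_study_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$metrics)) {
    utils::write.csv(report$metrics, file.path(output_dir, "study_metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations,
                     file.path(output_dir, "study_correlations.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    total_samples = report$total_samples,
    group_counts = as.list(report$group_counts),
    length_validation = if (!is.null(report$length_validation)) {
      unclass(report$length_validation)
    },
    conservation = report$conservation,
    failed = as.list(report$failed)
  )
  jsonlite::write_json(summary, file.path(output_dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d samples analyzed", x$total_samples))
  if (length(x$failed)) cat(sprintf(" (%d failed)", length(x$failed)))
  cat("\n")
  if (!is.null(x$group_counts)) {
    cat("  groups:", paste(sprintf("%s=%d", names(x$group_counts), x$group_counts),
                           collapse = ", "), "\n")
  }
  if (!is.null(x$length_validation)) {
    cat(sprintf("  length validation: slope %.6g, R^2 %.4g\n",
                x$length_validation$slope, x$length_validation$r_squared))
  }
  invisible(x)
}
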