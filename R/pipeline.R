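# End-to-end orchestration: register -> QC -> clip -> volumetrics -> cheek
# metric for one patient, and cohort-level aggregation.

#' Pipeline configuration
#'
#' @param grid_mm volumetric sampling grid in mm (default 0.4, the CBCT
#'   voxel size the surface models derive from).
#' @param icp list of ICP settings: `max_iter`, `tol_mm`, `sample`.
#' @param qc_rms_threshold_mm registration certification threshold in mm
#'   (default 0.5).
#' @param norm normative cheek-mass summary: list with `mean`, `sd`, `n`.
#' @return object of class `run_config`.
#' @export
run_config <- function(grid_mm = 0.4,
                       icp = list(max_iter = 100, tol_mm = 1e-4, sample = 1000),
                       qc_rms_threshold_mm = 0.5,
                       norm = list(mean = 2.145, sd = 1.201, n = 60)) {
  stopifnot(grid_mm > 0)
  structure(list(grid_mm = grid_mm, icp = icp,
                 qc_rms_threshold_mm = qc_rms_threshold_mm, norm = norm),
            class = "run_config")
}

#' Precompute the pre-operative context of a patient
#'
#' Builds the reference frame, plane set, pre-operative ROI patches (both
#' sides, both tissues) and the pre-operative rotational angle, so that the
#' pre-operative work can be shared when one pre-operative model is
#' measured against several post-operative models.
#'
#' @param pre list with `bone`, `soft` ([surface_mesh()]s) and `landmarks`
#'   (a [landmark_set()]).
#' @param config a [run_config()].
#' @return list used by [run_patient()]'s `pre_ctx` argument.
#' @export
prepare_patient <- function(pre, config = run_config()) {
  frame <- build_reference_frame(pre$landmarks)
  planes <- construct_planes(frame, pre$landmarks)
  patches <- list()
  for (side in c("L", "R")) {
    patches[[paste0("bone_", side)]] <- clip_mesh_to_roi(pre$bone, planes, side)
    patches[[paste0("soft_", side)]] <- clip_mesh_to_roi(pre$soft, planes, side)
  }
  list(
    frame = frame, planes = planes, patches = patches,
    rotation_pre = maxillary_rotation_angle(frame, pre$landmarks)
  )
}

#' Measure one patient (registration, volumetrics, cheek metric)
#'
#' Runs the full measurement chain for one pre/post model pair: landmark-
#' initialised best-fit registration of the post-operative bone over the
#' non-operated regions, RMS certification, ROI clipping and volumetric
#' subtraction per side and tissue, rotational change, and the
#' post-operative cheek-mass position per side. A registration RMS above
#' the threshold flags the patient (`qc$pass = FALSE`) without aborting;
#' an error in any stage returns a result with `status = "failed"` and the
#' stage name.
#'
#' @param pre,post lists with `bone`, `soft` and `landmarks` (post-op
#'   models in their own scanner space; they are registered into the
#'   pre-op space here).
#' @param config a [run_config()].
#' @param pre_ctx optional precomputed [prepare_patient()] context.
#' @return object of class `patient_result`: `status` ("ok"/"failed"),
#'   `failed_stage` (or `NULL`), `qc` (rms, pass), `measurements`
#'   (data.frame side/tissue/delta_volume/pre_area/movement),
#'   `rotation_pre`, `rotation_post`, `rotation_change`, `cheek`
#'   (data.frame side/position), `transform`.
#' @export
run_patient <- function(pre, post, config = run_config(), pre_ctx = NULL) {
  fail <- function(stage, err) {
    structure(list(status = "failed", failed_stage = stage,
                   message = conditionMessage(err)),
              class = "patient_result")
  }

  for (obj in list(pre, post)) {
    if (is.null(obj$bone) || is.null(obj$soft) || is.null(obj$landmarks)) {
      return(fail("inputs", simpleError("missing mesh or landmark input")))
    }
  }

  ctx <- tryCatch(
    if (is.null(pre_ctx)) prepare_patient(pre, config) else pre_ctx,
    error = function(e) e
  )
  if (inherits(ctx, "error")) return(fail("anatomy", ctx))

  reg <- tryCatch({
    frame_post <- build_reference_frame(post$landmarks)
    planes_post <- construct_planes(frame_post, post$landmarks)
    mask <- registration_mask(post$bone, planes_post, post$landmarks)
    init <- landmark_init(post$landmarks, pre$landmarks)
    rigid_icp(post$bone, pre$bone, mask, init = init,
              max_iter = config$icp$max_iter, tol_mm = config$icp$tol_mm,
              sample = config$icp$sample)
  }, error = function(e) e)
  if (inherits(reg, "error")) return(fail("registration", reg))

  post_bone <- apply_transform(post$bone, reg$transform)
  post_soft <- apply_transform(post$soft, reg$transform)
  post_lm <- apply_transform(post$landmarks, reg$transform)
  qc <- list(rms = reg$rms_deviation,
             pass = qc_registration(reg, config$qc_rms_threshold_mm))

  rot <- tryCatch({
    rotation_post <- maxillary_rotation_angle(ctx$frame, post_lm)
    list(post = rotation_post,
         change = rotation_change(ctx$rotation_pre, rotation_post))
  }, error = function(e) e)
  if (inherits(rot, "error")) return(fail("rotation", rot))

  meas <- tryCatch({
    rows <- list()
    for (side in c("L", "R")) {
      for (tissue in c("bone", "soft")) {
        patch <- ctx$patches[[paste0(tissue, "_", side)]]
        target <- if (tissue == "bone") post_bone else post_soft
        vc <- volumetric_change(patch, target, grid_mm = config$grid_mm)
        rows[[length(rows) + 1L]] <- data.frame(
          side = side, tissue = tissue,
          delta_volume = vc$delta_volume, pre_area = vc$pre_area,
          movement = vc$movement
        )
      }
    }
    do.call(rbind, rows)
  }, error = function(e) e)
  if (inherits(meas, "error")) return(fail("volumetrics", meas))

  cheek <- tryCatch({
    rows <- lapply(c("L", "R"), function(side) {
      cm <- cheek_mass_position(post_soft, ctx$frame, pre$landmarks, side)
      data.frame(side = side, position = cm$position)
    })
    do.call(rbind, rows)
  }, error = function(e) e)
  if (inherits(cheek, "error")) return(fail("cheekmetric", cheek))

  structure(list(
    status = "ok", failed_stage = NULL,
    qc = qc, measurements = meas,
    rotation_pre = ctx$rotation_pre, rotation_post = rot$post,
    rotation_change = rot$change,
    cheek = cheek, transform = reg$transform
  ), class = "patient_result")
}

#' @export
print.patient_result <- function(x, ...) {
  if (!identical(x$status, "ok")) {
    cat(sprintf("<patient_result> FAILED at stage '%s': %s\n",
                x$failed_stage, x$message))
    return(invisible(x))
  }
  cat(sprintf(
    "<patient_result> RMS %.3f mm (QC %s), rotation change %+.2f deg\n",
    x$qc$rms, if (x$qc$pass) "pass" else "FAIL", x$rotation_change
  ))
  print(x$measurements)
  invisible(x)
}

mean_sd <- function(v) c(n = length(v), mean = mean(v), sd = sd(v))

#' Cohort-level report
#'
#' Aggregates a cohort table (or a list of per-patient results) into the
#' standard report blocks: per-side movement summaries, soft-to-bone
#' ratios, side-comparison p-values, the prediction models per region with
#' multiple correlations, the stratified normative comparison of the
#' cheek-mass position, a QC summary, and the observed-vs-fitted scatter
#' data.
#'
#' @param x a [cohort_table()], or a list of `patient_result`s (patients
#'   failing QC or a pipeline stage are excluded and counted).
#' @param config a [run_config()] (normative constants).
#' @return object of class `cohort_report`.
#' @export
run_cohort <- function(x, config = run_config()) {
  qc_summary <- NULL
  if (!inherits(x, "cohort_table") && is.list(x) && !is.data.frame(x)) {
    results <- x
    ok <- vapply(results, function(r) identical(r$status, "ok"), logical(1))
    pass <- ok & vapply(results, function(r) isTRUE(r$qc$pass), logical(1))
    rms <- vapply(results[ok], function(r) r$qc$rms, numeric(1))
    qc_summary <- list(
      n_total = length(results), n_ok = sum(ok), n_qc_pass = sum(pass),
      rms_mean = if (length(rms)) mean(rms) else NA_real_,
      rms_range = if (length(rms)) range(rms) else c(NA_real_, NA_real_)
    )
    rows <- list()
    for (i in which(pass)) {
      r <- results[[i]]
      mm <- r$measurements
      for (side in c("L", "R")) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient = i, side = side,
          soft_movement = mm$movement[mm$side == side & mm$tissue == "soft"],
          bone_advancement = mm$movement[mm$side == side & mm$tissue == "bone"],
          rotation = r$rotation_change,
          cheek_position = r$cheek$position[r$cheek$side == side]
        )
      }
    }
    if (length(rows) < 4L) stop("too few patients passed QC for a cohort report")
    x <- cohort_table(do.call(rbind, rows))
  }
  table <- cohort_table(x)

  movements <- do.call(rbind, lapply(
    c(soft_movement = "soft_movement", bone_advancement = "bone_advancement",
      rotation = "rotation"),
    function(v) {
      rbind(
        R = mean_sd(table[[v]][table$side == "R"]),
        L = mean_sd(table[[v]][table$side == "L"]),
        Total = mean_sd(table[[v]])
      )
    }
  ))
  movements <- data.frame(
    variable = rep(c("soft_movement", "bone_advancement", "rotation"), each = 3L),
    region = rep(c("R", "L", "Total"), times = 3L),
    movements, row.names = NULL
  )

  sides <- lapply(
    c(soft_movement = "soft_movement",
      bone_advancement = "bone_advancement", rotation = "rotation"),
    function(v) side_comparison(table, v)$p_value
  )

  models <- lapply(c(R = "R", L = "L", Total = "Total"), function(rg) {
    fit_prediction_model(table, region = rg)
  })
  model_table <- data.frame(
    region = names(models),
    b1 = vapply(models, function(m) m$coefficients["b1"], numeric(1)),
    b2 = vapply(models, function(m) m$coefficients["b2"], numeric(1)),
    r_squared = vapply(models, function(m) m$r_squared, numeric(1)),
    r = vapply(models, multiple_correlation, numeric(1)),
    partial_r2_x1 = vapply(models, function(m) m$partial_r2["X1"], numeric(1)),
    partial_r2_x2 = vapply(models, function(m) m$partial_r2["X2"], numeric(1)),
    p_x1 = vapply(models, function(m) m$p_values["X1"], numeric(1)),
    p_x2 = vapply(models, function(m) m$p_values["X2"], numeric(1)),
    row.names = NULL
  )

  ratios <- soft_bone_ratio(table)

  norm_rows <- NULL
  if (!is.null(table$cheek_position)) {
    norm_rows <- do.call(rbind, lapply(advancement_strata(), function(s) {
      if (sum(table$stratum == s) < 2L) return(NULL)
      nc <- norm_comparison(table, s, config$norm$mean, config$norm$sd,
                            config$norm$n)
      data.frame(
        stratum = s, n = unname(nc$group["n"]),
        group_mean = unname(nc$group["mean"]), group_sd = unname(nc$group["sd"]),
        norm_mean = unname(nc$norm["mean"]), norm_sd = unname(nc$norm["sd"]),
        difference = nc$difference, t = nc$t, p_value = nc$p_value
      )
    }))
  }

  scatter <- data.frame(
    patient = table$patient, side = table$side,
    observed = table$soft_movement,
    fitted = models$Total$fitted
  )

  structure(list(
    n_sides = nrow(table),
    movements = movements,
    ratios = ratios,
    side_p_values = sides,
    models = model_table,
    model_fits = models,
    norm_comparison = norm_rows,
    qc = qc_summary,
    scatter = scatter
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d sides\n", x$n_sides))
  cat("\nMovements (mm / deg):\n")
  print(x$movements, digits = 4)
  cat("\nSoft/bone ratio:\n")
  print(x$ratios, digits = 4)
  cat("\nPrediction models:\n")
  print(x$models, digits = 4)
  if (!is.null(x$norm_comparison)) {
    cat("\nCheek-mass position vs norm:\n")
    print(x$norm_comparison, digits = 4)
  }
  if (!is.null(x$qc)) {
    cat(sprintf("\nQC: %d/%d patients usable, mean RMS %.3f mm (range %.3f-%.3f)\n",
                x$qc$n_qc_pass, x$qc$n_total, x$qc$rms_mean,
                x$qc$rms_range[1], x$qc$rms_range[2]))
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Writes `report.json` (all blocks) plus CSVs of the movement summary,
#' ratio table, model table, normative comparison and scatter data.
#'
#' @param report a `cohort_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- report[c("n_sides", "movements", "ratios", "side_p_values",
                     "models", "norm_comparison", "qc")]
  jsonlite::write_json(blocks, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(report$movements, file.path(dir, "movements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ratios, file.path(dir, "ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(report$models, file.path(dir, "models.csv"),
                   row.names = FALSE)
  if (!is.null(report$norm_comparison)) {
    utils::write.csv(report$norm_comparison,
                     file.path(dir, "norm_comparison.csv"), row.names = FALSE)
  }
  utils::write.csv(report$scatter, file.path(dir, "scatter.csv"),
                   row.names = FALSE)
  invisible(dir)
}
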