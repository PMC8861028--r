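#' Configuration for the self-validation suite
#'
#' Batteries are scaled down by default so the suite runs in seconds to a
#' few minutes on one CPU; the tolerances are stated alongside each battery
#' in the report. `n_typeI_reps = 0` skips the (slow) type-I battery.
#'
#' @param phantom_spec Phantom specification to validate against.
#' @param params Segmentation parameters.
#' @param n_noise_seeds Noisy phantom recovery replicates.
#' @param rotation_angles_deg Rotation-robustness angles (about x).
#' @param erosion_fraction Erosion linearity fraction.
#' @param n_regression_reps Agreement-regression recovery replicates.
#' @param regression_noise_sd Ex vivo noise SD for the regression battery.
#' @param n_typeI_reps Null-cohort replicates for the type-I battery.
#' @param alpha Nominal test size.
#' @param n_slices VOI length used by the quantification calls (default
#'   100; reduce for small phantoms).
#' @param tolerances Named list of acceptance tolerances.
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(phantom_spec = default_tarsal_spec(),
                              params = segmentation_params(),
                              n_noise_seeds = 3L,
                              rotation_angles_deg = c(20, 45),
                              erosion_fraction = 0.3,
                              n_regression_reps = 100L,
                              regression_noise_sd = 0.05,
                              n_typeI_reps = 0L,
                              alpha = 0.05,
                              n_slices = 100L,
                              tolerances = list(
                                bv_noiseless = 0,      # exact
                                stv_rel = 0.03,
                                bv_noise_rel = 0.02,
                                erosion_rel = 0.03,
                                rotation_rel = 0.03,
                                slope_abs = 0.02,
                                typeI_range = c(0.02, 0.10)
                              )) {
  structure(
    list(
      phantom_spec = phantom_spec, params = params,
      n_noise_seeds = as.integer(n_noise_seeds),
      rotation_angles_deg = rotation_angles_deg,
      erosion_fraction = erosion_fraction,
      n_regression_reps = as.integer(n_regression_reps),
      regression_noise_sd = regression_noise_sd,
      n_typeI_reps = as.integer(n_typeI_reps),
      alpha = alpha,
      n_slices = as.integer(n_slices),
      tolerances = tolerances
    ),
    class = "validation_config"
  )
}

report_row <- function(battery, metric, value, tolerance, pass) {
  data.frame(battery = battery, metric = metric, value = value,
             tolerance = tolerance, pass = pass, stringsAsFactors = FALSE)
}

#' Ground-truth bone/soft volumes restricted to the VOI actually analysed
#' @noRd
gt_in_voi <- function(gt, voi, spacing) {
  sl <- voi$start_slice:(voi$start_slice + voi$n_slices - 1L)
  list(
    bv = sum(gt$bone_mask[, , sl]) * prod(spacing),
    stv = sum(gt$soft_mask[, , sl]) * prod(spacing)
  )
}

#' Run the self-validation suite
#'
#' Executes the phantom-recovery, erosion-linearity, rotation-robustness,
#' regression-recovery and (optionally) type-I-error batteries against known
#' ground truth and returns a machine-readable pass/fail report. Failures
#' are report rows, never errors. Deterministic given the seed.
#'
#' @param config A [validation_config()].
#' @param seed Integer seed.
#' @return A data frame of class `validation_report` with columns battery,
#'   metric, value, tolerance, pass.
#' @export
run_validation_suite <- function(config = validation_config(), seed = 1L) {
  tol <- config$tolerances
  spec <- config$phantom_spec
  params <- config$params
  rows <- list()
  # a battery that errors out is a failing report row, never an exception
  safely <- function(battery, expr) {
    tryCatch(expr, error = function(e) {
      rows[[length(rows) + 1L]] <<- report_row(
        battery, "error", NA_real_, conditionMessage(e), FALSE
      )
      NULL
    })
  }

  # --- phantom recovery, noiseless ---
  spec0 <- spec; spec0$noise_sd <- 0
  ph <- make_phantom(spec0, seed = seed)
  bv_aligned <- NA_real_
  safely("phantom_recovery", {
    q <- quantify(ph$volume, params = params, n_slices = config$n_slices)
    gt <- gt_in_voi(ph$ground_truth, q$voi_used, ph$volume$spacing)
    rows[[length(rows) + 1L]] <- report_row(
      "phantom_recovery", "bv_noiseless_rel_err",
      abs(q$bone_volume_mm3 - gt$bv) / gt$bv,
      sprintf("== %g", tol$bv_noiseless),
      abs(q$bone_volume_mm3 - gt$bv) / gt$bv <= tol$bv_noiseless
    )
    rows[[length(rows) + 1L]] <- report_row(
      "phantom_recovery", "stv_noiseless_rel_err",
      abs(q$soft_volume_mm3 - gt$stv) / gt$stv,
      sprintf("<= %g", tol$stv_rel),
      abs(q$soft_volume_mm3 - gt$stv) / gt$stv <= tol$stv_rel
    )
    bv_aligned <- q$bone_volume_mm3 # promise evaluates in this frame
  })

  # --- phantom recovery, noisy ---
  if (config$n_noise_seeds > 0) safely("phantom_recovery", {
    errs <- vapply(seq_len(config$n_noise_seeds), function(i) {
      phn <- make_phantom(spec, seed = seed + i)
      qn <- quantify(phn$volume, params = params, n_slices = config$n_slices)
      gtn <- gt_in_voi(phn$ground_truth, qn$voi_used, phn$volume$spacing)
      abs(qn$bone_volume_mm3 - gtn$bv) / gtn$bv
    }, numeric(1))
    rows[[length(rows) + 1L]] <- report_row(
      "phantom_recovery", "bv_noise_max_rel_err", max(errs),
      sprintf("<= %g", tol$bv_noise_rel), max(errs) <= tol$bv_noise_rel
    )
  })

  # --- erosion linearity ---
  f <- config$erosion_fraction
  if (!is.null(f) && f > 0) safely("erosion_linearity", {
    spec_e <- apply_disease(spec0, erosion_fraction = f, seed = seed)
    ph_e <- make_phantom(spec_e, seed = seed)
    q_e <- quantify(ph_e$volume, params = params, n_slices = config$n_slices)
    ratio <- q_e$bone_volume_mm3 / bv_aligned
    rows[[length(rows) + 1L]] <- report_row(
      "erosion_linearity", sprintf("bv_ratio_at_f_%g", f), ratio,
      sprintf("within %g of %g", tol$erosion_rel, 1 - f),
      is.finite(ratio) && abs(ratio - (1 - f)) <= tol$erosion_rel
    )
  })

  # --- rotation robustness ---
  for (ang in config$rotation_angles_deg) safely("rotation_robustness", {
    spec_r <- spec0
    spec_r$rotation <- list(axis = c(1, 0, 0), angle_deg = ang)
    ph_r <- make_phantom(spec_r, seed = seed)
    q_r <- quantify(ph_r$volume, params = params, n_slices = config$n_slices)
    rel <- abs(q_r$bone_volume_mm3 - bv_aligned) / bv_aligned
    rows[[length(rows) + 1L]] <- report_row(
      "rotation_robustness", sprintf("bv_rel_change_%gdeg", ang), rel,
      sprintf("<= %g", tol$rotation_rel), is.finite(rel) && rel <= tol$rotation_rel
    )
  })

  # --- agreement-regression recovery ---
  if (config$n_regression_reps > 0) {
    design <- cohort_design(n_naive = 9L)
    link <- design$ex_vivo_link
    link$noise_sd <- config$regression_noise_sd
    slopes <- vapply(seq_len(config$n_regression_reps), function(i) {
      tab <- simulate_cohort(design, seed = seed + 10000L + i)
      prs <- simulate_ex_vivo_pairs(tab, link = link, seed = seed + 20000L + i)
      fit_agreement_regression(prs)$slope
    }, numeric(1))
    rows[[length(rows) + 1L]] <- report_row(
      "regression_recovery", "mean_slope", mean(slopes),
      sprintf("within %g of %g", tol$slope_abs, link$slope),
      abs(mean(slopes) - link$slope) <= tol$slope_abs
    )
  }

  # --- type-I error of the day-21 mixed-effects contrast under the null ---
  if (config$n_typeI_reps > 0) {
    nulld <- null_cohort_design()
    rej <- vapply(seq_len(config$n_typeI_reps), function(i) {
      tab <- simulate_cohort(nulld, seed = seed + 30000L + i)
      res <- compare_groups_longitudinal(tab, "bv_mm3", method = "mixed_effects")
      p <- res$p_value[res$day == 21 & res$group1 == "prednisolone"]
      p < config$alpha
    }, logical(1))
    rate <- mean(rej)
    rows[[length(rows) + 1L]] <- report_row(
      "type_I_error", "day21_rejection_rate", rate,
      sprintf("in [%g, %g]", tol$typeI_range[1], tol$typeI_range[2]),
      rate >= tol$typeI_range[1] && rate <= tol$typeI_range[2]
    )
  }

  res <- do.call(rbind, rows)
  class(res) <- c("validation_report", class(res))
  attr(res, "seed") <- as.integer(seed)
  res
}
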