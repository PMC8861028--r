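#' Longitudinal cohort design
#'
#' Parametric description of the three-group collagen-induced arthritis
#' study: per-group sample sizes, imaging days, per-group/day means for
#' caliper thickness, bone volume and soft-tissue volume, animal-level and
#' residual SDs per measure, terminal-day ordinal histopathology score
#' distributions, and the linear link tying day-21 in vivo BV to ex vivo BV.
#'
#' Defaults reproduce the printed study endpoints: groups of 10 naive, 6
#' untreated and 6 prednisolone-treated animals measured on days 0, 7, 14
#' and 21; day-21 caliper 2.6 mm untreated vs 2.08 mm treated, STV 19.5 vs
#' 10.7 mm^3, BV 1.4 vs 2.1 mm^3; and the agreement line
#' in_vivo = 0.7 * ex_vivo + 0.4. Intermediate-day means interpolate the
#' printed trajectory shapes (disease peaks at day 7, treatment from day 7)
#' and are synthetic, not printed values.
#'
#' @param n_naive,n_untreated,n_prednisolone Group sizes.
#' @param days Measurement days.
#' @param means Long data frame (group, day, measure, mean) overriding the
#'   default trajectories.
#' @param sd_animal Named per-measure SD of the animal-level random
#'   intercept.
#' @param sd_resid Named per-measure residual SD.
#' @param histo_probs List per histopathology measure of a 3 x 5 matrix of
#'   score probabilities (rows: naive, untreated, prednisolone; columns:
#'   scores 0-4).
#' @param ex_vivo_link `list(slope, intercept, noise_sd)` of the in vivo ~
#'   ex vivo agreement line.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_naive = 10L, n_untreated = 6L, n_prednisolone = 6L,
                          days = c(0L, 7L, 14L, 21L), means = NULL,
                          sd_animal = c(caliper_mm = 0.10, bv_mm3 = 0.07, stv_mm3 = 1.2),
                          sd_resid = c(caliper_mm = 0.10, bv_mm3 = 0.07, stv_mm3 = 1.2),
                          histo_probs = NULL, ex_vivo_link = list(slope = 0.7, intercept = 0.4, noise_sd = 0.05)) {
  if (is.null(means)) means <- default_cohort_means(days)
  if (is.null(histo_probs)) histo_probs <- default_histo_probs()
  for (m in names(histo_probs)) {
    pr <- histo_probs[[m]]
    if (any(pr < 0) || any(abs(rowSums(pr) - 1) > 1e-8)) {
      stop_tarsalct("histopathology score probabilities must be >= 0 and sum to 1 per group",
                    "contract")
    }
  }
  if (any(c(sd_animal, sd_resid) < 0)) {
    stop_tarsalct("SDs must be >= 0", "contract")
  }
  if (!is.null(ex_vivo_link) && ex_vivo_link$slope == 0) {
    stop_tarsalct("ex vivo link slope must be non-zero", "range")
  }
  structure(
    list(
      group_sizes = c(naive = as.integer(n_naive), untreated = as.integer(n_untreated),
                      prednisolone = as.integer(n_prednisolone)),
      days = as.integer(days),
      means = means,
      sd_animal = sd_animal,
      sd_resid = sd_resid,
      histo_probs = histo_probs,
      ex_vivo_link = ex_vivo_link
    ),
    class = "cohort_design"
  )
}

#' Default per-group/day mean trajectories. Day-21 endpoints are the printed
#' group means; earlier days follow the printed trajectory shapes (peak
#' inflammation at day 7, prednisolone dosed from day 7 onward).
#' @noRd
default_cohort_means <- function(days = c(0L, 7L, 14L, 21L)) {
  traj <- list(
    caliper_mm = list(
      naive = c(1.75, 1.75, 1.75, 1.75),
      untreated = c(2.0, 2.7, 2.65, 2.6),
      prednisolone = c(2.0, 2.7, 2.3, 2.08)
    ),
    bv_mm3 = list(
      naive = c(2.5, 2.5, 2.5, 2.5),
      untreated = c(2.4, 1.9, 1.6, 1.4),
      prednisolone = c(2.4, 1.9, 2.0, 2.1)
    ),
    stv_mm3 = list(
      naive = c(8.5, 8.5, 8.5, 8.5),
      untreated = c(13, 20, 20, 19.5),
      prednisolone = c(13, 20, 14, 10.7)
    )
  )
  full_days <- c(0L, 7L, 14L, 21L)
  keep <- match(days, full_days)
  if (anyNA(keep)) stop_tarsalct("default means are defined for days 0, 7, 14, 21", "contract")
  do.call(rbind, lapply(names(traj), function(m) {
    do.call(rbind, lapply(names(traj[[m]]), function(g) {
      data.frame(group = g, day = days, measure = m,
                 mean = traj[[m]][[g]][keep], stringsAsFactors = FALSE)
    }))
  }))
}

#' Terminal-day histopathology score distributions: naive massed at 0,
#' untreated centred at 3, prednisolone centred at 1-2 (reproducing the
#' group ordering without inventing unprinted means).
#' @noRd
default_histo_probs <- function() {
  probs <- rbind(
    naive = c(0.9, 0.1, 0, 0, 0),
    untreated = c(0, 0.05, 0.15, 0.45, 0.35),
    prednisolone = c(0.10, 0.35, 0.35, 0.15, 0.05)
  )
  colnames(probs) <- 0:4
  list(
    histo_inflammation = probs,
    histo_pannus = probs,
    histo_bone_destruction = probs
  )
}

#' A null version of the cohort design (no group effects)
#'
#' Every group follows the naive trajectory for every measure and shares the
#' naive histopathology distribution; used for type-I-error calibration.
#'
#' @param design A [cohort_design()] (defaults to the standard design).
#' @return A [cohort_design()] with all group means equalised.
#' @export
null_cohort_design <- function(design = cohort_design()) {
  mm <- design$means
  for (m in unique(mm$measure)) {
    for (d in unique(mm$day)) {
      sel <- mm$measure == m & mm$day == d
      mm$mean[sel] <- mm$mean[sel & mm$group == "naive"][1]
    }
  }
  design$means <- mm
  for (m in names(design$histo_probs)) {
    pr <- design$histo_probs[[m]]
    pr[] <- rep(pr["naive", ], each = nrow(pr))
    design$histo_probs[[m]] <- pr
  }
  design
}

#' Simulate a longitudinal cohort
#'
#' Each animal's trajectory for each continuous measure is
#' group/day mean + animal-level random intercept + residual noise (both
#' Gaussian, SDs from the design). Terminal-day histopathology scores are
#' drawn from the design's ordinal distributions. Deterministic given the
#' seed.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @return A validated long-format cohort table.
#' @export
simulate_cohort <- function(design, seed = 1L) {
  if (!inherits(design, "cohort_design")) {
    stop_tarsalct("`design` must be a cohort_design", "contract")
  }
  withr::with_seed(as.integer(seed), {
    rows <- list()
    measures <- unique(design$means$measure)
    nd <- length(design$days)
    for (g in names(design$group_sizes)) {
      n <- design$group_sizes[[g]]
      if (n < 1L) next
      ids <- sprintf("%s_%02d", g, seq_len(n))
      for (m in measures) {
        mu <- design$means[design$means$group == g & design$means$measure == m, ]
        mu <- mu$mean[match(design$days, mu$day)]
        b <- stats::rnorm(n, 0, design$sd_animal[[m]])
        eps <- stats::rnorm(n * nd, 0, design$sd_resid[[m]])
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = rep(ids, each = nd), group = g,
          day = rep(design$days, times = n), measure = m,
          value = rep(mu, times = n) + rep(b, each = nd) + eps,
          stringsAsFactors = FALSE
        )
      }
      d_term <- max(design$days)
      for (m in names(design$histo_probs)) {
        pr <- design$histo_probs[[m]][g, ]
        sc <- sample(0:4, n, replace = TRUE, prob = pr)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = ids, group = g, day = d_term,
          measure = m, value = as.numeric(sc),
          stringsAsFactors = FALSE
        )
      }
    }
    validate_cohort_table(do.call(rbind, rows), days = design$days)
  })
}

#' Simulate paired day-21 in vivo / ex vivo bone volumes
#'
#' The printed agreement line is in_vivo = slope * ex_vivo + intercept, so
#' the simulator inverts it: ex_vivo = (in_vivo - intercept) / slope plus
#' Gaussian noise on the ex vivo (predictor) side. Regressing in vivo on
#' ex vivo with [fit_agreement_regression()] then recovers (slope,
#' intercept) exactly in the noise-free limit.
#'
#' @param table A cohort table containing day-21 `bv_mm3` rows.
#' @param link `list(slope, intercept, noise_sd)`; slope must be non-zero.
#' @param seed Integer seed for the ex vivo noise.
#' @return Data frame with `animal_id`, `group`, `in_vivo_bv_mm3`,
#'   `ex_vivo_bv_mm3`.
#' @export
simulate_ex_vivo_pairs <- function(table,
                                   link = list(slope = 0.7, intercept = 0.4, noise_sd = 0.05),
                                   seed = 1L) {
  if (is.null(link$slope) || link$slope == 0) {
    stop_tarsalct("link slope must be non-zero", "range")
  }
  day21 <- table[table$measure == "bv_mm3" & table$day == 21, ]
  if (nrow(day21) == 0L) {
    stop_tarsalct("table contains no day-21 bone volume rows", "contract")
  }
  withr::with_seed(as.integer(seed), {
    noise <- stats::rnorm(nrow(day21), 0, link$noise_sd %||% 0)
    data.frame(
      animal_id = day21$animal_id,
      group = day21$group,
      in_vivo_bv_mm3 = day21$value,
      ex_vivo_bv_mm3 = (day21$value - link$intercept) / link$slope + noise,
      stringsAsFactors = FALSE
    )
  })
}
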