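#' In vivo vs ex vivo agreement regression
#'
#' Ordinary least squares of in vivo bone volume on ex vivo bone volume (the
#' study's orientation: the terminal ex vivo measurement is the predictor).
#'
#' @param pairs Data frame with columns `ex_vivo_bv_mm3` and
#'   `in_vivo_bv_mm3` (or `ex_vivo` / `in_vivo`), e.g. from
#'   [simulate_ex_vivo_pairs()].
#' @param swap_axes Regress ex vivo on in vivo instead (sensitivity
#'   analysis; default `FALSE`).
#' @return An object of class `agreement_fit` with `slope`, `intercept`,
#'   `r_squared`, `n_pairs`, `residual_sd`.
#' @export
fit_agreement_regression <- function(pairs, swap_axes = FALSE) {
  pick <- function(cands) {
    hit <- intersect(cands, names(pairs))
    if (!length(hit)) {
      stop_tarsalct(
        sprintf("`pairs` needs one of: %s", paste(cands, collapse = ", ")),
        "contract"
      )
    }
    pairs[[hit[1]]]
  }
  x <- pick(c("ex_vivo_bv_mm3", "ex_vivo", "ex_vivo_bv"))
  y <- pick(c("in_vivo_bv_mm3", "in_vivo", "in_vivo_bv"))
  if (swap_axes) { tmp <- x; x <- y; y <- tmp }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_tarsalct("need at least 3 pairs", "contract")
  if (stats::var(x) == 0) {
    stop_tarsalct("all predictor values identical; fit is singular", "singular_fit")
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      n_pairs = n,
      residual_sd = sqrt(ss_res / max(1L, n - 2L))
    ),
    class = "agreement_fit"
  )
}

#' @export
print.agreement_fit <- function(x, ...) {
  cat(sprintf(
    "<agreement_fit> in_vivo = %.4f * ex_vivo + %.4f, R^2 = %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_pairs
  ))
  invisible(x)
}

measure_subset <- function(table, measure) {
  df <- table[table$measure == measure, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop_tarsalct(sprintf("no rows for measure '%s'", measure), "design")
  }
  df
}

group_day_cells <- function(df) {
  stats::aggregate(value ~ group + day, df,
                   function(v) c(n = length(v), mean = mean(v), sd = stats::sd(v)))
}

check_cells <- function(df, groups, days) {
  for (g in groups) for (d in days) {
    if (!any(df$group == g & df$day == d)) {
      stop_tarsalct(
        sprintf("design cell (group %s, day %d) is empty", g, d),
        "design"
      )
    }
  }
}

#' Cell-mean contrast rows for an lm/lmer fit with formula
#' value ~ group * day_f. Returns one row per (day, group vs reference).
#' @noRd
cell_contrasts <- function(fit, df, reference, df_contrast, test_name, measure,
                           adjustment = "bonferroni") {
  groups <- levels(df$group)
  days <- levels(df$day_f)
  beta <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  trm <- stats::delete.response(stats::terms(stats::formula(
    if (inherits(fit, "merMod")) lme4::nobars(stats::formula(fit)) else fit
  )))
  xrow <- function(g, d) {
    nd <- data.frame(group = factor(g, levels = groups),
                     day_f = factor(d, levels = days))
    stats::model.matrix(trm, nd)[1, names(beta)]
  }
  out <- list()
  others <- setdiff(groups, reference)
  k <- length(others)
  for (d in days) {
    for (g in others) {
      L <- xrow(g, d) - xrow(reference, d)
      est <- sum(L * beta)
      se <- sqrt(drop(t(L) %*% V %*% L))
      tval <- est / se
      p <- 2 * stats::pt(-abs(tval), df_contrast)
      v1 <- df$value[df$group == g & df$day_f == d]
      v2 <- df$value[df$group == reference & df$day_f == d]
      out[[length(out) + 1L]] <- data.frame(
        test_name = test_name, measure = measure, day = as.integer(as.character(d)),
        contrast = sprintf("%s vs %s", g, reference),
        group1 = g, group2 = reference,
        n1 = length(v1), n2 = length(v2),
        mean1 = mean(v1), sd1 = stats::sd(v1),
        mean2 = mean(v2), sd2 = stats::sd(v2),
        estimate = est, se = se, statistic = tval, df = df_contrast,
        p_value = p, p_adjusted = min(1, p * k),
        adjustment = adjustment, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("group_test_result", class(res))
  res
}

#' Longitudinal group contrasts for one measure
#'
#' Fits either a two-way ANOVA with fixed effects group, day and their
#' interaction (the caliper analysis) or a mixed-effects model adding a
#' random intercept per animal fitted by REML (the in vivo uCT analysis),
#' then reports per-day contrasts of each group against the reference group
#' with Bonferroni adjustment across the groups compared at each day.
#' Mixed-model contrast p-values use containment degrees of freedom
#' (number of animals minus number of groups).
#'
#' For caliper thickness the response defaults to change from the day-0
#' baseline (the study plots change in paw thickness); other measures are
#' analysed on the raw scale.
#'
#' @param table A cohort table.
#' @param measure Measure to analyse, e.g. `"bv_mm3"`.
#' @param method `"mixed_effects"` or `"two_way_anova"`.
#' @param reference Reference group for contrasts (default `"untreated"`).
#' @param baseline_adjust Analyse change from day 0; default `TRUE` for
#'   `caliper_mm` only.
#' @return A `group_test_result` data frame, one row per (day, contrast);
#'   the fitted model is attached as attribute `"fit"` and the omnibus
#'   ANOVA table (two-way method) as `"anova"`.
#' @export
compare_groups_longitudinal <- function(table, measure,
                                        method = c("mixed_effects", "two_way_anova"),
                                        reference = "untreated",
                                        baseline_adjust = NULL) {
  method <- match.arg(method)
  df <- measure_subset(table, measure)
  baseline_adjust <- baseline_adjust %||% identical(measure, "caliper_mm")
  if (baseline_adjust) {
    base <- df[df$day == min(df$day), c("animal_id", "value")]
    names(base)[2] <- "baseline"
    df <- merge(df[df$day > min(df$day), ], base, by = "animal_id")
    df$value <- df$value - df$baseline
  }
  groups <- intersect(COHORT_GROUPS, unique(df$group))
  days <- sort(unique(df$day))
  if (length(groups) < 2L) {
    stop_tarsalct("need at least 2 groups for a longitudinal contrast", "design")
  }
  if (length(days) < 2L) {
    stop_tarsalct("need at least 2 days for a longitudinal contrast", "design")
  }
  check_cells(df, groups, days)
  if (!reference %in% groups) {
    stop_tarsalct(sprintf("reference group '%s' absent from the data", reference), "design")
  }
  df$group <- factor(df$group, levels = groups)
  df$day_f <- factor(df$day, levels = days)
  df$animal_id <- factor(df$animal_id)

  if (method == "two_way_anova") {
    fit <- stats::lm(value ~ group * day_f, data = df)
    res <- cell_contrasts(fit, df, reference, stats::df.residual(fit),
                          "two_way_anova", measure)
    attr(res, "anova") <- stats::anova(fit)
  } else {
    fit <- suppressMessages(lme4::lmer(
      value ~ group * day_f + (1 | animal_id),
      data = df, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
    ))
    df_contrast <- nlevels(df$animal_id) - length(groups)
    res <- cell_contrasts(fit, df, reference, df_contrast, "mixed_effects", measure)
  }
  attr(res, "fit") <- fit
  res
}

#' Terminal-day one-way ANOVA across groups
#'
#' One-way ANOVA on a terminal measurement (ex vivo bone volume by default)
#' with pairwise group contrasts using the pooled error term and Bonferroni
#' adjustment. Identical values everywhere are reported as F = 0, p = 1.
#'
#' @param table A cohort table.
#' @param measure Measure to test (default `"ex_vivo_bv_mm3"`).
#' @param day Day of the measurement (default 21).
#' @return A `group_test_result` data frame: an `overall` row (the F test)
#'   plus one row per pairwise contrast.
#' @export
compare_groups_terminal <- function(table, measure = "ex_vivo_bv_mm3", day = 21L) {
  df <- measure_subset(table, measure)
  df <- df[df$day == day, , drop = FALSE]
  groups <- intersect(COHORT_GROUPS, unique(df$group))
  if (length(groups) < 2L) {
    stop_tarsalct("need at least 2 groups", "design")
  }
  ns <- table(factor(df$group, levels = groups))
  if (any(ns < 2L)) {
    stop_tarsalct(
      sprintf("group(s) with fewer than 2 observations: %s",
              paste(names(ns)[ns < 2], collapse = ", ")),
      "design"
    )
  }
  df$group <- factor(df$group, levels = groups)
  N <- nrow(df)
  k <- length(groups)
  grand <- mean(df$value)
  means <- tapply(df$value, df$group, mean)
  sds <- tapply(df$value, df$group, stats::sd)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((df$value - means[df$group])^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ss_between == 0 && ss_within == 0) {
    Fstat <- 0; p <- 1; mse <- 0
  } else {
    mse <- ss_within / df2
    Fstat <- (ss_between / df1) / mse
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  rows <- list(data.frame(
    test_name = "one_way_anova", measure = measure, day = day,
    contrast = "overall", group1 = NA, group2 = NA,
    n1 = N, n2 = NA, mean1 = grand, sd1 = stats::sd(df$value),
    mean2 = NA, sd2 = NA, estimate = NA, se = NA,
    statistic = Fstat, df = df1, p_value = p, p_adjusted = p,
    adjustment = "none", stringsAsFactors = FALSE
  ))
  combs <- utils::combn(groups, 2)
  n_comp <- ncol(combs)
  for (i in seq_len(n_comp)) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    est <- means[[g1]] - means[[g2]]
    se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tval <- if (se > 0) est / se else 0
    pp <- if (se > 0) 2 * stats::pt(-abs(tval), df2) else 1
    rows[[length(rows) + 1L]] <- data.frame(
      test_name = "one_way_anova", measure = measure, day = day,
      contrast = sprintf("%s vs %s", g1, g2), group1 = g1, group2 = g2,
      n1 = ns[[g1]], n2 = ns[[g2]], mean1 = means[[g1]], sd1 = sds[[g1]],
      mean2 = means[[g2]], sd2 = sds[[g2]], estimate = est, se = se,
      statistic = tval, df = df2, p_value = pp,
      p_adjusted = min(1, pp * n_comp), adjustment = "bonferroni",
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  class(res) <- c("group_test_result", class(res))
  res
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Kruskal-Wallis H (midranks, tie-corrected) across groups on an ordinal
#' histopathology score, followed by Dunn's z tests of each group against
#' the untreated control with Bonferroni adjustment over the comparisons
#' performed. A fully tied sample is reported as H = 0, p = 1 (not an
#' error).
#'
#' @param table A cohort table.
#' @param score_measure One of the `histo_*` measures.
#' @param reference Control group for Dunn comparisons (default
#'   `"untreated"`).
#' @return A `group_test_result` data frame: the `overall` Kruskal-Wallis
#'   row plus one Dunn row per comparison vs the reference.
#' @export
ordinal_group_test <- function(table, score_measure, reference = "untreated") {
  df <- measure_subset(table, score_measure)
  groups <- intersect(COHORT_GROUPS, unique(df$group))
  if (length(groups) < 2L) stop_tarsalct("need at least 2 groups", "design")
  if (!reference %in% groups) {
    stop_tarsalct(sprintf("reference group '%s' absent from the data", reference), "design")
  }
  g <- factor(df$group, levels = groups)
  x <- df$value
  N <- length(x)
  if (length(unique(x)) == 1L) {
    H <- 0; p <- 1
  } else {
    kw <- stats::kruskal.test(x, g)
    H <- unname(kw$statistic)
    p <- kw$p.value
  }
  ns <- table(g)
  means <- tapply(x, g, mean)
  sds <- tapply(x, g, stats::sd)
  rows <- list(data.frame(
    test_name = "kruskal_wallis", measure = score_measure, day = NA,
    contrast = "overall", group1 = NA, group2 = NA,
    n1 = N, n2 = NA, mean1 = mean(x), sd1 = stats::sd(x),
    mean2 = NA, sd2 = NA, estimate = NA, se = NA,
    statistic = H, df = length(groups) - 1L, p_value = p, p_adjusted = p,
    adjustment = "none", stringsAsFactors = FALSE
  ))
  # Dunn's z with midranks and tie correction
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, g, mean)
  others <- setdiff(groups, reference)
  k <- length(others)
  for (gg in others) {
    diffr <- rbar[[gg]] - rbar[[reference]]
    se <- sqrt(s2 * (1 / ns[[gg]] + 1 / ns[[reference]]))
    z <- if (se > 0) diffr / se else 0
    pp <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
    rows[[length(rows) + 1L]] <- data.frame(
      test_name = "dunn", measure = score_measure, day = NA,
      contrast = sprintf("%s vs %s", gg, reference), group1 = gg, group2 = reference,
      n1 = ns[[gg]], n2 = ns[[reference]], mean1 = means[[gg]], sd1 = sds[[gg]],
      mean2 = means[[reference]], sd2 = sds[[reference]],
      estimate = diffr, se = se, statistic = z, df = NA,
      p_value = pp, p_adjusted = min(1, pp * k), adjustment = "bonferroni",
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  class(res) <- c("group_test_result", class(res))
  res
}

#' Cumulative radiation dose over an imaging protocol
#'
#' @param n_sessions Number of imaging sessions (>= 0).
#' @param dose_per_scan_mGy Dose per scan in mGy (default 1100, the study's
#'   per-session dose).
#' @return Cumulative dose in mGy (`n_sessions * dose_per_scan_mGy`).
#' @examples
#' cumulative_dose(4) # the study protocol: 4400 mGy
#' @export
cumulative_dose <- function(n_sessions, dose_per_scan_mGy = 1100) {
  if (n_sessions < 0 || dose_per_scan_mGy < 0) {
    stop_tarsalct("sessions and dose must be non-negative", "range")
  }
  n_sessions * dose_per_scan_mGy
}
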