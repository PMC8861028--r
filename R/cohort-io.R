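COHORT_GROUPS <- c("naive", "untreated", "prednisolone")
COHORT_DAYS <- c(0L, 7L, 14L, 21L)
COHORT_MEASURES <- c(
  "caliper_mm", "bv_mm3", "stv_mm3",
  "histo_inflammation", "histo_pannus", "histo_bone_destruction",
  "ex_vivo_bv_mm3"
)
HISTO_MEASURES <- c("histo_inflammation", "histo_pannus", "histo_bone_destruction")

#' Validate a long-format cohort table
#'
#' A cohort table has one row per (animal, day, measure) with columns
#' `animal_id`, `group`, `day`, `measure`, `value`. Groups are restricted to
#' naive / untreated / prednisolone; days to the study schedule (default
#' 0, 7, 14, 21); histopathology values must be integers on the 0-4 scale;
#' ex vivo bone volume appears only at the terminal day.
#'
#' @param table A data frame.
#' @param groups,days,measures Allowed levels of the schema.
#' @return The validated table (classed `cohort_table`), invisibly usable as
#'   a plain data frame.
#' @export
validate_cohort_table <- function(table, groups = COHORT_GROUPS,
                                  days = COHORT_DAYS,
                                  measures = COHORT_MEASURES) {
  required <- c("animal_id", "group", "day", "measure", "value")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop_tarsalct(
      sprintf("cohort table lacks columns: %s", paste(missing_cols, collapse = ", ")),
      "validation"
    )
  }
  bad <- which(!table$group %in% groups)
  if (length(bad)) {
    stop_tarsalct(
      sprintf("unknown group label(s) '%s' in rows %s",
              paste(unique(table$group[bad]), collapse = "', '"), fmt_rows(bad)),
      "validation"
    )
  }
  bad <- which(!table$day %in% days)
  if (length(bad)) {
    stop_tarsalct(
      sprintf("day outside schedule {%s} in rows %s",
              paste(days, collapse = ", "), fmt_rows(bad)),
      "validation"
    )
  }
  bad <- which(!table$measure %in% measures)
  if (length(bad)) {
    stop_tarsalct(
      sprintf("unknown measure(s) '%s' in rows %s",
              paste(unique(table$measure[bad]), collapse = "', '"), fmt_rows(bad)),
      "validation"
    )
  }
  val <- suppressWarnings(as.numeric(table$value))
  bad <- which(!is.finite(val))
  if (length(bad)) {
    stop_tarsalct(
      sprintf("non-numeric value(s) in rows %s", fmt_rows(bad)),
      "validation"
    )
  }
  table$value <- val
  histo <- table$measure %in% HISTO_MEASURES
  bad <- which(histo & (val != round(val) | val < 0 | val > 4))
  if (length(bad)) {
    stop_tarsalct(
      sprintf("histopathology scores must be integers 0-4; rows %s", fmt_rows(bad)),
      "validation"
    )
  }
  bad <- which(table$measure == "ex_vivo_bv_mm3" & table$day != max(days))
  if (length(bad)) {
    stop_tarsalct(
      sprintf("ex vivo bone volume is terminal-day only; rows %s", fmt_rows(bad)),
      "validation"
    )
  }
  key <- paste(table$animal_id, table$day, table$measure)
  if (anyDuplicated(key)) {
    stop_tarsalct(
      sprintf("duplicate (animal, day, measure) rows: %s",
              fmt_rows(which(duplicated(key)))),
      "validation"
    )
  }
  class(table) <- unique(c("cohort_table", class(table)))
  table
}

#' Read a cohort table from CSV
#'
#' @param path CSV file with header `animal_id, group, day, measure, value`.
#' @param ... Passed to [validate_cohort_table()] (schema overrides).
#' @return A validated cohort table (data frame).
#' @export
read_cohort_table <- function(path, ...) {
  if (!file.exists(path)) {
    stop_tarsalct(sprintf("file not found: %s", path), "format")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(df, ...)
}

#' Write a cohort table to CSV
#'
#' @param table A cohort table (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  table <- validate_cohort_table(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
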