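# Group filtering and one-way ANOVA on morphometry measures.

#' Filter group records by survival
#'
#' Drops container groups whose survival rate is at or below the cutoff.
#' High mortality diverts building material to burying corpses, so those
#' groups are excluded before any structural comparison (survival of
#' exactly 0.5 is excluded).
#'
#' @param records Data frame with a `survival_rate` column (proportions in
#'   \[0, 1\]).
#' @param cutoff Exclusion threshold (default 0.5).
#' @return The filtered data frame.
#' @export
filter_by_survival <- function(records, cutoff = 0.5) {
  if (!"survival_rate" %in% names(records))
    stop("records must contain a 'survival_rate' column")
  records[records$survival_rate > cutoff, , drop = FALSE]
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance:
#' `F = MS_between / MS_within`, with the p-value from the upper tail of
#' the F distribution. Unbalanced groups are allowed; no Welch correction
#' and no multiple-testing adjustment are applied.
#'
#' @param values Numeric measurements.
#' @param groups Group labels (e.g. colony codes), same length as `values`.
#' @return List with `statistic` (F), `df_between`, `df_within`, `p.value`.
#' @examples
#' one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (length(values) != length(g)) stop("values and groups lengths differ")
  if (anyNA(values) || anyNA(g)) stop("missing values are not supported")
  n <- length(values)
  if (n - nlevels(g) < 1L)
    stop("no residual degrees of freedom (need more than one record in some group)")
  tab <- stats::anova(stats::lm(values ~ g))
  list(statistic = tab[["F value"]][1],
       df_between = tab[["Df"]][1],
       df_within = tab[["Df"]][2],
       p.value = tab[["Pr(>F)"]][1])
}

#' Colony comparison of morphometry measures
#'
#' Applies the survival filter and runs, for each group size present, one
#' one-way ANOVA across colonies for each of the four structural measures
#' (total perimeter, area, perimeter along the edge, perimeter away from
#' the edge).
#'
#' @param records Data frame with columns `colony`, `group_size`,
#'   `survival_rate` and the four measure columns `perimeter_total`,
#'   `area`, `perimeter_edge`, `perimeter_away`.
#' @param cutoff Survival cutoff passed to [filter_by_survival()].
#' @return Data frame with one row per group size and measure: `group_size`,
#'   `measure`, `n`, `F`, `df_between`, `df_within`, `p`.
#' @export
morphometry_anova <- function(records, cutoff = 0.5) {
  measures <- c("perimeter_total", "area", "perimeter_edge", "perimeter_away")
  need <- c("colony", "group_size", "survival_rate", measures)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  kept <- filter_by_survival(records, cutoff)
  rows <- list()
  for (gs in sort(unique(kept$group_size))) {
    sub <- kept[kept$group_size == gs, , drop = FALSE]
    for (m in measures) {
      a <- one_way_anova(sub[[m]], sub$colony)
      rows[[length(rows) + 1L]] <- data.frame(
        group_size = gs, measure = m, n = nrow(sub),
        F = a$statistic, df_between = a$df_between,
        df_within = a$df_within, p = a$p.value)
    }
  }
  do.call(rbind, rows)
}

#' Read a group-records workbook
#'
#' Defensive reader for a spreadsheet of container-group records (colony,
#' group size, survival and structural measures). Column names are matched
#' case-insensitively against common spellings; unrecognized columns are
#' kept as-is. Requires the `readxl` package.
#'
#' @param path Path to an `.xlsx` file.
#' @param sheet Sheet name or index (default 1).
#' @return A data frame with standardized column names where recognized:
#'   `colony`, `group_size`, `survival_rate`, `area`, `perimeter_total`,
#'   `perimeter_edge`, `perimeter_away`.
#' @export
read_group_workbook <- function(path, sheet = 1) {
  if (!file.exists(path))
    stop("workbook not found: ", path)
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("read_group_workbook requires the 'readxl' package")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  standardize_record_names(df)
}

# Map common column spellings onto the package's record schema.
standardize_record_names <- function(df) {
  nm <- tolower(gsub("[^a-z0-9]+", "_", tolower(names(df))))
  pat <- list(
    colony = "^colony",
    group_size = "^(group_?size|n_?workers?|workers?)$",
    survival_rate = "survival",
    area = "^area",
    perimeter_total = "^(perimeter|perimeter_?total|total_?perimeter)$",
    perimeter_edge = "(perimeter.*edge|edge.*perimeter|along)",
    perimeter_away = "(away|non_?edge)")
  out <- names(df)
  for (std in names(pat)) {
    hit <- grep(pat[[std]], nm)
    if (length(hit)) out[hit[1]] <- std
  }
  names(df) <- out
  df
}
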