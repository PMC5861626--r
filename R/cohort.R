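#' Validate a bridging-vein cohort data frame
#'
#' A cohort is a plain data frame with one row per measured bridging vein (BV)
#' and columns `id` (character, unique), `group` (`"anterior"` or
#' `"posterior"`), `diameter_mm` (vein diameter, mm, > 0) and
#' `entry_angle_deg` (angle between the vein and the sinus axis at the dural
#' entrance, degrees, strictly inside (0, 180)).
#'
#' @param cohort data frame to validate.
#' @return The cohort, invisibly, with class `"bv_cohort"` prepended.
#' @export
validate_cohort <- function(cohort) {
  required <- c("id", "group", "diameter_mm", "entry_angle_deg")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  cohort$id <- as.character(cohort$id)
  cohort$group <- as.character(cohort$group)
  if (anyNA(cohort[required])) {
    stop("cohort contains missing values in row(s) ",
         paste(which(!stats::complete.cases(cohort[required])), collapse = ", "))
  }
  dup <- duplicated(cohort$id)
  if (any(dup)) {
    stop("duplicate id(s): ", paste(unique(cohort$id[dup]), collapse = ", "))
  }
  bad_group <- !(cohort$group %in% c("anterior", "posterior"))
  if (any(bad_group)) {
    stop("group must be 'anterior' or 'posterior'; offending row(s): ",
         paste(which(bad_group), collapse = ", "))
  }
  bad_d <- !(is.finite(cohort$diameter_mm) & cohort$diameter_mm > 0)
  if (any(bad_d)) {
    stop("diameter_mm must be positive; offending row(s): ",
         paste(which(bad_d), collapse = ", "))
  }
  bad_a <- !(is.finite(cohort$entry_angle_deg) &
               cohort$entry_angle_deg > 0 & cohort$entry_angle_deg < 180)
  if (any(bad_a)) {
    stop("entry_angle_deg must lie strictly within (0, 180); offending row(s): ",
         paste(which(bad_a), collapse = ", "))
  }
  if (!inherits(cohort, "bv_cohort")) class(cohort) <- c("bv_cohort", class(cohort))
  invisible(cohort)
}

#' Read a bridging-vein cohort from CSV
#'
#' Expects a UTF-8 CSV with header `id,group,diameter_mm,entry_angle_deg`,
#' one vein per row; see [validate_cohort()] for the field invariants.
#'
#' @param path path to the cohort CSV file.
#' @return A validated cohort data frame of class `"bv_cohort"`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  validate_cohort(df)
}

#' Write a bridging-vein cohort to CSV
#'
#' @param cohort a validated cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(
    as.data.frame(cohort)[, c("id", "group", "diameter_mm", "entry_angle_deg")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise one variable of a cohort group
#'
#' Computes n, arithmetic mean, sample standard deviation (n - 1 denominator),
#' minimum and maximum of one variable over one group, i.e. one cell of the
#' mean +/- SD (min-max) anatomical summary table.
#'
#' @param cohort a cohort data frame.
#' @param variable `"diameter"` or `"entry_angle"`.
#' @param group `"anterior"`, `"posterior"` or `"total"` (both groups pooled).
#' @return A one-row data frame with columns
#'   `group, variable, n, mean, sd, min, max`.
#' @export
summarize_cohort <- function(cohort,
                             variable = c("diameter", "entry_angle"),
                             group = c("total", "anterior", "posterior")) {
  cohort <- validate_cohort(cohort)
  variable <- match.arg(variable)
  group <- match.arg(group)
  sel <- if (group == "total") rep(TRUE, nrow(cohort)) else cohort$group == group
  if (!any(sel)) stop("no records in group '", group, "'")
  col <- if (variable == "diameter") "diameter_mm" else "entry_angle_deg"
  x <- cohort[[col]][sel]
  data.frame(group = group, variable = variable, n = length(x),
             mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
             min = min(x), max = max(x), stringsAsFactors = FALSE)
}

#' Full summary table of a cohort
#'
#' All group-by-variable summaries (anterior, posterior, total for diameter
#' and entry angle), the analogue of the anatomical cohort table. `digits`
#' rounds mean/sd to the table's printed precision: 1 decimal for diameters
#' (mm), integer for angles (degrees); `NULL` leaves values unrounded.
#'
#' @param cohort a cohort data frame.
#' @param digits `NULL` or "printed" for the table's native precision.
#' @return Data frame with one row per group-variable combination.
#' @export
cohort_table <- function(cohort, digits = NULL) {
  rows <- list()
  for (v in c("diameter", "entry_angle")) {
    for (g in c("anterior", "posterior", "total")) {
      rows[[length(rows) + 1L]] <- summarize_cohort(cohort, v, g)
    }
  }
  out <- do.call(rbind, rows)
  if (identical(digits, "printed")) {
    dg <- ifelse(out$variable == "diameter", 1L, 0L)
    for (cn in c("mean", "sd", "min", "max")) {
      out[[cn]] <- round(out[[cn]], dg)
    }
  }
  out
}

#' Size-weighted pooled mean of group means
#'
#' @param group_means numeric vector of per-group means.
#' @param group_sizes integer vector of group sizes (same length, all >= 1).
#' @return The pooled (size-weighted) mean.
#' @export
pooled_mean <- function(group_means, group_sizes) {
  if (length(group_means) != length(group_sizes)) {
    stop("group_means and group_sizes must have equal length")
  }
  if (length(group_means) == 0L) stop("empty input")
  if (any(group_sizes < 1)) stop("group sizes must be >= 1")
  stats::weighted.mean(group_means, group_sizes)
}

#' Classic one-way ANOVA
#'
#' Equal-variance one-way analysis of variance across k groups: F statistic
#' with (k - 1, N - k) degrees of freedom and its p-value.
#'
#' @param groups list of numeric vectors, one per group (each length >= 2).
#' @return List with elements `F`, `p`, `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("each group needs at least 2 values")
  }
  if (all(vapply(groups, stats::var, 1) == 0)) {
    stop("all within-group variances are zero")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value),
       df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]))
}
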