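#' Age distribution of VA deaths
#'
#' Counts and percentages per age bin (including Unknown), the first
#' plausibility check: does the age pattern of the VA deaths make
#' demographic sense for the implementation area?
#'
#' @param records Data frame of VA records.
#' @param scheme An [age_scheme()].
#' @return A tibble of class `va_age_table`: `age_group`, `n`, `percent`
#'   (rounded to 1 decimal, so the column sums to 100 within rounding) and
#'   `fraction` (unrounded).
#' @export
age_distribution <- function(records, scheme = age_scheme()) {
  if (nrow(records) == 0) abort("No records.")
  bins <- bin_age(records$age_years, scheme)
  cnt <- table(bins)
  out <- tibble(age_group = names(cnt), n = as.integer(cnt),
                fraction = as.integer(cnt) / nrow(records))
  out$percent <- round(100 * out$fraction, 1)
  out <- out[c("age_group", "n", "percent", "fraction")]
  structure(out, class = c("va_age_table", class(out)), n_total = nrow(records))
}

#' Compare a VA age distribution with a reference
#'
#' Joins the VA age table with reference percentages per bin and reports the
#' absolute percentage-point difference per bin plus the index of
#' dissimilarity (half the sum of absolute differences, in \[0, 100\]).
#' A reference with no Unknown row is taken to have 0 percent there.
#'
#' @param va_table A `va_age_table` from [age_distribution()].
#' @param reference Data frame `age_group`, `percent` over the same bins.
#' @return A tibble of class `va_age_comparison`: `age_group`, `n`,
#'   `va_percent`, `ref_percent`, `abs_difference`; the dissimilarity index
#'   is in the `dissimilarity` attribute.
#' @export
compare_age <- function(va_table, reference) {
  reference <- as_tibble(reference)
  if (!all(c("age_group", "percent") %in% names(reference))) {
    abort("`reference` needs columns `age_group` and `percent`.")
  }
  if (!"Unknown" %in% reference$age_group) {
    reference <- bind_rows(reference, tibble(age_group = "Unknown", percent = 0))
  }
  if (!setequal(va_table$age_group, reference$age_group)) {
    odd <- union(setdiff(va_table$age_group, reference$age_group),
                 setdiff(reference$age_group, va_table$age_group))
    abort(paste0("Age bins differ between VA table and reference: ",
                 paste(odd, collapse = ", ")))
  }
  ref <- reference$percent[match(va_table$age_group, reference$age_group)]
  out <- tibble(age_group = va_table$age_group, n = va_table$n,
                va_percent = va_table$percent, ref_percent = ref,
                abs_difference = abs(va_table$percent - ref))
  structure(out, class = c("va_age_comparison", class(out)),
            dissimilarity = dissimilarity_index(va_table$percent, ref))
}

#' Index of dissimilarity between two percentage distributions
#'
#' Half the sum of absolute differences: 0 for identical distributions, 100
#' for distributions with disjoint support. Symmetric in its arguments.
#'
#' @param p,q Numeric vectors of percentages over the same categories.
#' @return A number in \[0, 100\].
#' @export
#' @examples
#' dissimilarity_index(c(60, 40), c(50, 50))
dissimilarity_index <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(p - q)) / 2
}

#' Compare broad-cause-group fractions with a reference
#'
#' Flags any group whose reference fraction lies outside the VA estimate's
#' confidence interval. The reference is a modelled comparator, not a gold
#' standard: flags are prompts for scrutiny, not verdicts.
#'
#' @param groups A `va_groups` from [broad_group_fractions()] (or any data
#'   frame with `group`, `fraction_after`, `ci_low`, `ci_high`); the
#'   undetermined row, if present, is dropped.
#' @param ref_groups Data frame `group`, `fraction` of reference fractions.
#' @return A tibble: `group`, `va_fraction`, `ci_low`, `ci_high`,
#'   `ref_fraction`, `flag` (`TRUE` when the reference is outside the CI).
#' @export
compare_broad_groups <- function(groups, ref_groups) {
  g <- as_tibble(groups) |> filter(.data$group != va_undetermined())
  ref_groups <- as_tibble(ref_groups)
  if (!setequal(g$group, ref_groups$group)) {
    abort("Group sets differ between VA estimate and reference.")
  }
  ref <- ref_groups$fraction[match(g$group, ref_groups$group)]
  out <- tibble(group = g$group, va_fraction = g$fraction_after,
                ci_low = g$ci_low, ci_high = g$ci_high, ref_fraction = ref,
                flag = !is.na(g$ci_low) & (ref < g$ci_low | ref > g$ci_high))
  structure(out, class = c("va_group_comparison", class(out)))
}

#' Fraction of deaths left undetermined
#'
#' @param predictions A `va_predictions` tibble.
#' @return The share of deaths assigned [va_undetermined()], in \[0, 1\].
#'   Field experience puts typical values around 0.05-0.2, falling as
#'   interviewers gain experience.
#' @export
undetermined_fraction <- function(predictions) {
  if (nrow(predictions) == 0) abort("No predictions.")
  mean(predictions$assigned_cause == va_undetermined())
}

#' Structured plausibility report
#'
#' Bundles the plausibility checks a mortality-statistics office should run
#' before trusting VA-derived CSMFs: the age distribution (against a
#' reference age pattern if given), the broad-cause comparison with
#' CI-exclusion flags, the undetermined fraction, and the sex ratio.
#' Registration-completeness assessment needs population denominators this
#' package does not model; the report prints a placeholder prompting for
#' external input. Report generation is pure: the same inputs produce a
#' byte-identical body.
#'
#' @param records VA records (for age and sex distributions).
#' @param predictions A `va_predictions` tibble.
#' @param groups Optional `va_groups` from [broad_group_fractions()].
#' @param ref_age Optional reference age distribution (`age_group`,
#'   `percent`).
#' @param ref_groups Optional reference group fractions (`group`,
#'   `fraction`).
#' @param scheme An [age_scheme()].
#' @return An object of class `va_plausibility` with fields `age`,
#'   `age_comparison`, `group_comparison`, `undetermined`, `sex_ratio`,
#'   `flags`; its print method renders markdown.
#' @export
plausibility_report <- function(records, predictions, groups = NULL,
                                ref_age = NULL, ref_groups = NULL,
                                scheme = age_scheme()) {
  age <- age_distribution(records, scheme)
  age_cmp <- if (!is.null(ref_age)) compare_age(age, ref_age)
  grp_cmp <- if (!is.null(groups) && !is.null(ref_groups))
    compare_broad_groups(groups, ref_groups)
  und <- undetermined_fraction(predictions)
  n_m <- sum(records$sex == "male")
  n_f <- sum(records$sex == "female")
  flags <- character()
  if (!is.null(grp_cmp) && any(grp_cmp$flag)) {
    flags <- c(flags, sprintf(
      "broad group '%s': reference fraction %.3f outside VA 95%% CI (%.3f, %.3f)",
      grp_cmp$group[grp_cmp$flag], grp_cmp$ref_fraction[grp_cmp$flag],
      grp_cmp$ci_low[grp_cmp$flag], grp_cmp$ci_high[grp_cmp$flag]))
  }
  if (!is.null(age_cmp)) {
    flags <- c(flags, sprintf("age index of dissimilarity vs reference: %.1f",
                              attr(age_cmp, "dissimilarity")))
  }
  structure(list(age = age, age_comparison = age_cmp,
                 group_comparison = grp_cmp,
                 undetermined = und,
                 sex_ratio = if (n_f > 0) n_m / n_f else NA_real_,
                 n_records = nrow(records), flags = flags),
            class = "va_plausibility")
}

#' @export
format.va_plausibility <- function(x, ...) {
  fmt_tbl <- function(df) {
    df <- as_tibble(df)
    df[] <- lapply(df, function(col) if (is.numeric(col)) format(col, digits = 4) else as.character(col))
    header <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    body <- apply(df, 1, paste, collapse = " | ")
    c(paste("|", header, "|"), paste("|", sep, "|"), paste("|", body, "|"))
  }
  out <- c("# VA plausibility report", "",
           sprintf("Deaths analysed: %d", x$n_records),
           sprintf("Undetermined fraction: %.3f", x$undetermined),
           sprintf("Sex ratio (male:female): %s",
                   ifelse(is.na(x$sex_ratio), "undefined", sprintf("%.2f", x$sex_ratio))),
           "", "## Age distribution", "",
           fmt_tbl(if (is.null(x$age_comparison)) x$age[c("age_group", "n", "percent")]
                   else x$age_comparison))
  if (!is.null(x$group_comparison)) {
    out <- c(out, "", "## Broad cause groups vs reference", "",
             fmt_tbl(x$group_comparison))
  }
  out <- c(out, "", "## Flags", "",
           if (length(x$flags)) paste("-", x$flags) else "- none", "",
           "## Registration completeness", "",
           paste("- not assessed: requires population denominators;",
                 "supply an external completeness estimate."))
  out
}

#' @export
print.va_plausibility <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write a plausibility report to disk
#'
#' Emits `plausibility.md` (the markdown body) plus machine-readable CSV
#' sections (`plausibility_age.csv`, and `plausibility_groups.csv` when a
#' group comparison is present).
#'
#' @param report A `va_plausibility`.
#' @param dir Output directory (created if needed).
#' @return The markdown path, invisibly.
#' @export
write_plausibility_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- file.path(dir, "plausibility.md")
  writeLines(format(report), md)
  age <- if (is.null(report$age_comparison)) report$age else report$age_comparison
  readr::write_csv(as_tibble(age), file.path(dir, "plausibility_age.csv"))
  if (!is.null(report$group_comparison)) {
    readr::write_csv(report$group_comparison, file.path(dir, "plausibility_groups.csv"))
  }
  invisible(md)
}
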