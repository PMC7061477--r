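#' Symptom schema
#'
#' A schema fixes the ordered set of symptom identifiers (one record-table
#' column per symptom) and their human-readable labels for the life of a
#' pipeline run. All scoring and validation refers to this ordering.
#'
#' @param symptom_ids Character vector of unique, non-empty symptom
#'   identifiers, in the column order used by record tables.
#' @param labels Optional human-readable label per identifier; defaults to
#'   the identifiers themselves.
#' @return An object of class `va_schema`.
#' @export
#' @examples
#' va_schema(c("cough", "fever"), c("Persistent cough", "High fever"))
va_schema <- function(symptom_ids, labels = symptom_ids) {
  symptom_ids <- as.character(symptom_ids)
  if (length(symptom_ids) == 0 || anyNA(symptom_ids) || any(!nzchar(symptom_ids))) {
    abort("`symptom_ids` must be non-empty strings.")
  }
  if (anyDuplicated(symptom_ids)) {
    abort(paste0("Duplicate symptom ids: ",
                 paste(unique(symptom_ids[duplicated(symptom_ids)]), collapse = ", ")))
  }
  if (length(labels) != length(symptom_ids)) {
    abort("`labels` must have one entry per symptom id.")
  }
  structure(list(symptom_ids = symptom_ids,
                 labels = set_names(as.character(labels), symptom_ids)),
            class = "va_schema")
}

#' @export
print.va_schema <- function(x, ...) {
  cat("<va_schema> ", length(x$symptom_ids), " symptoms: ",
      paste(head(x$symptom_ids, 6), collapse = ", "),
      if (length(x$symptom_ids) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Infer a symptom schema from a record table
#'
#' Every column that is not one of the reserved fields (`record_id`,
#' `age_years`, `sex`, `true_cause`) is taken to be a symptom column.
#'
#' @param records A data frame of VA records.
#' @return A [va_schema()].
#' @export
schema_from_records <- function(records) {
  ids <- setdiff(names(records), .va_reserved_cols)
  if (length(ids) == 0) abort("No symptom columns found in `records`.")
  va_schema(ids)
}

#' Cause list
#'
#' The ordered vocabulary of assignable causes. The reserved label
#' [va_undetermined()] is never part of it: it is an output category, not a
#' cause that can be trained on.
#'
#' @param cause_ids Character vector of unique cause identifiers.
#' @return A character vector of class `va_causes`.
#' @export
va_causes <- function(cause_ids) {
  cause_ids <- as.character(cause_ids)
  if (length(cause_ids) == 0 || anyNA(cause_ids) || any(!nzchar(cause_ids))) {
    abort("`cause_ids` must be non-empty strings.")
  }
  if (anyDuplicated(cause_ids)) abort("Cause ids must be unique.")
  if (va_undetermined() %in% cause_ids) {
    abort(sprintf("'%s' is reserved and cannot be a cause id.", va_undetermined()))
  }
  structure(cause_ids, class = c("va_causes", "character"))
}

#' Adult age-group scheme
#'
#' The default decennial adult binning used for age-distribution reporting
#' and stratified redistribution: 12-19, then ten-year bins to 79, then 80+,
#' with an explicit Unknown bin for missing ages. Bins are closed integer
#' ranges (12-19 means 12 <= age <= 19).
#'
#' @return A tibble of class `va_age_scheme` with columns `label`, `lower`,
#'   `upper`.
#' @export
#' @examples
#' age_scheme()
age_scheme <- function() {
  sch <- tibble(
    label = c("12-19", "20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+"),
    lower = c(12, 20, 30, 40, 50, 60, 70, 80),
    upper = c(19, 29, 39, 49, 59, 69, 79, Inf)
  )
  class(sch) <- c("va_age_scheme", class(sch))
  sch
}

#' Bin ages into age groups
#'
#' Deterministically maps integer ages (fractional ages are floored) to the
#' scheme's bins; `NA` ages map to `"Unknown"`.
#'
#' @param age_years Numeric vector of ages in years; `NA` means unknown.
#' @param scheme An [age_scheme()] (or a user scheme with disjoint,
#'   exhaustive integer bins).
#' @return A factor with the scheme's labels plus `"Unknown"`.
#' @export
#' @examples
#' bin_age(c(80, 29, 30, NA))
bin_age <- function(age_years, scheme = age_scheme()) {
  age <- floor(as.numeric(age_years))
  known <- !is.na(age)
  if (any(known & age < min(scheme$lower))) {
    bad <- age[known & age < min(scheme$lower)]
    abort(sprintf(
      "Age(s) below the adult module floor of %d: %s. Deaths under this age are outside the adult questionnaire.",
      min(scheme$lower), paste(unique(bad), collapse = ", ")))
  }
  levels <- c(scheme$label, "Unknown")
  out <- rep("Unknown", length(age))
  idx <- findInterval(age[known], scheme$lower)
  out[known] <- scheme$label[idx]
  factor(out, levels = levels)
}

#' Validate VA records against a schema
#'
#' Report-based validation: nothing is modified and nothing aborts; the
#' caller decides what to do with offending records. Checks performed:
#' duplicate `record_id`s, invalid `sex`, negative or under-floor ages,
#' endorsement values outside \{1, 0, NA\}, symptom columns not in the
#' schema, and schema symptoms missing from the table.
#'
#' @param records A data frame of VA records (see [read_va_records()] for
#'   the column contract).
#' @param schema A [va_schema()]; defaults to one inferred from `records`.
#' @param age_floor Minimum valid age in years (default 12, the first bin of
#'   [age_scheme()]).
#' @return A tibble of class `va_validation` with columns `record_id`
#'   (`NA` for table-level problems), `field`, `problem`; zero rows when the
#'   table is clean.
#' @export
validate_records <- function(records, schema = NULL, age_floor = 12) {
  records <- as_tibble(records)
  schema <- schema %||% schema_from_records(records)
  v <- list()
  add <- function(record_id, field, problem) {
    v[[length(v) + 1]] <<- tibble(record_id = as.character(record_id),
                                  field = field, problem = problem)
  }

  for (col in c("record_id", "age_years", "sex")) {
    if (!col %in% names(records)) add(NA, col, "mandatory column missing")
  }
  extra <- setdiff(setdiff(names(records), .va_reserved_cols), schema$symptom_ids)
  for (col in extra) add(NA, col, "symptom column not in schema")
  missing_sym <- setdiff(schema$symptom_ids, names(records))
  for (col in missing_sym) add(NA, col, "schema symptom missing from records")

  if ("record_id" %in% names(records)) {
    dup <- records$record_id[duplicated(records$record_id)]
    for (id in unique(dup)) add(id, "record_id", "duplicate record_id")
  }
  if ("sex" %in% names(records)) {
    bad <- !records$sex %in% c("male", "female", "unknown")
    for (i in which(bad)) {
      add(.rid(records, i), "sex",
          sprintf("invalid sex '%s' (must be male/female/unknown)", records$sex[i]))
    }
  }
  if ("age_years" %in% names(records)) {
    age <- suppressWarnings(as.numeric(records$age_years))
    bad <- !is.na(age) & age < age_floor
    for (i in which(bad)) {
      add(.rid(records, i), "age_years",
          sprintf("age %s below floor %d", format(age[i]), age_floor))
    }
  }
  for (s in intersect(schema$symptom_ids, names(records))) {
    vals <- records[[s]]
    bad <- !is.na(vals) & !vals %in% c(0, 1)
    for (i in which(bad)) {
      add(.rid(records, i), s, sprintf("endorsement value '%s' not in {1, 0, missing}", vals[i]))
    }
  }

  out <- if (length(v)) list_rbind(v) else
    tibble(record_id = character(), field = character(), problem = character())
  structure(out, class = c("va_validation", class(out)),
            n_records = nrow(records))
}

.rid <- function(records, i) {
  if ("record_id" %in% names(records)) records$record_id[i] else as.character(i)
}

#' @export
print.va_validation <- function(x, ...) {
  cat(sprintf("<va_validation> %d violation(s) across %d record(s)\n",
              nrow(x), attr(x, "n_records")))
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' Validate a reference age-sex-cause distribution table
#'
#' Checks that `reference` has columns `sex`, `age_group`, `cause_id`,
#' `fraction`, that fractions are non-negative, and that every
#' (sex, age_group) stratum sums to 1.
#'
#' @param reference A data frame (see [read_reference()]).
#' @param tol Tolerance on each stratum sum (default 1e-9).
#' @return `reference`, invisibly, as a tibble; aborts on violation.
#' @export
check_reference <- function(reference, tol = 1e-9) {
  reference <- as_tibble(reference)
  need <- c("sex", "age_group", "cause_id", "fraction")
  miss <- setdiff(need, names(reference))
  if (length(miss)) abort(paste0("Reference table missing column(s): ", paste(miss, collapse = ", ")))
  if (any(reference$fraction < 0)) abort("Reference fractions must be non-negative.")
  sums <- reference |>
    group_by(.data$sex, .data$age_group) |>
    summarise(s = sum(.data$fraction), .groups = "drop")
  bad <- sums |> filter(abs(.data$s - 1) > tol)
  if (nrow(bad)) {
    abort(sprintf("Reference stratum (%s, %s) sums to %.12f, not 1.",
                  bad$sex[1], bad$age_group[1], bad$s[1]))
  }
  invisible(reference)
}

#' Validate a cause-to-broad-group map
#'
#' The map must assign every cause in `causes` to exactly one broad group
#' (GBD level 1 style: communicable/maternal/nutritional; non-communicable;
#' injuries).
#'
#' @param map A data frame with columns `cause_id`, `group`.
#' @param causes Optional cause vocabulary the map must cover.
#' @return `map` as a tibble, invisibly; aborts on violation.
#' @export
check_broad_group_map <- function(map, causes = NULL) {
  map <- as_tibble(map)
  if (!all(c("cause_id", "group") %in% names(map))) {
    abort("Broad-group map needs columns `cause_id` and `group`.")
  }
  if (anyDuplicated(map$cause_id)) abort("Each cause must map to exactly one group.")
  if (!is.null(causes)) {
    miss <- setdiff(setdiff(causes, va_undetermined()), map$cause_id)
    if (length(miss)) {
      abort(paste0("Cause(s) missing from broad-group map: ", paste(miss, collapse = ", ")))
    }
  }
  invisible(map)
}
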