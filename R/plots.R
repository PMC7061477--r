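#' Plot a CSMF table
#'
#' Dodged bars of the cause-specific mortality fractions before and after
#' undetermined redistribution, with 95 percent bootstrap CIs on the
#' after-redistribution estimates.
#'
#' @param object A `va_csmf` from [csmf_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.va_csmf <- function(object, ...) {
  df <- as_tibble(unclass(object)[c("cause_id", "fraction_before",
                                    "fraction_after", "ci_low", "ci_high")]) |>
    pivot_longer(c("fraction_before", "fraction_after"),
                 names_to = "stage", values_to = "fraction") |>
    mutate(stage = factor(.data$stage, c("fraction_before", "fraction_after"),
                          c("before redistribution", "after redistribution")),
           ci_low = ifelse(.data$stage == "after redistribution", .data$ci_low, NA),
           ci_high = ifelse(.data$stage == "after redistribution", .data$ci_high, NA))
  ggplot(df, aes(x = stats::reorder(.data$cause_id, -.data$fraction),
                 y = .data$fraction, fill = .data$stage)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  position = position_dodge(width = 0.8), width = 0.25,
                  na.rm = TRUE) +
    labs(x = NULL, y = "cause-specific mortality fraction", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot broad-cause-group fractions against a reference
#'
#' @param object A comparison from [compare_broad_groups()].
#' @param ... Unused.
#' @return A ggplot: VA fractions with CIs as bars, reference fractions as
#'   points; flagged groups (reference outside the CI) in a warning colour.
#' @export
autoplot.va_group_comparison <- function(object, ...) {
  ggplot(object, aes(x = .data$group)) +
    geom_col(aes(y = .data$va_fraction, fill = .data$flag), width = 0.6) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.2,
                  na.rm = TRUE) +
    geom_point(aes(y = .data$ref_fraction), shape = 18, size = 3) +
    scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                      labels = c(`FALSE` = "consistent", `TRUE` = "flagged")) +
    labs(x = NULL, y = "fraction of deaths", fill = "vs reference",
         caption = "diamonds: reference fractions") +
    theme_minimal()
}

#' Plot a VA/reference age-distribution comparison
#'
#' @param object A `va_age_comparison` from [compare_age()].
#' @param ... Unused.
#' @return A ggplot of paired bars per age bin.
#' @export
autoplot.va_age_comparison <- function(object, ...) {
  df <- as_tibble(object) |>
    pivot_longer(c("va_percent", "ref_percent"),
                 names_to = "source", values_to = "percent") |>
    mutate(source = factor(.data$source, c("va_percent", "ref_percent"),
                           c("VA deaths", "reference")),
           age_group = factor(.data$age_group, unique(object$age_group)))
  ggplot(df, aes(x = .data$age_group, y = .data$percent, fill = .data$source)) +
    geom_col(position = "dodge") +
    labs(x = "age group (years)", y = "percent of deaths", fill = NULL) +
    theme_minimal()
}

#' Plot a tariff matrix as a heatmap
#'
#' @param object A `va_tariffs` from [compute_tariffs()].
#' @param ... Unused.
#' @return A ggplot tile map of tariff scores (zero-valued cells blank out
#'   visually under the diverging scale).
#' @export
autoplot.va_tariffs <- function(object, ...) {
  df <- tidy(object) |>
    mutate(cause_id = factor(.data$cause_id, rev(object$causes)),
           symptom_id = factor(.data$symptom_id, object$schema$symptom_ids))
  ggplot(df, aes(x = .data$symptom_id, y = .data$cause_id, fill = .data$tariff)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "symptom", y = "cause", fill = "tariff") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6))
}

#' @export
autoplot.va_groups <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$group != va_undetermined())
  ggplot(df, aes(x = .data$group, y = .data$fraction_after)) +
    geom_col(fill = "grey60", width = 0.6) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.2,
                  na.rm = TRUE) +
    geom_point(aes(y = .data$fraction_before), shape = 1, size = 3) +
    labs(x = NULL, y = "fraction of deaths",
         caption = "bars: after redistribution (95% CI); circles: before") +
    theme_minimal()
}
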