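# Shared fixtures and independent oracles, all built in code.

# hand-rolled inclusive linear-interpolation quantile (order-statistic
# interpolation), independent of stats::quantile
oracle_quantile <- function(v, p) {
  s <- unname(sort(v))
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# brute-force tariff of one endorsement matrix (no rounding/truncation)
oracle_tariffs <- function(x) {
  t_mat <- x * 0
  for (s in seq_len(ncol(x))) {
    med <- oracle_quantile(x[, s], 0.5)
    iqr <- oracle_quantile(x[, s], 0.75) - oracle_quantile(x[, s], 0.25)
    t_mat[, s] <- if (iqr == 0) 0 else (x[, s] - med) / iqr
  }
  t_mat
}

# a tiny handmade gold standard: 3 causes with exclusive signature symptoms
tiny_gold <- function(per_cause = 4) {
  causes <- c("a", "b", "c")
  rows <- list()
  for (ci in seq_along(causes)) {
    for (r in seq_len(per_cause)) {
      e <- rep(0L, 6)
      e[(2 * ci - 1):(2 * ci)] <- 1L
      rows[[length(rows) + 1]] <- tibble::tibble(
        record_id = sprintf("%s%d", causes[ci], r),
        age_years = 40 + 10 * ci, sex = c("male", "female")[1 + r %% 2],
        s1 = e[1], s2 = e[2], s3 = e[3], s4 = e[4], s5 = e[5], s6 = e[6],
        true_cause = causes[ci])
    }
  }
  dplyr::bind_rows(rows)
}

# build a va_tariffs object directly from a matrix (for hand-built scenarios)
make_tariffs <- function(t_mat) {
  structure(list(t = t_mat, schema = tariffva::va_schema(colnames(t_mat)),
                 causes = rownames(t_mat),
                 metadata = list(round_to = NA_real_, top_k = NA_integer_,
                                 quantile_convention = "inclusive linear interpolation (type 7)",
                                 significance_filtering = "unavailable")),
            class = "va_tariffs")
}

# build a va_fit from parts (hand-built baselines etc.)
make_fit <- function(tariffs, baseline, policy = tariffva::cutoff_policy(),
                     restrictions = NULL) {
  structure(list(schema = tariffs$schema, causes = tariffs$causes,
                 endorsement = NULL, tariffs = tariffs, baseline = baseline,
                 policy = policy, restrictions = restrictions,
                 n_train = NA_integer_, seed = NA_integer_),
            class = "va_fit")
}

make_baseline <- function(score_matrix) {
  structure(list(scores = apply(score_matrix, 2, sort, decreasing = TRUE),
                 per_cause_n = NA_integer_, seed = NA_integer_),
            class = "va_baseline")
}

# predictions tibble with a given number of deaths per assigned cause,
# all in one (sex, age_group) stratum
make_predictions <- function(counts, sex = "female", age_group = "50-59") {
  tibble::tibble(
    record_id = sprintf("r%04d", seq_len(sum(counts))),
    sex = sex,
    age_group = factor(age_group, levels = c(tariffva::age_scheme()$label, "Unknown")),
    assigned_cause = rep(names(counts), counts))
}

# single-stratum reference table over the given cause fractions
make_reference <- function(fractions, sexes = c("male", "female")) {
  purrr::map(sexes, function(sx) {
    purrr::map(tariffva::age_scheme()$label, function(ag) {
      tibble::tibble(sex = sx, age_group = ag,
                     cause_id = names(fractions), fraction = unname(fractions))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}
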