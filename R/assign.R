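#' Cutoff policy for undetermined-cause decisions
#'
#' A record is left undetermined when its best candidate cause is not
#' convincing enough: (a) the candidate's rank against the resampled
#' gold-standard baseline exceeds `rank_quantile_cutoff` times the baseline
#' size, (b) the candidate's score falls below `minimum_score`, or (c) the
#' rank exceeds `overall_rank_cap` times the baseline size. Defaults mirror
#' the public adult configuration of the tariff method and are fully
#' overridable; the thresholds are deployment calibrations, not constants of
#' the method.
#'
#' @param rank_quantile_cutoff Fraction of the baseline a candidate's rank
#'   may not exceed (default 0.89).
#' @param minimum_score Minimum candidate tariff score (default 0).
#' @param overall_rank_cap Hard cap as a fraction of the baseline size
#'   (default 1, i.e. inactive).
#' @return An object of class `va_cutoff_policy`.
#' @export
cutoff_policy <- function(rank_quantile_cutoff = 0.89, minimum_score = 0,
                          overall_rank_cap = 1) {
  stopifnot(is.finite(rank_quantile_cutoff), rank_quantile_cutoff > 0,
            rank_quantile_cutoff <= 1, is.finite(minimum_score),
            is.finite(overall_rank_cap), overall_rank_cap > 0)
  structure(list(rank_quantile_cutoff = rank_quantile_cutoff,
                 minimum_score = minimum_score,
                 overall_rank_cap = overall_rank_cap),
            class = "va_cutoff_policy")
}

#' Build the rank baseline from a gold-standard database
#'
#' Resamples, with replacement, `per_cause_n` records of every cause
#' (uniform cause composition, so the baseline does not inherit the gold
#' standard's cause mix), scores the pooled resample with the tariff matrix,
#' and stores each cause's pooled score list sorted in descending order.
#' Field records are then ranked within these lists.
#'
#' @param gold Gold-standard data frame (must cover every tariff cause).
#' @param tariffs A `va_tariffs`.
#' @param per_cause_n Resampled records per cause (default 100).
#' @param seed Integer seed; the resample is reproducible given it.
#' @return An object of class `va_baseline`: `scores` (pool-size by cause
#'   matrix, each column sorted descending), `per_cause_n`, `seed`.
#' @export
rank_baseline <- function(gold, tariffs, per_cause_n = 100, seed = 1) {
  gold <- as_tibble(gold)
  if (nrow(gold) == 0) abort("Gold-standard database is empty.")
  stopifnot(per_cause_n >= 1)
  causes <- tariffs$causes
  idx_by_cause <- split(seq_len(nrow(gold)), factor(gold$true_cause, levels = causes))
  empty <- names(idx_by_cause)[lengths(idx_by_cause) == 0]
  if (length(empty)) {
    abort(paste0("Gold standard has no records for cause(s): ",
                 paste(empty, collapse = ", ")))
  }
  pool <- withr::with_seed(seed, {
    unlist(lapply(idx_by_cause, function(ix) {
      ix[sample.int(length(ix), per_cause_n, replace = TRUE)]
    }), use.names = FALSE)
  })
  S <- .score_matrix(gold[pool, , drop = FALSE], tariffs)
  S <- apply(S, 2, sort, decreasing = TRUE)
  colnames(S) <- causes
  structure(list(scores = S, per_cause_n = per_cause_n, seed = seed),
            class = "va_baseline")
}

#' @export
print.va_baseline <- function(x, ...) {
  cat(sprintf("<va_baseline> pool of %d resampled gold-standard deaths (%d per cause), seed %d\n",
              nrow(x$scores), x$per_cause_n, x$seed))
  invisible(x)
}

#' Rank a score within a baseline score list
#'
#' Rank 1 is best. The rank is one plus the number of baseline scores
#' strictly greater than the record's score, so ties are broken in the
#' record's favour.
#'
#' @param score Numeric vector of scores.
#' @param baseline_list Numeric baseline scores sorted in descending order.
#' @return Integer ranks, one per score.
#' @export
#' @examples
#' rank_score(c(10, 5, 4.5), c(9, 7, 5, 5, 1))
rank_score <- function(score, baseline_list) {
  n <- length(baseline_list)
  if (n == 0) abort("`baseline_list` must be non-empty.")
  asc <- rev(baseline_list)
  as.integer(1L + n - findInterval(score, asc))
}

# ranks of every record (rows) within every cause's baseline column
.rank_matrix <- function(S, baseline) {
  R <- matrix(0L, nrow(S), ncol(S), dimnames = dimnames(S))
  for (j in seq_len(ncol(S))) {
    R[, j] <- rank_score(S[, j], baseline$scores[, j])
  }
  R
}

# logical records x causes eligibility under demographic restrictions
.eligibility_matrix <- function(records, causes, restrictions) {
  E <- matrix(TRUE, nrow(records), length(causes),
              dimnames = list(NULL, causes))
  if (is.null(restrictions) || nrow(restrictions) == 0) return(E)
  age <- suppressWarnings(as.numeric(records$age_years))
  sex <- records$sex
  for (k in seq_len(nrow(restrictions))) {
    cz <- restrictions$cause_id[k]
    if (!cz %in% causes) next
    ok <- rep(TRUE, nrow(records))
    if (!is.na(restrictions$sex[k]) && nzchar(restrictions$sex[k])) {
      # records of unknown sex stay eligible everywhere
      ok <- ok & (sex == restrictions$sex[k] | sex == "unknown")
    }
    if (!is.na(restrictions$age_min[k])) ok <- ok & (is.na(age) | age >= restrictions$age_min[k])
    if (!is.na(restrictions$age_max[k])) ok <- ok & (is.na(age) | age <= restrictions$age_max[k])
    E[, cz] <- E[, cz] & ok
  }
  E
}

#' Train a tariff pipeline
#'
#' One-stop constructor bundling everything assignment needs: endorsement
#' rates, the tariff matrix, the rank baseline, the cutoff policy and any
#' demographic restrictions.
#'
#' @inheritParams endorsement_rates
#' @inheritParams compute_tariffs
#' @inheritParams rank_baseline
#' @param policy A [cutoff_policy()].
#' @param restrictions Optional data frame `cause_id, sex, age_min, age_max`
#'   of demographic eligibility rules (e.g. maternal causes female-only,
#'   ages 12-49). Shipped as editable data, see
#'   `system.file("extdata", "cause_restrictions.csv", package = "tariffva")`.
#' @return An object of class `va_fit`.
#' @export
va_train <- function(gold, schema = NULL, causes = NULL,
                     policy = cutoff_policy(), restrictions = NULL,
                     per_cause_n = 100, round_to = 0.5, top_k = 40, seed = 1) {
  gold <- as_tibble(gold)
  schema <- schema %||% schema_from_records(gold)
  em <- endorsement_rates(gold, schema, causes)
  tf <- compute_tariffs(em, round_to = round_to, top_k = top_k)
  bl <- rank_baseline(gold, tf, per_cause_n = per_cause_n, seed = seed)
  structure(list(schema = schema, causes = tf$causes, endorsement = em,
                 tariffs = tf, baseline = bl, policy = policy,
                 restrictions = restrictions, n_train = nrow(gold), seed = seed),
            class = "va_fit")
}

#' @export
print.va_fit <- function(x, ...) {
  cat(sprintf("<va_fit> %d causes, %d symptoms, %d gold-standard deaths; baseline pool %d\n",
              length(x$causes), length(x$schema$symptom_ids), x$n_train,
              nrow(x$baseline$scores)))
  invisible(x)
}

#' @export
tidy.va_fit <- function(x, ...) tidy(x$tariffs)

#' @export
glance.va_fit <- function(x, ...) {
  tibble(n_causes = length(x$causes),
         n_symptoms = length(x$schema$symptom_ids),
         n_train = x$n_train,
         baseline_pool = nrow(x$baseline$scores),
         rank_quantile_cutoff = x$policy$rank_quantile_cutoff,
         minimum_score = x$policy$minimum_score,
         overall_rank_cap = x$policy$overall_rank_cap,
         round_to = x$tariffs$metadata$round_to,
         top_k = x$tariffs$metadata$top_k,
         seed = x$seed)
}

#' Assign an individual cause (or undetermined) to each record
#'
#' Each record is scored against every cause and ranked within each cause's
#' baseline score list; the candidate is the eligible cause with the lowest
#' rank (ties: higher score, then cause-list order). The candidate is
#' replaced by [va_undetermined()] when any cutoff rule fires (see
#' [cutoff_policy()]) or when no cause is demographically eligible. The
#' `k` best-ranked causes are also reported for decision support.
#'
#' @param records Data frame of validated VA records.
#' @param fit A `va_fit` from [va_train()].
#' @param k Number of top candidate causes to report (default 3).
#' @return A tibble of class `va_predictions`: `record_id`, `sex`,
#'   `age_group`, `assigned_cause`, then `cause1, score1, rank1, ...` up to
#'   `k` (or the number of eligible causes, if fewer).
#' @export
assign_causes <- function(records, fit, k = 3) {
  records <- as_tibble(records)
  S <- .score_matrix(records, fit$tariffs)
  R <- .rank_matrix(S, fit$baseline)
  E <- .eligibility_matrix(records, fit$causes, fit$restrictions)
  N <- nrow(fit$baseline$scores)
  p <- fit$policy
  kk <- min(k, length(fit$causes))

  n <- nrow(records)
  assigned <- character(n)
  top_cause <- matrix(NA_character_, n, kk)
  top_score <- matrix(NA_real_, n, kk)
  top_rank <- matrix(NA_integer_, n, kk)
  for (i in seq_len(n)) {
    elig <- which(E[i, ])
    if (length(elig) == 0) {
      assigned[i] <- va_undetermined()
      next
    }
    ord <- elig[order(R[i, elig], -S[i, elig])]  # stable: cause order breaks ties
    take <- head(ord, kk)
    top_cause[i, seq_along(take)] <- fit$causes[take]
    top_score[i, seq_along(take)] <- S[i, take]
    top_rank[i, seq_along(take)] <- R[i, take]
    cand <- ord[1]
    undet <- R[i, cand] > p$rank_quantile_cutoff * N ||
      S[i, cand] < p$minimum_score ||
      R[i, cand] > p$overall_rank_cap * N
    assigned[i] <- if (undet) va_undetermined() else fit$causes[cand]
  }

  out <- tibble(record_id = as.character(records$record_id),
                sex = records$sex,
                age_group = bin_age(records$age_years),
                assigned_cause = assigned)
  for (j in seq_len(kk)) {
    out[[paste0("cause", j)]] <- top_cause[, j]
    out[[paste0("score", j)]] <- top_score[, j]
    out[[paste0("rank", j)]] <- top_rank[, j]
  }
  class(out) <- c("va_predictions", class(out))
  out
}

#' Top-k candidate causes in long form
#'
#' The decision-support view: for each record, the `k` best-ranked eligible
#' causes with their scores and baseline ranks, one row per candidate,
#' ignoring the undetermined rules.
#'
#' @inheritParams assign_causes
#' @return A tibble: `record_id`, `rank_order` (1 = best), `cause_id`,
#'   `score`, `rank`.
#' @export
top_causes <- function(records, fit, k = 3) {
  preds <- assign_causes(records, fit, k = k)
  kk <- sum(grepl("^cause[0-9]+$", names(preds)))
  purrr::map(seq_len(kk), function(j) {
    tibble(record_id = preds$record_id,
           rank_order = j,
           cause_id = preds[[paste0("cause", j)]],
           score = preds[[paste0("score", j)]],
           rank = preds[[paste0("rank", j)]])
  }) |>
    list_rbind() |>
    filter(!is.na(.data$cause_id)) |>
    arrange(.data$record_id, .data$rank_order)
}
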