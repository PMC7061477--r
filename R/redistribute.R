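#' Undetermined-propensity weights from per-cause counts
#'
#' Some causes (pneumonia is the classic example) are inherently harder to
#' diagnose from symptoms and end up undetermined more often. The fractional
#' redistribution weight for cause c is proportional to the rate at which
#' gold-standard deaths of true cause c were left undetermined by the
#' pipeline. When nothing is ever undetermined the weights fall back to
#' uniform, with a warning.
#'
#' @param n_undetermined Named integer vector: gold-standard deaths of each
#'   cause assigned undetermined.
#' @param n_total Named integer vector: gold-standard deaths per cause.
#' @return A tibble of class `va_frac_weights`: `cause_id`, `n`,
#'   `n_undetermined`, `rate`, `weight` (weights sum to 1).
#' @export
#' @examples
#' fractional_weights_from_counts(c(a = 2, b = 1, c = 0), c(a = 10, b = 10, c = 10))
fractional_weights_from_counts <- function(n_undetermined, n_total) {
  causes <- names(n_total)
  stopifnot(!is.null(causes), all(names(n_undetermined) %in% causes))
  n_und <- set_names(rep(0, length(causes)), causes)
  n_und[names(n_undetermined)] <- n_undetermined
  rate <- n_und / n_total
  uniform <- sum(rate) == 0
  if (uniform) {
    warn("No gold-standard death was assigned undetermined; falling back to uniform fractional weights.")
    w <- rep(1 / length(causes), length(causes))
  } else {
    w <- rate / sum(rate)
  }
  out <- tibble(cause_id = causes, n = as.integer(n_total),
                n_undetermined = as.integer(n_und), rate = unname(rate),
                weight = unname(w))
  structure(out, class = c("va_frac_weights", class(out)),
            fallback_uniform = uniform)
}

#' Estimate undetermined-propensity weights from a gold-standard database
#'
#' Runs every gold-standard record through the assignment pipeline and
#' counts, per true cause, how often the pipeline returns undetermined. By
#' default this is done by 5-fold cross-validation (each record is assigned
#' by a pipeline trained without it) to avoid resubstitution bias;
#' `method = "insample"` trains once on everything.
#'
#' @param gold Gold-standard data frame.
#' @param method `"cv"` (default) or `"insample"`.
#' @param folds Number of cross-validation folds (default 5). Every cause
#'   needs at least `2` records for cross-validation.
#' @param seed Integer seed controlling fold assignment and baselines.
#' @param ... Passed to [va_train()] (policy, per_cause_n, round_to, ...).
#' @return A `va_frac_weights` tibble (see
#'   [fractional_weights_from_counts()]).
#' @export
fractional_weights <- function(gold, method = c("cv", "insample"), folds = 5,
                               seed = 1, ...) {
  method <- match.arg(method)
  gold <- as_tibble(gold)
  causes <- unique(gold$true_cause)
  if (method == "insample") {
    fit <- va_train(gold, seed = seed, ...)
    preds <- assign_causes(gold, fit, k = 1)
    und <- preds$assigned_cause == va_undetermined()
  } else {
    n_per <- table(gold$true_cause)
    if (any(n_per < 2)) {
      abort(paste0("Cross-validated fractional weights need >= 2 gold records per cause; ",
                   "use method = \"insample\" for: ",
                   paste(names(n_per)[n_per < 2], collapse = ", ")))
    }
    fold_of <- integer(nrow(gold))
    withr::with_seed(seed, {
      for (ix in split(seq_len(nrow(gold)), gold$true_cause)) {
        fold_of[ix] <- sample(rep_len(seq_len(folds), length(ix)))
      }
    })
    und <- logical(nrow(gold))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      fit <- va_train(gold[!test, , drop = FALSE],
                      causes = va_causes(causes), seed = seed + f, ...)
      preds <- assign_causes(gold[test, , drop = FALSE], fit, k = 1)
      und[test] <- preds$assigned_cause == va_undetermined()
    }
  }
  n_tot <- table(factor(gold$true_cause, levels = causes))
  n_und <- tapply(und, factor(gold$true_cause, levels = causes), sum)
  fractional_weights_from_counts(
    set_names(as.integer(n_und), causes),
    set_names(as.integer(n_tot), causes)
  )
}

#' Reference redistribution weights for one demographic stratum
#'
#' Looks up a (sex, age-group) stratum of a reference age-sex cause
#' distribution (GBD-style) and renormalises its fractions over the causes
#' the VA cause list can actually assign. Records of unknown sex use the
#' mean of the male and female strata; records of unknown age use the
#' all-age marginal (mean over age groups).
#'
#' @param reference Reference table: `sex`, `age_group`, `cause_id`,
#'   `fraction` (see [check_reference()]).
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param age_group An [age_scheme()] label or `"Unknown"`.
#' @param causes Character vector of assignable causes to renormalise over.
#' @return Named numeric weight vector over `causes`, summing to 1.
#' @export
reference_weights <- function(reference, sex, age_group, causes) {
  reference <- as_tibble(reference)
  sexes <- if (identical(sex, "unknown")) c("male", "female") else sex
  sub <- reference |> filter(.data$sex %in% sexes)
  if (!identical(as.character(age_group), "Unknown")) {
    sub <- sub |> filter(.data$age_group == !!as.character(age_group))
  }
  if (nrow(sub) == 0) {
    abort(sprintf("Reference distribution has no stratum for (sex = %s, age_group = %s).",
                  sex, age_group))
  }
  # mean over the contributing strata (sex fallback and/or all-age marginal)
  w <- sub |>
    group_by(.data$sex, .data$age_group) |>
    mutate(.f = .data$fraction / sum(.data$fraction)) |>
    group_by(.data$cause_id) |>
    summarise(fraction = mean(.data$.f), .groups = "drop")
  out <- set_names(rep(0, length(causes)), causes)
  hit <- intersect(w$cause_id, causes)
  out[hit] <- w$fraction[match(hit, w$cause_id)]
  if (sum(out) == 0) {
    abort(sprintf("Reference stratum (%s, %s) has no mass on any assignable cause.",
                  sex, age_group))
  }
  out / sum(out)
}

#' Redistribute undetermined deaths across causes
#'
#' Undetermined deaths are reallocated at the population level only;
#' individual predictions are never altered. Within each (sex, age-group)
#' stratum the redistribution weight for cause c combines the gold-standard
#' undetermined-propensity weight with the stratum's reference weight:
#' \deqn{w_c = \lambda\, w^{frac}_c + (1 - \lambda)\, w^{ref}_c}
#' renormalised; the default `lambda = 0.5` is the unweighted average of the
#' two. Each stratum's undetermined count is then spread over causes in
#' proportion to the combined weights, and strata are summed for the
#' population totals.
#'
#' @param predictions A `va_predictions` tibble from [assign_causes()].
#' @param w_frac A `va_frac_weights` tibble or a named weight vector over
#'   causes.
#' @param reference Reference distribution table (see
#'   [reference_weights()]).
#' @param lambda Mixing weight on the fractional component in \[0, 1\];
#'   1 = pure gold-standard propensity, 0 = pure reference.
#' @return An object of class `va_redistribution`: `by_stratum` (tibble
#'   `sex, age_group, cause_id, w_frac, w_ref, combined, added`), `added`
#'   (named per-cause totals), `total_redistributed`, `stratum_weights`
#'   (strata by cause matrix of combined weights, reused by the bootstrap),
#'   `lambda`.
#' @export
redistribute <- function(predictions, w_frac, reference, lambda = 0.5) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (inherits(w_frac, "va_frac_weights")) {
    wf <- set_names(w_frac$weight, w_frac$cause_id)
  } else {
    stopifnot(!is.null(names(w_frac)), all(w_frac >= 0))
    wf <- w_frac / sum(w_frac)
  }
  causes <- names(wf)
  und <- predictions |>
    filter(.data$assigned_cause == va_undetermined()) |>
    count(.data$sex, .data$age_group, name = "n_undetermined")

  if (nrow(und) == 0) {
    by_stratum <- tibble(sex = character(), age_group = character(),
                         cause_id = character(), w_frac = numeric(),
                         w_ref = numeric(), combined = numeric(),
                         added = numeric())
    return(structure(list(by_stratum = by_stratum,
                          added = set_names(rep(0, length(causes)), causes),
                          total_redistributed = 0,
                          stratum_weights = matrix(0, 0, length(causes),
                                                   dimnames = list(NULL, causes)),
                          lambda = lambda),
                     class = "va_redistribution"))
  }

  W <- matrix(0, nrow(und), length(causes),
              dimnames = list(paste(und$sex, und$age_group, sep = "|"), causes))
  rows <- vector("list", nrow(und))
  for (i in seq_len(nrow(und))) {
    wr <- reference_weights(reference, und$sex[i], as.character(und$age_group[i]), causes)
    comb <- lambda * wf + (1 - lambda) * wr
    comb <- comb / sum(comb)
    W[i, ] <- comb
    rows[[i]] <- tibble(sex = und$sex[i],
                        age_group = as.character(und$age_group[i]),
                        cause_id = causes,
                        w_frac = unname(wf), w_ref = unname(wr),
                        combined = unname(comb),
                        added = unname(comb) * und$n_undetermined[i])
  }
  by_stratum <- list_rbind(rows)
  added <- by_stratum |>
    group_by(.data$cause_id) |>
    summarise(added = sum(.data$added), .groups = "drop")
  added_vec <- set_names(rep(0, length(causes)), causes)
  added_vec[added$cause_id] <- added$added
  structure(list(by_stratum = by_stratum, added = added_vec,
                 total_redistributed = sum(und$n_undetermined),
                 stratum_weights = W, lambda = lambda),
            class = "va_redistribution")
}

#' @export
print.va_redistribution <- function(x, ...) {
  cat(sprintf("<va_redistribution> %g undetermined death(s) reallocated over %d cause(s) in %d stratum(um/a), lambda = %g\n",
              x$total_redistributed, length(x$added), nrow(x$stratum_weights), x$lambda))
  invisible(x)
}

#' @export
tidy.va_redistribution <- function(x, ...) x$by_stratum
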