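#' Cause-specific mortality fractions from individual predictions
#'
#' The before-redistribution CSMF: the share of deaths assigned each cause,
#' with undetermined kept as its own category.
#'
#' @param predictions A `va_predictions` tibble (or any data frame with an
#'   `assigned_cause` column).
#' @param causes Optional cause universe (undetermined is appended
#'   automatically); defaults to the causes observed.
#' @return A tibble: `cause_id`, `n_assigned`, `fraction`.
#' @export
csmf <- function(predictions, causes = NULL) {
  if (nrow(predictions) == 0) abort("Cannot aggregate an empty prediction set.")
  causes <- causes %||% setdiff(unique(predictions$assigned_cause), va_undetermined())
  lev <- c(setdiff(causes, va_undetermined()), va_undetermined())
  cnt <- table(factor(predictions$assigned_cause, levels = lev))
  tibble(cause_id = lev, n_assigned = as.integer(cnt),
         fraction = as.integer(cnt) / nrow(predictions))
}

#' CSMF table with redistribution and bootstrap confidence intervals
#'
#' The population-level summary: per cause the fraction of deaths before
#' redistribution (undetermined as its own category) and after redistribution
#' (undetermined mass reallocated, so its after-fraction is 0), with
#' 95 percent percentile-bootstrap confidence intervals on the
#' after-redistribution fractions. Bootstrapping resamples deaths with
#' replacement and redoes the stratified redistribution arithmetic in every
#' replicate, so every replicate's fractions still sum to 1.
#'
#' @param predictions A `va_predictions` tibble.
#' @param redistribution A `va_redistribution` from [redistribute()]
#'   computed from the same prediction set; may be `NULL` only when no
#'   death is undetermined.
#' @param B Bootstrap replicates (default 1000); `ci = FALSE` skips the
#'   bootstrap.
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @param seed Integer seed for the bootstrap resampling.
#' @param ci Compute confidence intervals? (default `TRUE`)
#' @return A tibble of class `va_csmf`: `cause_id`, `n_assigned`,
#'   `fraction_before`, `fraction_after`, `ci_low`, `ci_high`. Attributes:
#'   `n`, `B`, `alpha`, `seed`, `boot` (replicate-by-cause matrix of
#'   after-redistribution fractions), `ci_method`.
#' @export
csmf_table <- function(predictions, redistribution = NULL, B = 1000,
                       alpha = 0.05, seed = 1, ci = TRUE) {
  if (nrow(predictions) == 0) abort("Cannot aggregate an empty prediction set.")
  n <- nrow(predictions)
  n_und <- sum(predictions$assigned_cause == va_undetermined())
  if (is.null(redistribution)) {
    if (n_und > 0) {
      abort("Predictions contain undetermined deaths: supply a `redistribution` result.")
    }
    causes <- setdiff(unique(predictions$assigned_cause), va_undetermined())
    redistribution <- structure(
      list(by_stratum = tibble(), added = set_names(rep(0, length(causes)), causes),
           total_redistributed = 0,
           stratum_weights = matrix(0, 0, length(causes), dimnames = list(NULL, causes)),
           lambda = NA_real_),
      class = "va_redistribution")
  }
  causes <- names(redistribution$added)
  if (abs(redistribution$total_redistributed - n_und) > 1e-9) {
    abort("`redistribution` was not computed from this prediction set (undetermined counts differ).")
  }
  before <- csmf(predictions, causes)
  after_counts <- before$n_assigned[match(causes, before$cause_id)] + redistribution$added
  after <- c(after_counts / n, 0)  # undetermined reallocated to zero

  out <- tibble(cause_id = before$cause_id,
                n_assigned = before$n_assigned,
                fraction_before = before$fraction,
                fraction_after = unname(after),
                ci_low = NA_real_, ci_high = NA_real_)

  boot <- NULL
  if (ci) {
    boot <- .bootstrap_after(predictions, redistribution, causes, B, seed)
    qs <- apply(boot, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                names = FALSE, type = 7)
    out$ci_low <- c(unname(qs[1, ]), 0)
    out$ci_high <- c(unname(qs[2, ]), 0)
  }
  structure(out, class = c("va_csmf", class(out)),
            n = n, B = if (ci) B else NA_integer_, alpha = alpha, seed = seed,
            boot = boot, lambda = redistribution$lambda,
            ci_method = "percentile bootstrap over deaths")
}

# B x causes matrix of after-redistribution fractions under resampling
.bootstrap_after <- function(predictions, redistribution, causes, B, seed) {
  n <- nrow(predictions)
  W <- redistribution$stratum_weights
  cause_idx <- match(predictions$assigned_cause, causes)  # NA for undetermined
  strat_idx <- rep(NA_integer_, n)
  if (nrow(W) > 0) {
    key <- paste(predictions$sex, predictions$age_group, sep = "|")
    is_und <- predictions$assigned_cause == va_undetermined()
    strat_idx[is_und] <- match(key[is_und], rownames(W))
  }
  nc <- length(causes)
  ns <- nrow(W)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cc <- tabulate(cause_idx[idx], nbins = nc)
      if (ns > 0) {
        us <- tabulate(strat_idx[idx], nbins = ns)
        cc <- cc + as.vector(crossprod(W, us))
      }
      cc / n
    }, numeric(nc))
  })
  out <- matrix(reps, nrow = B, ncol = nc, byrow = TRUE)
  colnames(out) <- causes
  out
}

#' @export
print.va_csmf <- function(x, ...) {
  cat(sprintf("<va_csmf> %d deaths; B = %s bootstrap replicates (%s)\n",
              attr(x, "n"), format(attr(x, "B")), attr(x, "ci_method")))
  NextMethod()
}

#' @export
tidy.va_csmf <- function(x, ...) as_tibble(unclass(x)[names(x)])

#' @export
glance.va_csmf <- function(x, ...) {
  und <- x$fraction_before[x$cause_id == va_undetermined()]
  tibble(n = attr(x, "n"), B = attr(x, "B"), alpha = attr(x, "alpha"),
         undetermined_fraction = if (length(und)) und else 0,
         lambda = attr(x, "lambda"),
         ranking_stable = cause_ranking_stable(x))
}

#' Broad-cause-group fractions
#'
#' Collapses a CSMF table to broad cause groups (GBD level-1 style). In the
#' before-redistribution view the undetermined category is kept as its own
#' group; after redistribution groups sum to 1. Group CIs reuse the cause
#' bootstrap replicates of the table.
#'
#' @param table A `va_csmf` from [csmf_table()].
#' @param map Data frame `cause_id`, `group` mapping every assignable cause
#'   to exactly one group.
#' @return A tibble of class `va_groups`: `group`, `fraction_before`,
#'   `fraction_after`, `ci_low`, `ci_high` (boot replicates carried in the
#'   `boot` attribute).
#' @export
broad_group_fractions <- function(table, map) {
  causes <- setdiff(table$cause_id, va_undetermined())
  check_broad_group_map(map, causes)
  grp <- map$group[match(causes, map$cause_id)]
  groups <- unique(map$group)
  alpha <- attr(table, "alpha") %||% 0.05

  real <- table |> filter(.data$cause_id != va_undetermined())
  agg <- function(v) vapply(groups, function(g) sum(v[grp == g]), numeric(1))
  before <- agg(real$fraction_before)
  after <- agg(real$fraction_after)
  und_before <- table$fraction_before[table$cause_id == va_undetermined()]

  out <- tibble(group = c(groups, va_undetermined()),
                fraction_before = c(unname(before), und_before),
                fraction_after = c(unname(after), 0),
                ci_low = NA_real_, ci_high = NA_real_)
  gboot <- NULL
  boot <- attr(table, "boot")
  if (!is.null(boot)) {
    gboot <- sapply(groups, function(g) rowSums(boot[, grp == g, drop = FALSE]))
    qs <- apply(gboot, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                names = FALSE, type = 7)
    out$ci_low <- c(unname(qs[1, ]), 0)
    out$ci_high <- c(unname(qs[2, ]), 0)
  }
  structure(out, class = c("va_groups", class(out)), boot = gboot)
}

#' Chance-corrected CSMF accuracy
#'
#' The standard population-level agreement metric between a true and a
#' predicted CSMF vector:
#' \deqn{1 - \frac{\sum_c |true_c - pred_c|}{2\,(1 - \min_c true_c)}}
#' It is 1 iff the distributions are equal, 0 when the prediction puts all
#' mass on the rarest true cause (the worst possible prediction), and is
#' invariant under relabelling applied to both vectors.
#'
#' @param true,pred Numeric CSMF vectors over the same causes, each summing
#'   to 1. If both are named they are aligned by name.
#' @return A number in \[0, 1\] (clamped at 0 below).
#' @export
#' @examples
#' csmf_accuracy(c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2))
csmf_accuracy <- function(true, pred) {
  if (!is.null(names(true)) && !is.null(names(pred))) {
    stopifnot(setequal(names(true), names(pred)))
    pred <- pred[names(true)]
  }
  stopifnot(length(true) == length(pred),
            abs(sum(true) - 1) < 1e-6, abs(sum(pred) - 1) < 1e-6)
  denom <- 2 * (1 - min(true))
  if (denom == 0) return(as.numeric(max(abs(true - pred)) < 1e-12))
  max(0, 1 - sum(abs(true - pred)) / denom)
}

#' Is the cause ranking stable under redistribution?
#'
#' Checks (rather than assumes) that the ordering of causes by mortality
#' fraction is the same before and after undetermined deaths are
#' reallocated.
#'
#' @param table A `va_csmf`.
#' @return `TRUE` if the before- and after-redistribution cause orderings
#'   (undetermined excluded) coincide.
#' @export
cause_ranking_stable <- function(table) {
  real <- table |> filter(.data$cause_id != va_undetermined())
  identical(order(-real$fraction_before, real$cause_id),
            order(-real$fraction_after, real$cause_id))
}
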