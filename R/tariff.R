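#' Symptom endorsement rates by cause
#'
#' For each cause c and symptom s, the fraction of gold-standard deaths of
#' cause c whose interview endorsed s. Missing responses count as "no" here
#' (scoring sums over endorsed symptoms only) while remaining missing in the
#' stored records.
#'
#' @param gold A gold-standard data frame: VA record columns plus
#'   `true_cause`.
#' @param schema A [va_schema()]; inferred from `gold` when `NULL`.
#' @param causes A [va_causes()] vocabulary; defaults to the causes present
#'   in `gold`, in first-appearance order. Every cause must have at least
#'   one training record.
#' @return An object of class `va_endorsement` with fields `x` (cause by
#'   symptom matrix of rates in \[0, 1\]), `n` (training deaths per cause)
#'   and `schema`.
#' @export
#' @examples
#' gold <- tibble::tibble(
#'   record_id = as.character(1:4), age_years = 50, sex = "female",
#'   s1 = c(1, 1, 1, 0), s2 = c(0, NA, 0, 0),
#'   true_cause = c("a", "a", "b", "b")
#' )
#' endorsement_rates(gold)$x
endorsement_rates <- function(gold, schema = NULL, causes = NULL) {
  gold <- as_tibble(gold)
  if (!"true_cause" %in% names(gold)) abort("`gold` must have a `true_cause` column.")
  schema <- schema %||% schema_from_records(gold)
  causes <- causes %||% va_causes(unique(gold$true_cause))
  if (va_undetermined() %in% gold$true_cause) {
    abort(sprintf("'%s' cannot appear as a training label.", va_undetermined()))
  }
  n <- table(factor(gold$true_cause, levels = causes))
  if (any(n == 0)) {
    abort(paste0("No gold-standard records for cause(s): ",
                 paste(names(n)[n == 0], collapse = ", ")))
  }
  Y <- .endorsement_indicator(gold, schema)
  x <- rowsum(Y, group = factor(gold$true_cause, levels = causes)) / as.vector(n)
  structure(list(x = x, n = set_names(as.integer(n), causes), schema = schema),
            class = "va_endorsement")
}

# records -> numeric matrix of yes-indicators (missing = 0), cols in schema order
.endorsement_indicator <- function(records, schema) {
  miss <- setdiff(schema$symptom_ids, names(records))
  if (length(miss)) {
    abort(paste0("Records are missing schema symptom column(s): ",
                 paste(miss, collapse = ", ")))
  }
  Y <- as.matrix(records[schema$symptom_ids])
  storage.mode(Y) <- "numeric"
  Y[is.na(Y)] <- 0
  Y
}

#' @export
print.va_endorsement <- function(x, ...) {
  cat(sprintf("<va_endorsement> %d causes x %d symptoms (n = %d gold-standard deaths)\n",
              nrow(x$x), ncol(x$x), sum(x$n)))
  invisible(x)
}

#' @export
tidy.va_endorsement <- function(x, ...) {
  as_tibble(x$x, rownames = "cause_id") |>
    pivot_longer(-"cause_id", names_to = "symptom_id", values_to = "rate")
}

#' Compute tariff scores from endorsement rates
#'
#' The tariff for a cause-symptom pair standardises the cause's endorsement
#' rate against the spread of that symptom's rates across all causes:
#' \deqn{t_{cs} = (x_{cs} - \mathrm{median}_c(x_{\cdot s})) /
#'   \mathrm{IQR}_c(x_{\cdot s})}
#' using inclusive linear-interpolation quantiles (R type 7). A symptom whose
#' rate is identical across causes carries no signal and gets a zero column
#' (the IQR-zero rule). Optionally tariffs are rounded to the nearest
#' `round_to` (midpoints away from zero) and, per cause, all but the
#' `top_k` largest-magnitude tariffs are truncated to zero; both behaviours
#' are on by default and recorded in the returned metadata.
#'
#' @param endorsement A `va_endorsement` from [endorsement_rates()].
#' @param round_to Rounding step (default 0.5); `NULL` disables rounding.
#' @param top_k Per-cause truncation rank (default 40); `NULL` disables
#'   truncation. Ties at the cut are broken by schema symptom order.
#' @return An object of class `va_tariffs`: `t` (cause by symptom tariff
#'   matrix), `schema`, `causes`, `metadata`.
#' @export
#' @examples
#' em <- structure(list(
#'   x = matrix(c(0.9, 0.1, 0.1), 3, 1,
#'              dimnames = list(c("a", "b", "c"), "s1")),
#'   n = c(a = 10, b = 10, c = 10), schema = va_schema("s1")),
#'   class = "va_endorsement")
#' compute_tariffs(em, round_to = NULL, top_k = NULL)$t
compute_tariffs <- function(endorsement, round_to = 0.5, top_k = 40) {
  x <- endorsement$x
  if (nrow(x) < 3) {
    abort("Tariffs need at least 3 causes: the per-symptom median and IQR are degenerate below that.")
  }
  t_mat <- apply(x, 2, function(col) {
    q <- quantile(col, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    if (iqr == 0) rep(0, length(col)) else (col - q[2]) / iqr
  })
  dimnames(t_mat) <- dimnames(x)
  if (!is.null(round_to) && round_to > 0) {
    t_mat[] <- round_half_away(t_mat, round_to)
  }
  if (!is.null(top_k) && is.finite(top_k) && top_k < ncol(t_mat)) {
    for (c_i in seq_len(nrow(t_mat))) {
      keep <- order(-abs(t_mat[c_i, ]), seq_len(ncol(t_mat)))[seq_len(top_k)]
      t_mat[c_i, -keep] <- 0
    }
  }
  structure(list(
    t = t_mat,
    schema = endorsement$schema,
    causes = rownames(t_mat),
    metadata = list(
      round_to = round_to %||% NA_real_,
      top_k = top_k %||% NA_integer_,
      quantile_convention = "inclusive linear interpolation (type 7)",
      significance_filtering = "unavailable"
    )
  ), class = "va_tariffs")
}

#' Round to the nearest multiple of a step, midpoints away from zero
#'
#' @param x Numeric.
#' @param step Positive rounding step.
#' @return `x` rounded to the nearest multiple of `step`; exact midpoints
#'   move away from zero, so the rule is deterministic and sign-symmetric.
#' @export
#' @examples
#' round_half_away(c(1.24, 1.26, -1.25), 0.5)
round_half_away <- function(x, step) {
  sign(x) * floor(abs(x) / step + 0.5) * step
}

#' @export
print.va_tariffs <- function(x, ...) {
  cat(sprintf("<va_tariffs> %d causes x %d symptoms (round_to = %s, top_k = %s)\n",
              nrow(x$t), ncol(x$t), format(x$metadata$round_to), format(x$metadata$top_k)))
  invisible(x)
}

#' @export
tidy.va_tariffs <- function(x, ...) {
  as_tibble(x$t, rownames = "cause_id") |>
    pivot_longer(-"cause_id", names_to = "symptom_id", values_to = "tariff")
}

#' Score records against a tariff matrix
#'
#' A record's score for a cause is the sum of that cause's tariffs over the
#' symptoms the record endorsed "yes"; missing and "no" responses contribute
#' nothing.
#'
#' @param records A data frame of VA records.
#' @param tariffs A `va_tariffs` from [compute_tariffs()].
#' @return A tibble: `record_id` plus one numeric score column per cause.
#' @export
score_records <- function(records, tariffs) {
  records <- as_tibble(records)
  S <- .score_matrix(records, tariffs)
  bind_cols(tibble(record_id = as.character(records$record_id)),
            as_tibble(S))
}

.score_matrix <- function(records, tariffs) {
  Y <- .endorsement_indicator(records, tariffs$schema)
  S <- Y %*% t(tariffs$t)
  rownames(S) <- NULL
  S
}

#' Write / read a tariff matrix as CSV with a metadata sidecar
#'
#' The CSV has causes as rows and symptoms as columns; the sidecar
#' (`<path>.meta`) is a plain `key: value` file recording the rounding step,
#' truncation rank and quantile convention so a reloaded matrix carries its
#' provenance.
#'
#' @param tariffs A `va_tariffs`.
#' @param path Output CSV path.
#' @return `write_tariffs()` returns `path` invisibly; `read_tariffs()`
#'   returns a `va_tariffs`.
#' @export
write_tariffs <- function(tariffs, path) {
  df <- as_tibble(tariffs$t, rownames = "cause_id")
  readr::write_csv(df, path)
  meta <- tariffs$metadata
  writeLines(sprintf("%s: %s", names(meta), vapply(meta, format, "")),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_tariffs
#' @export
read_tariffs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  t_mat <- as.matrix(df[-1])
  rownames(t_mat) <- df$cause_id
  meta <- list(round_to = NA_real_, top_k = NA_integer_,
               quantile_convention = "inclusive linear interpolation (type 7)",
               significance_filtering = "unavailable")
  mpath <- paste0(path, ".meta")
  if (file.exists(mpath)) {
    kv <- strsplit(readLines(mpath), ": ", fixed = TRUE)
    for (p in kv) {
      if (length(p) == 2) {
        meta[[p[1]]] <- if (p[1] %in% c("round_to", "top_k"))
          suppressWarnings(as.numeric(p[2])) else p[2]
      }
    }
  }
  structure(list(t = t_mat, schema = va_schema(colnames(t_mat)),
                 causes = rownames(t_mat), metadata = meta),
            class = "va_tariffs")
}
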