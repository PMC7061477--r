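#' Read and write VA record tables
#'
#' The records CSV has one row per death: columns `record_id`, `age_years`,
#' `sex`, then one column per symptom with values `1`/`0`/blank for
#' yes/no/missing. The gold-standard CSV adds a `true_cause` column. Header
#' row mandatory; UTF-8; CRLF and LF line endings parse identically. Blank
#' ages become unknown (`NA`); unparseable ages are set to `NA` and
#' collected into the `parse_violations` attribute rather than aborting the
#' read.
#'
#' @param path CSV path.
#' @param schema Optional [va_schema()]; when given, any symptom column not
#'   in the schema is an error naming the column, and missing schema
#'   columns are an error too.
#' @return A tibble of records (attribute `parse_violations`: a tibble
#'   `record_id`, `field`, `problem`, zero rows when clean).
#' @export
read_va_records <- function(path, schema = NULL) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  col_types = readr::cols(.default = readr::col_character())))
  chr_cols <- intersect(c("record_id", "age_years", "sex", "true_cause"), header)
  spec <- do.call(readr::cols, c(
    set_names(purrr::map(chr_cols, ~ readr::col_character()), chr_cols),
    list(.default = readr::col_double())))
  df <- readr::read_csv(path, col_types = spec)
  need <- c("record_id", "age_years", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("Records file is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!is.null(schema)) {
    sym_cols <- setdiff(names(df), .va_reserved_cols)
    extra <- setdiff(sym_cols, schema$symptom_ids)
    if (length(extra)) {
      abort(paste0("Symptom column(s) not in schema: ", paste(extra, collapse = ", ")))
    }
    absent <- setdiff(schema$symptom_ids, names(df))
    if (length(absent)) {
      abort(paste0("Schema symptom column(s) missing from file: ",
                   paste(absent, collapse = ", ")))
    }
  }
  age_raw <- df$age_years
  age <- suppressWarnings(as.numeric(age_raw))
  bad <- !is.na(age_raw) & nzchar(trimws(age_raw)) & is.na(age)
  df$age_years <- age
  viol <- tibble(record_id = df$record_id[bad],
                 field = rep("age_years", sum(bad)),
                 problem = sprintf("unparseable age '%s'", age_raw[bad]))
  attr(df, "parse_violations") <- viol
  df
}

#' @rdname read_va_records
#' @export
read_gold_standard <- function(path, schema = NULL) {
  df <- read_va_records(path, schema)
  if (!"true_cause" %in% names(df)) {
    abort("Gold-standard file is missing the `true_cause` column.")
  }
  df$true_cause <- as.character(df$true_cause)
  df
}

#' @rdname read_va_records
#' @param records A records tibble to write.
#' @export
write_va_records <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read a reference age-sex cause distribution
#'
#' CSV columns `sex, age_group, cause_id, fraction`; each (sex, age-group)
#' stratum must sum to 1 (checked).
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_reference <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(), age_group = readr::col_character(),
    cause_id = readr::col_character(), fraction = readr::col_double()))
  check_reference(df)
  df
}

#' Read a cause-to-broad-group map
#'
#' CSV columns `cause_id, group`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_broad_groups <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    cause_id = readr::col_character(), group = readr::col_character()))
  check_broad_group_map(df)
  df
}

#' Tally outcomes with counts, fractions and percentages
#'
#' The filter-count surface behind the run log: given per-death outcome
#' labels (certification route, exclusion category, assignment outcome, ...)
#' it returns counts, fractions of the total, and percentages. Used to make
#' headline statements such as "of N deaths, the tool certified k (p%)"
#' recomputable from the log alone.
#'
#' @param outcomes Character vector of outcome labels, or a data frame with
#'   an `outcome` column (and optionally an `n` column of pre-tallied
#'   counts).
#' @return A tibble: `outcome`, `n`, `fraction`, `percent` (1 decimal),
#'   plus a `TOTAL` row.
#' @export
#' @examples
#' tally_outcomes(c("assigned", "assigned", "undetermined"))
tally_outcomes <- function(outcomes) {
  if (is.data.frame(outcomes)) {
    df <- as_tibble(outcomes)
    if (!"outcome" %in% names(df)) abort("`outcomes` data frame needs an `outcome` column.")
    tal <- if ("n" %in% names(df)) {
      df |> group_by(.data$outcome) |> summarise(n = sum(.data$n), .groups = "drop")
    } else {
      df |> count(.data$outcome, name = "n")
    }
  } else {
    tal <- tibble(outcome = outcomes) |> count(.data$outcome, name = "n")
  }
  total <- sum(tal$n)
  out <- tal |> mutate(fraction = .data$n / total,
                       percent = round(100 * .data$n / total, 1))
  bind_rows(out, tibble(outcome = "TOTAL", n = total, fraction = 1, percent = 100))
}

#' Pipeline configuration
#'
#' Bundles every input path and tuning parameter of a batch run. Written to
#' and read from YAML so a monthly production run is a single committed
#' config file.
#'
#' @param gold,records,reference,broad_groups Input CSV paths.
#' @param out_dir Output directory.
#' @param restrictions Optional demographic-restrictions CSV path.
#' @param rank_quantile_cutoff,minimum_score,overall_rank_cap See
#'   [cutoff_policy()].
#' @param lambda Redistribution mixing weight, see [redistribute()].
#' @param per_cause_n Baseline resample size per cause.
#' @param round_to,top_k Tariff post-processing, see [compute_tariffs()].
#' @param cv_folds Folds for [fractional_weights()] (0 = in-sample).
#' @param bootstrap_b Bootstrap replicates for CIs.
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `va_pipeline_config`.
#' @export
pipeline_config <- function(gold, records, reference, broad_groups, out_dir,
                            restrictions = NULL,
                            rank_quantile_cutoff = 0.89, minimum_score = 0,
                            overall_rank_cap = 1, lambda = 0.5,
                            per_cause_n = 100, round_to = 0.5, top_k = 40,
                            cv_folds = 5, bootstrap_b = 1000, seed = 1) {
  structure(list(gold = gold, records = records, reference = reference,
                 broad_groups = broad_groups, out_dir = out_dir,
                 restrictions = restrictions,
                 rank_quantile_cutoff = rank_quantile_cutoff,
                 minimum_score = minimum_score,
                 overall_rank_cap = overall_rank_cap, lambda = lambda,
                 per_cause_n = per_cause_n, round_to = round_to,
                 top_k = top_k, cv_folds = cv_folds,
                 bootstrap_b = bootstrap_b, seed = as.integer(seed)),
            class = "va_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config A `va_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

#' Run the full batch pipeline
#'
#' Executes train, assign, undetermined redistribution, CSMF estimation and
#' plausibility reporting, writing every output CSV plus a stage-count log
#' and a metadata stamp (config hash and seed) so a rerun with the same
#' inputs is byte-identical apart from file timestamps. Any stage failure
#' aborts with a stage-labelled message.
#'
#' @param config A [pipeline_config()] or path to its YAML.
#' @return Invisibly, a list: `predictions`, `csmf`, `groups`,
#'   `redistribution`, `weights`, `report`, `log`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  log <- list()
  note <- function(stg, what, n) {
    log[[length(log) + 1]] <<- tibble(stage = stg, count_of = what, n = n)
  }

  gold <- stage("read", read_gold_standard(config$gold))
  records <- stage("read", read_va_records(config$records))
  reference <- stage("read", read_reference(config$reference))
  gmap <- stage("read", read_broad_groups(config$broad_groups))
  restrictions <- if (!is.null(config$restrictions))
    stage("read", readr::read_csv(config$restrictions, show_col_types = FALSE))
  note("read", "gold_standard_deaths", nrow(gold))
  note("read", "field_deaths", nrow(records))

  schema <- schema_from_records(gold)
  viol <- stage("validate", validate_records(records, schema))
  note("validate", "violations", nrow(viol))
  note("validate", "valid_deaths", nrow(records))

  policy <- cutoff_policy(config$rank_quantile_cutoff, config$minimum_score,
                          config$overall_rank_cap)
  fit <- stage("train", va_train(
    gold, schema = schema, policy = policy, restrictions = restrictions,
    per_cause_n = config$per_cause_n, round_to = config$round_to,
    top_k = config$top_k, seed = config$seed))

  preds <- stage("assign", assign_causes(records, fit))
  if (nrow(preds) == 0) abort("[aggregate] Cannot aggregate an empty prediction set.")
  note("assign", "assigned_cause", sum(preds$assigned_cause != va_undetermined()))
  note("assign", "undetermined", sum(preds$assigned_cause == va_undetermined()))

  wf <- stage("redistribute", if (config$cv_folds > 0) {
    fractional_weights(gold, method = "cv", folds = config$cv_folds,
                       seed = config$seed, policy = policy,
                       per_cause_n = config$per_cause_n,
                       round_to = config$round_to, top_k = config$top_k)
  } else {
    fractional_weights(gold, method = "insample", seed = config$seed,
                       policy = policy, per_cause_n = config$per_cause_n,
                       round_to = config$round_to, top_k = config$top_k)
  })
  rd <- stage("redistribute", redistribute(preds, wf, reference, config$lambda))
  note("redistribute", "redistributed_deaths", rd$total_redistributed)

  tab <- stage("csmf", csmf_table(preds, rd, B = config$bootstrap_b,
                                  seed = config$seed))
  grp <- stage("csmf", broad_group_fractions(tab, gmap))

  ref_groups <- reference |>
    left_join(gmap, by = "cause_id") |>
    group_by(.data$group) |>
    summarise(fraction = sum(.data$fraction), .groups = "drop") |>
    mutate(fraction = .data$fraction / sum(.data$fraction))
  report <- stage("plausibility", plausibility_report(
    records, preds, groups = grp, ref_groups = ref_groups))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  readr::write_csv(preds, p("predictions.csv"))
  readr::write_csv(tidy(tab), p("csmf.csv"))
  readr::write_csv(as_tibble(grp), p("broad_groups.csv"))
  readr::write_csv(rd$by_stratum, p("redistribution.csv"))
  readr::write_csv(as_tibble(wf), p("fractional_weights.csv"))
  log_tbl <- list_rbind(log)
  readr::write_csv(log_tbl, p("run_log.csv"))
  write_plausibility_report(report, config$out_dir)
  writeLines(c(sprintf("config_hash: %s", hash(unclass(config))),
               sprintf("seed: %d", config$seed),
               sprintf("ranking_stable: %s", cause_ranking_stable(tab))),
             p("run_metadata.txt"))

  invisible(list(predictions = preds, csmf = tab, groups = grp,
                 redistribution = rd, weights = wf, report = report,
                 log = log_tbl,
                 paths = vapply(c("predictions.csv", "csmf.csv", "broad_groups.csv",
                                  "redistribution.csv", "fractional_weights.csv",
                                  "run_log.csv", "plausibility.md",
                                  "run_metadata.txt"), p, "")))
}
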