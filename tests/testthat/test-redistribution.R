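test_that("fractional weights normalise per-cause undetermined rates", {
  w <- fractional_weights_from_counts(c(a = 2, b = 1, c = 0),
                                      c(a = 10, b = 10, c = 10))
  expect_equal(w$weight, c(2 / 3, 1 / 3, 0))
  # only one cause ever undetermined
  w1 <- fractional_weights_from_counts(c(a = 3, b = 0, c = 0),
                                       c(a = 10, b = 10, c = 10))
  expect_equal(w1$weight, c(1, 0, 0))
  # identical rates -> uniform, even with unequal training counts
  w2 <- fractional_weights_from_counts(c(a = 1, b = 2, c = 3),
                                       c(a = 10, b = 20, c = 30))
  expect_equal(w2$weight, rep(1 / 3, 3))
  # nothing undetermined -> uniform fallback with a warning
  expect_warning(
    w3 <- fractional_weights_from_counts(c(a = 0, b = 0, c = 0),
                                         c(a = 5, b = 5, c = 5)),
    "uniform")
  expect_equal(w3$weight, rep(1 / 3, 3))
  expect_true(attr(w3, "fallback_uniform"))
})

test_that("cross-validated propensity weights come from held-out assignments", {
  cfg <- sim_config(n_causes = 4, n_symptoms = 16, signal = 0.6,
                    background_rate = 0.3, n_train_per_cause = 40,
                    n_deaths = 0, seed = 31)
  gold <- simulate_gold_standard(cfg)
  w <- suppressWarnings(fractional_weights(gold, method = "cv", folds = 3,
                                           seed = 2, per_cause_n = 40))
  expect_s3_class(w, "va_frac_weights")
  expect_equal(sum(w$weight), 1)
  expect_true(all(w$weight >= 0))
  expect_equal(w$cause_id, cfg$causes)
  solo <- gold[1, ]
  solo$record_id <- "solo"
  solo$true_cause <- "lonely"
  expect_error(fractional_weights(dplyr::bind_rows(gold, solo), method = "cv"),
               "insample")
})

test_that("reference weights renormalise a stratum over the assignable causes", {
  ref <- make_reference(c(a = 0.2, b = 0.3, c = 0.5))
  w <- reference_weights(ref, "female", "50-59", c("a", "b", "c"))
  expect_equal(w, c(a = 0.2, b = 0.3, c = 0.5))
  # a cause outside the VA list is dropped and the rest renormalised
  w2 <- reference_weights(ref, "female", "50-59", c("a", "b"))
  expect_equal(w2, c(a = 0.4, b = 0.6))
  expect_error(reference_weights(ref, "female", "nonexistent", c("a", "b")),
               "no stratum")
})

test_that("unknown sex averages the sex strata; unknown age uses the all-age marginal", {
  sch <- age_scheme()
  ref <- dplyr::bind_rows(
    purrr::map(sch$label, ~ tibble::tibble(sex = "male", age_group = .x,
                                           cause_id = c("a", "b"), fraction = c(0.8, 0.2))),
    purrr::map(sch$label, ~ tibble::tibble(sex = "female", age_group = .x,
                                           cause_id = c("a", "b"), fraction = c(0.2, 0.8))))
  w <- reference_weights(ref, "unknown", "50-59", c("a", "b"))
  expect_equal(w, c(a = 0.5, b = 0.5))
  # all-age marginal: strata identical here, so the marginal equals any stratum
  w2 <- reference_weights(ref, "male", "Unknown", c("a", "b"))
  expect_equal(w2, c(a = 0.8, b = 0.2))
})

test_that("redistribution splits each stratum's undetermined mass by the combined weights", {
  preds <- make_predictions(c(a = 5, b = 5, undetermined = 10))
  ref <- make_reference(c(a = 0.2, b = 0.3, c = 0.5))
  w_frac <- c(a = 0.5, b = 0.5, c = 0)
  rd <- redistribute(preds, w_frac, ref, lambda = 0.5)
  # w_ref = (0.2, 0.3, 0.5); combined = (0.35, 0.4, 0.25); 10 undetermined
  expect_equal(unname(rd$added), c(3.5, 4.0, 2.5))
  expect_equal(rd$total_redistributed, 10)
  expect_equal(rd$by_stratum$w_ref, c(0.2, 0.3, 0.5))
  expect_equal(rd$by_stratum$combined, c(0.35, 0.4, 0.25))

  # averaging identity: equal weight vectors pass through
  rd2 <- redistribute(preds, c(a = 0.2, b = 0.3, c = 0.5), ref)
  expect_equal(unname(rd2$added), 10 * c(0.2, 0.3, 0.5))
  # lambda extremes select a single component
  expect_equal(unname(redistribute(preds, w_frac, ref, lambda = 1)$added),
               10 * c(0.5, 0.5, 0))
  expect_equal(unname(redistribute(preds, w_frac, ref, lambda = 0)$added),
               10 * c(0.2, 0.3, 0.5))
  # nothing undetermined -> nothing added
  rd0 <- redistribute(make_predictions(c(a = 3, b = 2)), w_frac, ref)
  expect_equal(unname(rd0$added), c(0, 0, 0))
  expect_equal(rd0$total_redistributed, 0)
})

test_that("redistribution conserves mass and never allocates to doubly-zero causes", {
  withr::with_seed(13, {
    for (trial in 1:20) {
      causes <- paste0("c", 1:4)
      counts <- c(sample(0:30, 4), undetermined = sample(0:20, 1))
      names(counts) <- c(causes, "undetermined")
      sexes <- sample(c("male", "female", "unknown"), sum(counts), replace = TRUE)
      ages <- sample(c(age_scheme()$label, "Unknown"), sum(counts), replace = TRUE)
      preds <- make_predictions(counts)
      preds$sex <- sexes
      preds$age_group <- factor(ages, levels = c(age_scheme()$label, "Unknown"))
      wf <- stats::runif(4); wf[1] <- 0
      wf <- setNames(wf / sum(wf), causes)
      rf <- stats::runif(4); rf[1] <- 0
      ref <- make_reference(setNames(rf / sum(rf), causes))
      rd <- redistribute(preds, wf, ref, lambda = stats::runif(1))
      n_und <- sum(preds$assigned_cause == "undetermined")
      expect_lt(abs(sum(rd$added) - n_und), 1e-6)
      expect_true(all(rd$added >= 0))
      # both weights zero for c1 -> nothing lands there
      expect_equal(unname(rd$added["c1"]), 0)
    }
  })
})
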