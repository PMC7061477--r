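test_that("age distribution reports counts and 1-decimal percentages per bin", {
  rec <- tibble::tibble(record_id = as.character(1:8),
                        age_years = c(15, 25, 25, 47, 65, 83, 90, NA),
                        sex = "female", s1 = 0)
  tab <- age_distribution(rec)
  expect_equal(tab$n[tab$age_group == "20-29"], 2L)
  expect_equal(tab$percent[tab$age_group == "20-29"], 25)
  expect_equal(tab$n[tab$age_group == "80+"], 2L)
  expect_equal(tab$percent[tab$age_group == "Unknown"], 12.5)
  expect_equal(sum(tab$n), 8L)
  expect_lt(abs(sum(tab$percent) - 100), 0.2)
  # boundary: every age unknown
  recu <- tibble::tibble(record_id = c("a", "b"), age_years = NA_real_,
                         sex = "male", s1 = 0)
  tabu <- age_distribution(recu)
  expect_equal(tabu$percent[tabu$age_group == "Unknown"], 100)
})

test_that("age comparison computes per-bin differences and the dissimilarity index", {
  rec <- tibble::tibble(record_id = as.character(1:10),
                        age_years = c(rep(25, 6), rep(65, 4)),
                        sex = "male", s1 = 0)
  tab <- age_distribution(rec)
  ref_same <- tibble::tibble(age_group = tab$age_group, percent = tab$percent)
  expect_equal(attr(compare_age(tab, ref_same), "dissimilarity"), 0)
  ref <- ref_same
  ref$percent[ref$age_group == "20-29"] <- 50
  ref$percent[ref$age_group == "60-69"] <- 50
  cmp <- compare_age(tab, ref)
  expect_equal(attr(cmp, "dissimilarity"), 10)
  expect_equal(cmp$abs_difference[cmp$age_group == "20-29"], 10)
  # disjoint support maximises the index
  ref2 <- ref_same; ref2$percent <- 0
  ref2$percent[ref2$age_group == "80+"] <- 100
  expect_equal(attr(compare_age(tab, ref2), "dissimilarity"), 100)
  expect_error(compare_age(tab, tibble::tibble(age_group = "0-11", percent = 100)),
               "bins differ")
})

test_that("the dissimilarity index is symmetric and bounded", {
  expect_equal(dissimilarity_index(c(60, 40), c(50, 50)), 10)
  withr::with_seed(9, {
    for (i in 1:10) {
      p <- stats::runif(5); p <- 100 * p / sum(p)
      q <- stats::runif(5); q <- 100 * q / sum(q)
      expect_equal(dissimilarity_index(p, q), dissimilarity_index(q, p))
      expect_gte(dissimilarity_index(p, q), 0)
      expect_lte(dissimilarity_index(p, q), 100)
    }
  })
})

test_that("broad-group comparison flags references outside the CI", {
  g <- tibble::tibble(group = c("g1", "g2", "g3"),
                      fraction_after = c(0.35, 0.35, 0.30),
                      ci_low = c(0.30, 0.30, 0.25),
                      ci_high = c(0.40, 0.40, 0.35))
  ref_in <- tibble::tibble(group = c("g1", "g2", "g3"),
                           fraction = c(0.33, 0.36, 0.30))
  expect_false(any(compare_broad_groups(g, ref_in)$flag))
  ref_out <- ref_in; ref_out$fraction[2] <- 0.55
  cmp <- compare_broad_groups(g, ref_out)
  expect_equal(cmp$flag, c(FALSE, TRUE, FALSE))
})

test_that("an engineered reference discrepancy flags exactly the shifted groups", {
  cfg <- sim_config(n_causes = 6, n_symptoms = 24, n_train_per_cause = 150,
                    n_deaths = 1500, seed = 17)
  gold <- simulate_gold_standard(cfg)
  fd <- simulate_field_deaths(cfg)
  map <- sim_broad_groups(cfg)
  # reference with an NCD excess at the expense of communicable causes,
  # mimicking a modelled reference ahead of the epidemiological transition
  ref <- simulate_reference(cfg, group_shift = list(from = "group1", to = "group2",
                                                    amount = 0.5))
  fit <- va_train(gold, seed = 17)
  preds <- assign_causes(fd$records, fit)
  wf <- suppressWarnings(fractional_weights(gold, method = "insample", seed = 17))
  rd <- redistribute(preds, wf, simulate_reference(cfg), lambda = 0.5)
  tab <- csmf_table(preds, rd, B = 300, seed = 17)
  grp <- broad_group_fractions(tab, map)
  ref_groups <- ref |>
    dplyr::left_join(map, by = "cause_id") |>
    dplyr::group_by(group) |>
    dplyr::summarise(fraction = sum(fraction) / 16)  # mean over 16 strata
  cmp <- compare_broad_groups(grp, ref_groups)
  expect_true(cmp$flag[cmp$group == "group1"])
  expect_true(cmp$flag[cmp$group == "group2"])
})

test_that("undetermined fraction is the undetermined share of predictions", {
  expect_equal(undetermined_fraction(make_predictions(c(a = 82, undetermined = 18))),
               0.18)
  expect_equal(undetermined_fraction(make_predictions(c(a = 5))), 0)
  expect_equal(undetermined_fraction(make_predictions(c(undetermined = 4))), 1)
})

test_that("report generation is pure and carries the quantitative flags", {
  rec <- tibble::tibble(record_id = as.character(1:10),
                        age_years = c(rep(30, 4), rep(70, 5), NA),
                        sex = rep(c("male", "female"), 5), s1 = 0)
  preds <- make_predictions(c(a = 8, undetermined = 2))
  g <- tibble::tibble(group = c("g1", "g2"),
                      fraction_before = c(0.5, 0.3), fraction_after = c(0.6, 0.4),
                      ci_low = c(0.5, 0.3), ci_high = c(0.7, 0.5))
  ref_groups <- tibble::tibble(group = c("g1", "g2"), fraction = c(0.2, 0.8))
  rep1 <- plausibility_report(rec, preds, groups = g, ref_groups = ref_groups)
  rep2 <- plausibility_report(rec, preds, groups = g, ref_groups = ref_groups)
  expect_identical(format(rep1), format(rep2))
  expect_equal(rep1$undetermined, 0.2)
  expect_equal(rep1$sex_ratio, 1)
  expect_length(rep1$flags, 2)  # both groups outside their CIs
  dir <- withr::local_tempdir()
  md <- write_plausibility_report(rep1, dir)
  expect_true(file.exists(md))
  expect_true(file.exists(file.path(dir, "plausibility_groups.csv")))
})
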