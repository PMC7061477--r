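#' Simulation configuration
#'
#' Defines the generative model every pipeline stage is exercised against:
#' each cause owns a disjoint block of `signature_size` "signature" symptoms
#' endorsed with probability `signal`; every other symptom is endorsed at
#' `background_rate`; symptoms are independent given the cause. Deaths carry
#' an age and sex drawn from one of three demographic archetypes assigned to
#' causes in rotation (old non-communicable, mid-age infectious, young
#' injury), so age gradients by cause group arise naturally.
#'
#' Defaults describe a strong-signal adult mortality study: 10 causes, 40
#' symptoms (30 signature + 10 pure-noise), signal 0.95 against background
#' 0.05, 500 gold-standard deaths per cause, 5,000 field deaths, and a
#' geometric-decay true CSMF (leading cause about 30 percent of deaths).
#'
#' @param n_causes Number of causes (default 10).
#' @param n_symptoms Number of symptoms (default 40; must be at least
#'   `n_causes * signature_size`).
#' @param signature_size Signature symptoms per cause (default 3).
#' @param signal Endorsement probability of a cause's signature symptoms
#'   (default 0.95).
#' @param background_rate Endorsement probability of all other symptoms
#'   (default 0.05; must be below `signal`).
#' @param true_csmf Cause-specific mortality fractions of the simulated
#'   population; defaults to normalised `exp(-0.35 * (0:(n_causes-1)))`.
#' @param n_train_per_cause Gold-standard deaths per cause (default 500).
#' @param n_deaths Field deaths (default 5000).
#' @param seed Integer seed (default 1).
#' @return An object of class `va_sim_config`.
#' @export
sim_config <- function(n_causes = 10, n_symptoms = 40, signature_size = 3,
                       signal = 0.95, background_rate = 0.05,
                       true_csmf = NULL, n_train_per_cause = 500,
                       n_deaths = 5000, seed = 1) {
  if (n_symptoms < n_causes * signature_size) {
    abort(sprintf(
      "n_symptoms (%d) < n_causes * signature_size (%d): no disjoint signature blocks possible.",
      n_symptoms, n_causes * signature_size))
  }
  if (!(background_rate >= 0 && background_rate < signal && signal <= 1)) {
    abort("Need 0 <= background_rate < signal <= 1.")
  }
  true_csmf <- true_csmf %||% {
    w <- exp(-0.35 * (seq_len(n_causes) - 1))
    w / sum(w)
  }
  if (length(true_csmf) != n_causes || abs(sum(true_csmf) - 1) > 1e-9 || any(true_csmf < 0)) {
    abort("`true_csmf` must be a probability vector of length n_causes.")
  }
  causes <- sprintf("cause_%02d", seq_len(n_causes))
  archetypes <- rep(c("old-ncd", "mid-infectious", "young-injury"),
                    length.out = n_causes)
  structure(list(n_causes = n_causes, n_symptoms = n_symptoms,
                 signature_size = signature_size, signal = signal,
                 background_rate = background_rate,
                 true_csmf = set_names(true_csmf, causes),
                 causes = causes,
                 symptoms = sprintf("s%02d", seq_len(n_symptoms)),
                 archetypes = set_names(archetypes, causes),
                 n_train_per_cause = n_train_per_cause,
                 n_deaths = n_deaths, seed = as.integer(seed)),
            class = "va_sim_config")
}

#' @export
print.va_sim_config <- function(x, ...) {
  cat(sprintf("<va_sim_config> %d causes, %d symptoms (signature %d @ %.2f vs background %.2f); %d train/cause, %d field deaths, seed %d\n",
              x$n_causes, x$n_symptoms, x$signature_size, x$signal,
              x$background_rate, x$n_train_per_cause, x$n_deaths, x$seed))
  invisible(x)
}

# demographic archetypes: age-bin probabilities over age_scheme() bins + P(male)
.archetypes <- function() {
  list(
    "old-ncd" = list(age = c(0.01, 0.02, 0.04, 0.08, 0.15, 0.22, 0.25, 0.23), p_male = 0.45),
    "mid-infectious" = list(age = c(0.05, 0.12, 0.18, 0.20, 0.20, 0.13, 0.08, 0.04), p_male = 0.50),
    "young-injury" = list(age = c(0.15, 0.30, 0.25, 0.15, 0.08, 0.04, 0.02, 0.01), p_male = 0.70)
  )
}

#' Generating endorsement-probability matrix of a simulation
#'
#' @param cfg A [sim_config()].
#' @return Cause-by-symptom matrix of endorsement probabilities; the oracle
#'   that empirical endorsement rates converge to.
#' @export
sim_endorsement_probs <- function(cfg) {
  P <- matrix(cfg$background_rate, cfg$n_causes, cfg$n_symptoms,
              dimnames = list(cfg$causes, cfg$symptoms))
  for (c_i in seq_len(cfg$n_causes)) {
    block <- ((c_i - 1) * cfg$signature_size + 1):(c_i * cfg$signature_size)
    P[c_i, block] <- cfg$signal
  }
  P
}

# draw ages and sexes for a vector of cause indices
.sim_demographics <- function(cfg, cause_idx) {
  arch <- .archetypes()
  sch <- age_scheme()
  a <- arch[cfg$archetypes[cause_idx]]
  n <- length(cause_idx)
  age_bin <- vapply(a, function(z) sample.int(8, 1, prob = z$age), integer(1))
  lower <- sch$lower[age_bin]
  upper <- pmin(sch$upper[age_bin], 94)
  age <- lower + floor(stats::runif(n) * (upper - lower + 1))
  sex <- ifelse(stats::runif(n) < vapply(a, `[[`, numeric(1), "p_male"),
                "male", "female")
  list(age = age, sex = sex)
}

# Bernoulli endorsement block for given causes
.sim_endorsements <- function(cfg, cause_idx) {
  P <- sim_endorsement_probs(cfg)
  n <- length(cause_idx)
  E <- matrix(as.integer(stats::runif(n * cfg$n_symptoms) < P[cause_idx, , drop = FALSE]),
              n, cfg$n_symptoms)
  colnames(E) <- cfg$symptoms
  E
}

#' Generate a synthetic gold-standard database
#'
#' `n_train_per_cause` deaths per cause, endorsements drawn from the
#' generating matrix, demographics from the cause's archetype. Reproducible
#' given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A tibble of gold-standard records (`record_id`, `age_years`,
#'   `sex`, symptom columns, `true_cause`) with the generating matrix in
#'   the `endorsement_probs` attribute for oracle checks.
#' @export
simulate_gold_standard <- function(cfg) {
  withr::with_seed(cfg$seed, {
    cause_idx <- rep(seq_len(cfg$n_causes), each = cfg$n_train_per_cause)
    dem <- .sim_demographics(cfg, cause_idx)
    E <- .sim_endorsements(cfg, cause_idx)
    out <- bind_cols(
      tibble(record_id = sprintf("gs%05d", seq_along(cause_idx)),
             age_years = dem$age, sex = dem$sex),
      as_tibble(E),
      tibble(true_cause = cfg$causes[cause_idx])
    )
    attr(out, "endorsement_probs") <- sim_endorsement_probs(cfg)
    out
  })
}

#' Generate synthetic field deaths with a hidden truth table
#'
#' Causes are drawn from the configured true CSMF; the truth table is
#' returned separately so it can be withheld from the pipeline and used
#' only for evaluation.
#'
#' @param cfg A [sim_config()].
#' @return A list: `records` (VA records without cause labels) and `truth`
#'   (`record_id`, `true_cause`).
#' @export
simulate_field_deaths <- function(cfg) {
  if (cfg$n_deaths == 0) {
    empty <- bind_cols(
      tibble(record_id = character(), age_years = numeric(), sex = character()),
      as_tibble(matrix(integer(), 0, cfg$n_symptoms,
                       dimnames = list(NULL, cfg$symptoms))))
    return(list(records = empty,
                truth = tibble(record_id = character(), true_cause = character())))
  }
  withr::with_seed(cfg$seed + 1L, {
    cause_idx <- sample.int(cfg$n_causes, cfg$n_deaths, replace = TRUE,
                            prob = cfg$true_csmf)
    dem <- .sim_demographics(cfg, cause_idx)
    E <- .sim_endorsements(cfg, cause_idx)
    records <- bind_cols(
      tibble(record_id = sprintf("d%06d", seq_along(cause_idx)),
             age_years = dem$age, sex = dem$sex),
      as_tibble(E))
    list(records = records,
         truth = tibble(record_id = records$record_id,
                        true_cause = cfg$causes[cause_idx]))
  })
}

#' Generate a reference age-sex cause distribution
#'
#' Builds the stratified cause distribution implied by the simulation truth
#' (cause fractions within each sex and age bin, proportional to the CSMF
#' times the cause's demographic profile), optionally perturbed:
#' `distortion` applies seeded log-normal noise of that magnitude to every
#' cause fraction; `group_shift` moves a fixed share of each stratum's mass
#' from one broad group to another (for constructing scenarios where the
#' reference disagrees with the truth, as modelled references sometimes do).
#'
#' @param cfg A [sim_config()].
#' @param distortion Non-negative noise magnitude; 0 (default) returns the
#'   exact truth-implied reference.
#' @param group_shift Optional `list(from =, to =, amount =)` with broad
#'   group names from [sim_broad_groups()] and a mass share in \[0, 1\].
#' @return A tibble `sex, age_group, cause_id, fraction`; each (sex,
#'   age-group) stratum sums to 1.
#' @export
simulate_reference <- function(cfg, distortion = 0, group_shift = NULL) {
  stopifnot(distortion >= 0)
  arch <- .archetypes()
  sch <- age_scheme()
  map <- sim_broad_groups(cfg)
  z <- withr::with_seed(cfg$seed + 1000L, rnorm(cfg$n_causes))
  rows <- list()
  for (sx in c("male", "female")) {
    p_sex <- vapply(cfg$archetypes, function(a) {
      pm <- arch[[a]]$p_male
      if (sx == "male") pm else 1 - pm
    }, numeric(1))
    for (b in seq_len(nrow(sch))) {
      p_age <- vapply(cfg$archetypes, function(a) arch[[a]]$age[b], numeric(1))
      f <- cfg$true_csmf * p_sex * p_age
      f <- f / sum(f)
      if (distortion > 0) {
        f <- f * exp(distortion * z)
        f <- f / sum(f)
      }
      if (!is.null(group_shift)) {
        from <- map$cause_id[map$group == group_shift$from]
        to <- map$cause_id[map$group == group_shift$to]
        moved <- group_shift$amount * sum(f[from])
        f[from] <- f[from] * (1 - group_shift$amount)
        f[to] <- f[to] + moved * f[to] / sum(f[to])
        f <- f / sum(f)
      }
      rows[[length(rows) + 1]] <- tibble(sex = sx, age_group = sch$label[b],
                                         cause_id = cfg$causes,
                                         fraction = unname(f))
    }
  }
  ref <- list_rbind(rows)
  check_reference(ref)
  ref
}

#' Broad-group map of a simulation
#'
#' Causes inherit their broad group from their demographic archetype:
#' mid-age infectious causes are group1 (communicable/maternal/
#' nutritional), old non-communicable causes group2 (NCDs), young injury
#' causes group3 (injuries).
#'
#' @param cfg A [sim_config()].
#' @return A tibble `cause_id`, `group`.
#' @export
sim_broad_groups <- function(cfg) {
  grp <- c("old-ncd" = "group2", "mid-infectious" = "group1",
           "young-injury" = "group3")
  tibble(cause_id = cfg$causes, group = unname(grp[cfg$archetypes]))
}

#' True CSMF of a simulation as a named vector
#'
#' @param cfg A [sim_config()].
#' @return Named numeric vector over the configured causes.
#' @export
sim_true_csmf <- function(cfg) cfg$true_csmf
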