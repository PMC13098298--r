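#' Distribution specifications for subject parameters
#'
#' Small declarative wrappers describing how each latent subject parameter is
#' drawn when a cohort is simulated. `dist_bimodal()` draws from a two-mode
#' mixture (each mode plus Gaussian jitter, truncated at zero) and is the
#' tool for parameter-recovery studies where ground-truth group membership
#' is the mode a subject was drawn from.
#'
#' @param meanlog,sdlog,shape,scale,value,modes,sd,p Distribution parameters.
#' @return A `dist_spec` list understood by [draw_subjects()].
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  structure(list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_gamma <- function(shape, scale) {
  structure(list(kind = "gamma", shape = shape, scale = scale),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_constant <- function(value) {
  structure(list(kind = "constant", value = value), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_bimodal <- function(modes, sd = 0.05 * abs(diff(modes)), p = 0.5) {
  stopifnot(length(modes) == 2L)
  structure(list(kind = "bimodal", modes = sort(modes), sd = sd, p = p),
            class = "dist_spec")
}

draw_dist <- function(spec, n) {
  switch(spec$kind,
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
    constant = rep(spec$value, n),
    bimodal = {
      # balanced design: component counts fixed at round(n * p), order
      # randomized — recovery studies then compare like-sized groups
      n_hi <- round(n * spec$p)
      hi <- sample(rep(c(TRUE, FALSE), c(n_hi, n - n_hi)))
      pmax(0, ifelse(hi, spec$modes[2L], spec$modes[1L]) +
             rnorm(n, 0, spec$sd))
    },
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  )
}

#' Default subject-parameter population
#'
#' Distributions over the latent per-subject parameters that generate the
#' phenotypes the analysis recovers: baseline locomotor speed (cm/s),
#' salience weight (attraction toward the active-lever zone during pre-lever
#' periods, plus anticipatory hyperactivity), sensitization slope
#' (multiplicative change in the locomotor response per noncontingent drug
#' challenge; > 1 sensitizing, < 1 tolerant — the default puts slightly more
#' mass below 1, matching a cohort where tolerance outnumbers
#' sensitization), intake escalation rate (additional expected infusions per
#' successive session), progressive-ratio press rate, and the cohort sex
#' ratio (21 males : 16 females by default).
#'
#' @param baseline_speed,salience_weight,sensitization_slope,escalation_rate,press_rate
#'   `dist_spec` objects.
#' @param p_male Probability a subject is male.
#' @return A list of class `population_spec`.
#' @export
default_population <- function(baseline_speed = dist_lognormal(log(3), 0.25),
                               salience_weight = dist_gamma(1.6, 1),
                               sensitization_slope = dist_lognormal(-0.06, 0.25),
                               escalation_rate = dist_gamma(2, 0.5),
                               press_rate = dist_lognormal(log(3), 0.3),
                               p_male = 21 / 37) {
  structure(
    list(baseline_speed = baseline_speed, salience_weight = salience_weight,
         sensitization_slope = sensitization_slope,
         escalation_rate = escalation_rate, press_rate = press_rate,
         p_male = p_male),
    class = "population_spec"
  )
}

#' Draw a cohort's ground-truth subject parameters
#'
#' Uses the current RNG state; callers seed it (see [generate_cohort()]).
#'
#' @param n Number of subjects.
#' @param population A [default_population()]-style `population_spec`.
#' @param id_prefix Prefix for subject identifiers.
#' @return Tibble with one row per subject: identifiers, the drawn
#'   parameters, sex and a per-subject RNG seed.
#' @export
draw_subjects <- function(n, population = default_population(),
                          id_prefix = "R") {
  stopifnot(n >= 1)
  tibble::tibble(
    subject_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    baseline_speed = draw_dist(population$baseline_speed, n),
    salience_weight = draw_dist(population$salience_weight, n),
    sensitization_slope = pmax(1e-6,
                               draw_dist(population$sensitization_slope, n)),
    escalation_rate = draw_dist(population$escalation_rate, n),
    press_rate = draw_dist(population$press_rate, n),
    sex = ifelse(runif(n) < population$p_male, "M", "F"),
    rng_seed = sample.int(.Machine$integer.max - 1L, n)
  )
}
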