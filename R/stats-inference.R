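#' Normality-gated correlation
#'
#' Correlates two paired vectors with Pearson's r when a Shapiro-Wilk test
#' finds both compatible with normality (both p > `alpha`), and with
#' Spearman's rank correlation otherwise. This keeps the parametric
#' estimate where its assumptions hold and degrades to ranks where they do
#' not.
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped;
#'   4 <= n <= 5000).
#' @param alpha Normality-gate significance level.
#' @return A one-row tibble of class `gated_correlation`: `method`,
#'   `estimate`, `p_raw`, both normality p-values and `n`.
#' @export
gated_correlation <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (n > 5000L) stop("normality gate supports at most 5000 pairs",
                      call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  px <- shapiro.test(x)$p.value
  py <- shapiro.test(y)$p.value
  method <- if (px > alpha && py > alpha) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  out <- tibble::tibble(method = method, estimate = unname(ct$estimate),
                        p_raw = ct$p.value, normality_p_x = px,
                        normality_p_y = py, n = n)
  class(out) <- c("gated_correlation", class(out))
  out
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence:
#' with `m` p-values sorted ascending, `adj_(i) = min(1, min_{j >= i}
#' m * c(m) / j * p_(j))` where `c(m) = sum_{k=1..m} 1/k`, mapped back to
#' input order. NAs pass through and do not count toward `m`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
by_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  ord <- order(p[ok])
  ps <- p[ok][ord]
  cm <- sum(1 / seq_len(m))
  raw <- m * cm / seq_len(m) * ps
  adj <- pmin(1, rev(cummin(rev(raw))))
  out[ok[ord]] <- adj
  out
}

#' Run the mixed-model suite over a cohort table
#'
#' Orchestrates the delegated model fits around the package's
#' pre-processing: for each model the response is winsorized at the upper
#' percentile, optionally power-transformed at the profile-likelihood
#' lambda, and then handed to an established mixed-model backend —
#' `lmerTest` for linear mixed models (Type III F tests with Satterthwaite
#' degrees of freedom) or `glmmTMB` + `car::Anova` for generalized models
#' (Type III Wald chi-square). Raw p-values across the whole suite are
#' Benjamini-Yekutieli adjusted. Every fit's provenance (winsorization cap,
#' transform family and lambda) is recorded. If the backend packages are
#' not installed the suite degrades to per-subject summaries with a
#' warning.
#'
#' @param cohort A [build_cohort_table()] tibble.
#' @param models List of model specs; each a list with `name`, `formula`
#'   (lme4-style, random effects included), optional `family` (default
#'   gaussian -> linear mixed model), optional `transform`
#'   (`"none"`, `"box_cox"`, `"yeo_johnson"`).
#' @param winsor Upper winsorization percentile for responses.
#' @param adjust Adjust the pooled p-values by [by_adjust()]?
#' @return A `model_suite`: `tests` tibble (`model`, `term`, `statistic`,
#'   `df`, `p_raw`, `p_by`) and a `provenance` list.
#' @export
run_model_suite <- function(cohort, models, winsor = 0.95, adjust = TRUE) {
  have_lmer <- requireNamespace("lmerTest", quietly = TRUE)
  have_tmb <- requireNamespace("glmmTMB", quietly = TRUE) &&
    requireNamespace("car", quietly = TRUE)
  tests <- list()
  provenance <- list()
  for (spec in models) {
    fam <- spec$family %||% "gaussian"
    transform <- spec$transform %||% "none"
    resp <- all.vars(spec$formula)[1L]
    dat <- cohort[stats::complete.cases(cohort[, all.vars(spec$formula)]), ]
    y <- winsorize_upper(dat[[resp]], winsor)
    cap <- quantile(dat[[resp]], winsor, na.rm = TRUE, names = FALSE)
    lambda <- NA_real_
    if (transform != "none") {
      ts <- fit_power_transform(y, family = transform)
      lambda <- ts$lambda
      y <- apply_power_transform(y, lambda, transform)
    }
    dat[[resp]] <- y
    provenance[[spec$name]] <- list(response = resp, winsor_percentile = winsor,
                                    winsor_cap = cap, transform = transform,
                                    lambda = lambda, family = fam,
                                    n = nrow(dat))
    if (identical(fam, "gaussian")) {
      if (!have_lmer) next
      fit <- lmerTest::lmer(spec$formula, data = dat)
      an <- stats::anova(fit, type = 3)
      tests[[spec$name]] <- tibble::tibble(
        model = spec$name, term = rownames(an),
        statistic = an[["F value"]], df = an[["NumDF"]],
        p_raw = an[["Pr(>F)"]]
      )
    } else {
      if (!have_tmb) next
      fit <- glmmTMB::glmmTMB(spec$formula, data = dat, family = fam)
      an <- car::Anova(fit, type = "III")
      keep <- rownames(an) != "(Intercept)"
      tests[[spec$name]] <- tibble::tibble(
        model = spec$name, term = rownames(an)[keep],
        statistic = an[["Chisq"]][keep], df = an[["Df"]][keep],
        p_raw = an[["Pr(>Chisq)"]][keep]
      )
    }
  }
  if ((!have_lmer || !have_tmb) && !length(tests)) {
    warning("mixed-model backends unavailable; returning per-subject ",
            "summaries only", call. = FALSE)
    summ <- dplyr::summarise(
      dplyr::group_by(cohort, .data$subject_id),
      dplyr::across(dplyr::where(is.numeric), ~mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
    return(structure(list(tests = NULL, subject_summary = summ,
                          provenance = provenance),
                     class = "model_suite"))
  }
  tests <- dplyr::bind_rows(tests)
  tests$p_by <- if (adjust && nrow(tests)) by_adjust(tests$p_raw) else {
    tests$p_raw
  }
  structure(list(tests = tests, provenance = provenance),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("<model_suite>\n")
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}
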