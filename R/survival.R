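#' Build an endpoint-specific survival dataset
#'
#' Endpoint semantics follow the usual lymphoma conventions: PFS counts
#' relapse/progression or lymphoma death as the event; OS counts death from
#' any cause; DSS counts lymphoma death, censoring other-cause death at the
#' death time. Administrative censoring is applied at `horizon_months`
#' (default 60): later times are truncated and their events dropped.
#'
#' @param clinical Clinical tibble (see [read_clinical_table()]). Optional
#'   `os_event`/`dss_event` columns, when present, are cross-checked against
#'   `death_cause` (a lymphoma death without `os_event`, for instance, is an
#'   error).
#' @param endpoint `"OS"`, `"DSS"`, or `"PFS"`.
#' @param horizon_months Administrative censoring horizon.
#' @return Tibble `patient_id`, `time_months`, `event` (logical), with the
#'   endpoint recorded in the `"endpoint"` attribute.
#' @export
build_endpoint <- function(clinical, endpoint = c("OS", "DSS", "PFS"),
                           horizon_months = 60) {
  endpoint <- match.arg(endpoint)
  died <- clinical$death_cause %in% c("lymphoma", "other")
  died_lymphoma <- clinical$death_cause == "lymphoma"
  if ("os_event" %in% names(clinical) &&
      any(died & !clinical$os_event, na.rm = TRUE)) {
    abort("inconsistent flags: death recorded without os_event")
  }
  if ("dss_event" %in% names(clinical) &&
      any(died_lymphoma & !clinical$dss_event, na.rm = TRUE)) {
    abort("inconsistent flags: lymphoma death recorded without dss_event")
  }
  relapse_time <- ifelse(is.na(clinical$time_to_relapse_months),
                         Inf, clinical$time_to_relapse_months)
  ds <- switch(endpoint,
    OS = tibble(patient_id = clinical$patient_id,
                time_months = clinical$follow_up_months,
                event = died),
    DSS = tibble(patient_id = clinical$patient_id,
                 time_months = clinical$follow_up_months,
                 event = died_lymphoma),
    PFS = tibble(patient_id = clinical$patient_id,
                 time_months = pmin(relapse_time,
                                    clinical$follow_up_months),
                 event = clinical$relapse_flag | died_lymphoma))
  ds <- ds |>
    mutate(event = .data$event & .data$time_months <= horizon_months,
           time_months = pmin(.data$time_months, horizon_months))
  attr(ds, "endpoint") <- endpoint
  attr(ds, "horizon_months") <- horizon_months
  ds
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival estimate, with the median survival time (earliest
#' time the curve reaches 0.5 or below; `NA` when it never does) and the
#' survival probability at 60 months.
#'
#' @param data Survival tibble (`time_months`, `event`), e.g. from
#'   [build_endpoint()].
#' @return An object of class `lp_km` wrapping the `survival::survfit` fit;
#'   `tidy()` returns the step coordinates, `glance()` the median and
#'   5-year survival.
#' @export
km_estimate <- function(data) {
  if (nrow(data) == 0) abort("no subjects")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = mutate(data, event = as.integer(.data$event)))
  structure(list(fit = fit, n = nrow(data)), class = "lp_km")
}

#' @export
print.lp_km <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<Kaplan-Meier> n=%d, events=%d, median=%s months, S(60)=%s\n",
              g$n, g$n_events,
              ifelse(is.na(g$median_months), "not reached",
                     format(g$median_months)),
              ifelse(is.na(g$s60), "-", sprintf("%.2f", g$s60))))
  invisible(x)
}

#' @describeIn km_estimate Step-function coordinates (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`).
#' @param x An `lp_km` object.
#' @param ... Unused.
#' @method tidy lp_km
#' @export
tidy.lp_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  tibble(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
         n_censor = s$n.censor, surv = s$surv)
}

#' @describeIn km_estimate Median survival, number of events, S(60).
#' @method glance lp_km
#' @export
glance.lp_km <- function(x, ...) {
  steps <- tidy(x)
  at_or_below <- steps$time[steps$surv <= 0.5]
  s60 <- if (any(steps$time <= 60)) {
    utils::tail(steps$surv[steps$time <= 60], 1)
  } else 1
  tibble(n = x$n,
         n_events = sum(steps$n_event),
         median_months = if (length(at_or_below)) min(at_or_below)
                         else NA_real_,
         s60 = s60)
}

#' Log-rank comparison of survival between groups
#'
#' @param data Survival tibble (`time_months`, `event`).
#' @param group Grouping vector (length `nrow(data)`) or the name of a
#'   column of `data`; at least 2 non-empty groups.
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, group) {
  if (is.character(group) && length(group) == 1) {
    group <- data[[group]]
  }
  if (length(group) != nrow(data)) abort("group length must match data")
  tab <- table(group)
  if (length(tab) < 2 || any(tab == 0)) {
    abort("log-rank needs at least two non-empty groups")
  }
  d <- mutate(data, .grp = group, event = as.integer(.data$event))
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ .grp,
                           data = d)
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
         p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Per-gene univariable Cox screen with Bonferroni correction
#'
#' One univariable Cox proportional-hazards fit per gene (Efron tie
#' handling), testing the mutated-vs-wild-type hazard ratio on the chosen
#' endpoint. Genes mutated in fewer than `min_carriers` patients, or in all
#' patients, are not testable and are skipped. The Bonferroni denominator
#' `m` is the number of genes actually tested and estimable (fits with
#' monotone-likelihood separation are flagged non-estimable and excluded
#' from `m`): `p_adjusted = min(1, p_raw * m)`.
#'
#' @param data Survival tibble (`patient_id`, `time_months`, `event`).
#' @param gene_flags Tibble with `patient_id` and one logical/0-1 column per
#'   gene.
#' @param min_carriers Minimum carriers for a gene to enter the screen.
#' @return A tibble of class `cox_screen`, sorted by `p_adjusted`: `gene`,
#'   `n_carriers`, `hr`, `ci_lower`, `ci_upper`, `p_raw`, `p_adjusted`,
#'   `estimable`; `m` and the skipped genes are attributes.
#' @export
cox_per_gene <- function(data, gene_flags, min_carriers = 2) {
  merged <- inner_join(data, gene_flags, by = "patient_id")
  if (nrow(merged) == 0) abort("no patients shared between data and gene_flags")
  genes <- setdiff(names(gene_flags), "patient_id")
  n <- nrow(merged)
  fits <- purrr::map(genes, function(g) {
    flag <- as.logical(merged[[g]])
    k <- sum(flag)
    if (k < min_carriers || k > n - 1) {
      return(tibble(gene = g, n_carriers = k, hr = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    p_raw = NA_real_, estimable = NA,
                    tested = FALSE))
    }
    d <- tibble(time = merged$time_months,
                event = as.integer(merged$event), x = flag)
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ x, data = d,
                      ties = "efron"))
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(diag(fit$var)))
    # monotone-likelihood separation: diverging coefficient, huge SE
    estimable <- is.finite(beta) && is.finite(se) && se < 10 &&
      abs(beta) < 15
    s <- summary(fit)
    tibble(gene = g, n_carriers = k,
           hr = if (estimable) exp(beta) else NA_real_,
           ci_lower = if (estimable) s$conf.int[1, "lower .95"] else NA_real_,
           ci_upper = if (estimable) s$conf.int[1, "upper .95"] else NA_real_,
           p_raw = if (estimable) s$coefficients[1, "Pr(>|z|)"] else NA_real_,
           estimable = estimable,
           tested = TRUE)
  })
  res <- bind_rows(fits)
  m <- sum(res$tested & !is.na(res$estimable) & res$estimable)
  out <- res |>
    filter(.data$tested) |>
    mutate(p_adjusted = pmin(1, .data$p_raw * m)) |>
    arrange(.data$p_adjusted) |>
    select("gene", "n_carriers", "hr", "ci_lower", "ci_upper",
           "p_raw", "p_adjusted", "estimable")
  attr(out, "m") <- m
  attr(out, "skipped_genes") <- res$gene[!res$tested]
  class(out) <- c("cox_screen", class(out))
  out
}

#' @describeIn cox_per_gene One-row screen summary (genes tested, Bonferroni
#'   denominator, significant hits).
#' @param x A `cox_screen` tibble.
#' @param ... Unused.
#' @method glance cox_screen
#' @export
glance.cox_screen <- function(x, ...) {
  tibble(n_tested = nrow(x),
         m = attr(x, "m"),
         n_significant = sum(x$p_adjusted < 0.05, na.rm = TRUE),
         n_skipped = length(attr(x, "skipped_genes")))
}
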