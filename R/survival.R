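#' Log-rank comparison of survival between patient subgroups
#'
#' K-sample log-rank (score) test of whether the survival curves of the
#' subgroups differ: at each event time, observed events per group are
#' compared with the events expected under a common hazard, and the
#' accumulated discrepancies give a chi-square statistic with K-1 degrees
#' of freedom. Per-group counts, event totals and Kaplan-Meier median
#' survival times are reported alongside; a median that the curve never
#' reaches (estimated survival stays above 0.5) is `NA`.
#'
#' @param labels Subgroup labels: a `subgroup_result`, a data frame with
#'   `patient_id` and `subgroup`, or a plain vector aligned with
#'   `survival`.
#' @param survival Survival table: tibble with `patient_id`, `time_days`
#'   (non-negative), `event` (1 = observed, 0 = censored), e.g. from
#'   [read_survival()]. Matched to labels by patient ID when both carry
#'   IDs.
#' @return An object of class `survival_comparison`: `chi_square`,
#'   `degrees_of_freedom` (K-1), `p_value` (chi-square upper tail),
#'   `per_group` (tibble: `subgroup`, `n`, `events`,
#'   `median_survival_days`).
#' @export
logrank_test <- function(labels, survival) {
  survival <- tibble::as_tibble(survival)
  validate_survival(survival)
  lab <- extract_subgroups(labels)
  if (!is.null(lab$patient_id)) {
    idx <- match(lab$patient_id, survival$patient_id)
    if (anyNA(idx)) {
      stop("patients in labels missing from the survival table: ",
           paste(utils::head(lab$patient_id[is.na(idx)], 3L), collapse = ", "),
           call. = FALSE)
    }
    survival <- survival[idx, ]
  } else if (length(lab$subgroup) != nrow(survival)) {
    stop("labels and survival table have different lengths", call. = FALSE)
  }
  grp <- factor(lab$subgroup)
  if (nlevels(grp) < 2L) stop("need at least 2 non-empty subgroups", call. = FALSE)
  if (sum(survival$event) < 1L) stop("no events observed", call. = FALSE)

  sd_fit <- survival::survdiff(
    survival::Surv(time_days, event) ~ grp,
    data = data.frame(time_days = survival$time_days,
                      event = survival$event, grp = grp)
  )
  df <- nlevels(grp) - 1L
  chisq <- unname(sd_fit$chisq)
  p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)

  km <- survival::survfit(
    survival::Surv(time_days, event) ~ grp,
    data = data.frame(time_days = survival$time_days,
                      event = survival$event, grp = grp)
  )
  km_tab <- summary(km)$table
  if (is.null(dim(km_tab))) km_tab <- matrix(km_tab, nrow = 1L,
                                             dimnames = list(NULL, names(km_tab)))
  per_group <- tibble::tibble(
    subgroup = levels(grp),
    n = as.integer(km_tab[, "records"]),
    events = as.integer(km_tab[, "events"]),
    median_survival_days = as.numeric(km_tab[, "median"])
  )
  structure(
    list(chi_square = chisq, degrees_of_freedom = df, p_value = p,
         per_group = per_group, fit = km),
    class = "survival_comparison"
  )
}

#' @keywords internal
extract_subgroups <- function(labels) {
  if (inherits(labels, "subgroup_result")) {
    return(list(patient_id = labels$subgroups$patient_id,
                subgroup = labels$subgroups$subgroup))
  }
  if (is.data.frame(labels)) {
    id_col <- if ("patient_id" %in% names(labels)) "patient_id" else names(labels)[1L]
    lab_col <- if ("subgroup" %in% names(labels)) "subgroup" else setdiff(names(labels), id_col)[1L]
    return(list(patient_id = as.character(labels[[id_col]]),
                subgroup = labels[[lab_col]]))
  }
  list(patient_id = NULL, subgroup = labels)
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("<survival_comparison> log-rank chi-square = ",
      signif(x$chi_square, 5), " on ", x$degrees_of_freedom,
      " df, p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  print(x$per_group)
  invisible(x)
}

#' @describeIn logrank_test Per-subgroup survival summary (n, events,
#'   Kaplan-Meier median; `NA` median = not reached).
#' @param x A `survival_comparison`.
#' @param ... Unused.
#' @export
tidy.survival_comparison <- function(x, ...) {
  x$per_group
}

#' @describeIn logrank_test One-row test summary.
#' @export
glance.survival_comparison <- function(x, ...) {
  tibble::tibble(
    chi_square = x$chi_square,
    degrees_of_freedom = x$degrees_of_freedom,
    p_value = x$p_value,
    n = sum(x$per_group$n),
    events = sum(x$per_group$events)
  )
}
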