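#' Nottingham Prognostic Index scoring
#'
#' The NPI combines tumor size, nodal status and histologic grade as
#' `NPI = 0.2 * S + N + G`, where `S` is the size of the index lesion in cm,
#' `N` the node-status category (0 nodes = 1, 1-3 nodes = 2, > 3 nodes = 3)
#' and `G` the histologic grade (1-3). Scores are binned into four prognostic
#' levels with decreasing 5-year survival:
#'
#' | Level | Score            |
#' |-------|------------------|
#' | I     | 2.0 <= s <= 2.4  |
#' | II    | 2.4 <  s <= 3.4  |
#' | III   | 3.4 <  s <= 5.4  |
#' | IV    | s > 5.4          |
#'
#' Scores below the minimum attainable 2.0 are rejected rather than clamped:
#' they can only arise from data errors.
#'
#' @param S Tumor size in cm (positive).
#' @param N Node-status category, integer in 1:3.
#' @param G Histologic grade, integer in 1:3.
#' @return `compute_npi()`: numeric score(s).
#' @export
compute_npi <- function(S, N, G) {
  if (any(!is.finite(S)) || any(S <= 0)) stop("S must be positive tumor size in cm", call. = FALSE)
  if (any(!N %in% 1:3)) stop("N must be a node category in 1:3", call. = FALSE)
  if (any(!G %in% 1:3)) stop("G must be a grade in 1:3", call. = FALSE)
  0.2 * S + N + G
}

#' @rdname compute_npi
#' @param positive_nodes Non-negative integer count of positive lymph nodes.
#' @return `node_category()`: integer category in 1:3.
#' @export
node_category <- function(positive_nodes) {
  if (any(is.na(positive_nodes)) || any(positive_nodes < 0) ||
      any(positive_nodes != round(positive_nodes))) {
    stop("positive_nodes must be non-negative integers", call. = FALSE)
  }
  ifelse(positive_nodes == 0, 1L, ifelse(positive_nodes <= 3, 2L, 3L))
}

NPI_LEVELS <- c("I", "II", "III", "IV")

#' @rdname compute_npi
#' @param score NPI score(s), >= 2.0.
#' @return `npi_level()`: factor with levels `I`, `II`, `III`, `IV`.
#' @export
npi_level <- function(score) {
  if (any(!is.finite(score)) || any(score < 2.0)) {
    stop("NPI score below the attainable minimum of 2.0", call. = FALSE)
  }
  cut(score, breaks = c(-Inf, 2.4, 3.4, 5.4, Inf), labels = NPI_LEVELS,
      right = TRUE)
}

#' Score a clinical table with NPI
#'
#' Data-frame-first wrapper: adds `node_cat`, `npi_score` and `npi_level`
#' columns to a clinical tibble.
#'
#' @param clinical Clinical tibble with `tumor_size_cm`, `positive_nodes`,
#'   `grade` columns (see [read_clinical_table()]).
#' @return The input tibble with scoring columns appended.
#' @export
npi_score <- function(clinical) {
  clinical <- validate_clinical(clinical)
  clinical |>
    dplyr::mutate(
      node_cat = node_category(.data$positive_nodes),
      npi_score = compute_npi(.data$tumor_size_cm, .data$node_cat, .data$grade),
      npi_level = npi_level(.data$npi_score)
    )
}

#' Kaplan-Meier relapse-free survival curve
#'
#' Product-limit estimate of the survival function under right censoring,
#' computed with [survival::survfit()]. Ties between events and censorings at
#' the same time are handled with the standard convention (events first).
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical; `TRUE` = relapse observed, `FALSE` = censored.
#' @return A tibble of class `npi_km` with columns `time`, `survival`,
#'   `at_risk`, `n_event`, starting at `time = 0`, `survival = 1`.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events)) stop("times and events differ in length", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be non-negative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  out <- tibble::tibble(
    time = c(0, fit$time),
    survival = c(1, fit$surv),
    at_risk = as.integer(c(length(times), fit$n.risk)),
    n_event = as.integer(c(0, fit$n.event))
  )
  class(out) <- c("npi_km", class(out))
  out
}

#' Kaplan-Meier curves per NPI level
#'
#' @param scored Clinical tibble with `npi_level`, `relapse_time_months` and
#'   `relapse_event` columns (see [npi_score()]).
#' @return A tibble with one curve row per (level, time), class `npi_km_set`.
#' @export
km_by_level <- function(scored) {
  need <- c("npi_level", "relapse_time_months", "relapse_event")
  miss <- setdiff(need, names(scored))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- scored |>
    dplyr::group_by(.data$npi_level) |>
    dplyr::group_modify(function(d, key) {
      kaplan_meier(d$relapse_time_months, d$relapse_event)
    }) |>
    dplyr::ungroup()
  class(out) <- c("npi_km_set", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function (right-continuous) evaluation of the product-limit estimate.
#'
#' @param curve An `npi_km` tibble from [kaplan_meier()].
#' @param at Times at which to read off survival.
#' @return Numeric survival probabilities.
#' @export
km_survival_at <- function(curve, at) {
  stats::approx(curve$time, curve$survival, xout = at, method = "constant",
                f = 0, rule = 2)$y
}

#' @export
autoplot.npi_km_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival,
                                       color = .data$npi_level)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Relapse-free time (months)", y = "Survival probability",
                  color = "NPI level") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.npi_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
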