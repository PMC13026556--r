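#' Assemble a survival table
#'
#' @param subject Subject identifiers.
#' @param time Overall survival time in months (> 0).
#' @param event Event indicator: `TRUE`/1 = death observed, `FALSE`/0 =
#'   right-censored.
#' @param group Group label per subject (e.g. `"low"` / `"high"`).
#' @return A tibble of class `surv_table` (subject, time, event, group).
#' @export
survival_table <- function(subject, time, event, group) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (any(time <= 0) || anyNA(time)) stop("survival times must be positive", call. = FALSE)
  if (anyNA(event)) stop("event indicators must be TRUE/FALSE", call. = FALSE)
  out <- tibble::tibble(subject = as.character(subject), time = time,
                        event = event, group = as.character(group))
  class(out) <- c("surv_table", class(out))
  out
}

#' Read a clinical table from TSV/CSV
#'
#' Expects columns `subject_id`, `os_months`, `event`, plus optional marker
#' columns which are carried along.
#'
#' @param path File path.
#' @return A tibble with the clinical columns.
#' @export
load_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path, call. = FALSE)
  tbl <- readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE,
                           progress = FALSE)
  need <- c("subject_id", "os_months", "event")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("clinical table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tbl
}

surv_fit_groups <- function(tbl) {
  stopifnot(inherits(tbl, "surv_table") || all(c("time", "event", "group") %in% names(tbl)))
  survival::survfit(survival::Surv(time, event) ~ group, data = tbl)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function per group, honoring
#' right-censoring.
#'
#' @param tbl A [survival_table()].
#' @param group Optional single group label to restrict to.
#' @return A tibble (group, time, n_risk, n_event, n_censor, survival)
#'   giving the step function at each observed time; S(0) = 1 is implicit.
#' @export
km_estimate <- function(tbl, group = NULL) {
  if (!is.null(group)) {
    tbl <- dplyr::filter(tbl, .data$group %in% !!group)
    if (nrow(tbl) == 0L) stop("no subjects in group: ", group, call. = FALSE)
  }
  fits <- dplyr::group_split(dplyr::group_by(tbl, .data$group))
  purrr::map_dfr(fits, function(g) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = g)
    tibble::tibble(group = g$group[1],
                   time = fit$time,
                   n_risk = fit$n.risk,
                   n_event = fit$n.event,
                   n_censor = fit$n.censor,
                   survival = fit$surv)
  })
}

#' Two-group log-rank test
#'
#' Observed-versus-expected event comparison between exactly two survival
#' groups; the statistic is chi-square distributed with 1 degree of freedom
#' under the null of equal hazards.
#'
#' @param tbl A [survival_table()] with exactly two group labels and at
#'   least one event.
#' @return A list of class `logrank_result`: `chi_square`, `p`, `df`,
#'   `observed` and `expected` (named per group).
#' @export
logrank_test <- function(tbl) {
  groups <- unique(tbl$group)
  if (length(groups) != 2L) stop("log-rank test needs exactly two groups", call. = FALSE)
  if (!any(tbl$event)) stop("no events observed; log-rank test undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = tbl)
  chi <- unname(sd$chisq)
  structure(list(chi_square = chi,
                 p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 df = 1L,
                 observed = stats::setNames(sd$obs, sub("^group=", "", names(sd$n))),
                 expected = stats::setNames(sd$exp, sub("^group=", "", names(sd$n)))),
            class = "logrank_result")
}

#' Mantel-Haenszel hazard ratio
#'
#' Summarizes the relative hazard between two groups from the log-rank
#' observed (O) and expected (E) event counts: HR = (O1/E1) / (O2/E2),
#' with a normal 95% confidence interval on the log scale using
#' SE = sqrt(1/E1 + 1/E2). The first group (alphabetical, or the level
#' order of a factor `group` column) is the numerator.
#'
#' @param tbl A [survival_table()] with exactly two groups, each with at
#'   least one expected event.
#' @return A list of class `hr_result`: `hr`, `ci_lower`, `ci_upper`,
#'   `numerator` (group label), `denominator`.
#' @export
hazard_ratio <- function(tbl) {
  groups <- if (is.factor(tbl$group)) levels(droplevels(tbl$group)) else sort(unique(tbl$group))
  if (length(groups) != 2L) stop("hazard ratio needs exactly two groups", call. = FALSE)
  lr <- logrank_test(tbl)
  o <- lr$observed[groups]
  e <- lr$expected[groups]
  if (any(e <= 0)) stop("a group has zero expected events", call. = FALSE)
  if (any(o == 0)) warning("a group has zero observed events; HR degenerate", call. = FALSE)
  hr <- (o[[1]] / e[[1]]) / (o[[2]] / e[[2]])
  se <- sqrt(1 / e[[1]] + 1 / e[[2]])
  structure(list(hr = hr,
                 ci_lower = hr * exp(-1.96 * se),
                 ci_upper = hr * exp(1.96 * se),
                 numerator = groups[1],
                 denominator = groups[2],
                 p = lr$p),
            class = "hr_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("# Log-rank test: chi-square = %.4g (df = 1), p = %.4g\n",
              x$chi_square, x$p))
  invisible(x)
}

#' @export
print.hr_result <- function(x, ...) {
  cat(sprintf("# Hazard ratio (%s vs %s): HR = %.4g, 95%% CI %.4g to %.4g, p = %.4g\n",
              x$numerator, x$denominator, x$hr, x$ci_lower, x$ci_upper, x$p))
  invisible(x)
}

#' Median-split stratification on two markers
#'
#' Labels each subject `hi`/`lo` per marker, `"hi"` meaning strictly above
#' the per-marker median (values at the median go to `lo`, the conservative
#' and deterministic choice), and combines the two into four groups
#' `hi/hi`, `hi/lo`, `lo/hi`, `lo/lo`. Explicit cutoffs (e.g. a 37%
#' positivity threshold from an external cohort) can replace the medians.
#'
#' @param data Data frame with one row per subject.
#' @param markers Character vector of the two marker column names.
#' @param thresholds Optional named numeric cutoffs per marker; defaults to
#'   the per-marker median.
#' @return `data` with added columns `<marker>_level` and `group`.
#' @export
median_split_groups <- function(data, markers, thresholds = NULL) {
  stopifnot(length(markers) == 2L, all(markers %in% names(data)))
  if (nrow(data) < 2L) stop("at least 2 subjects are required", call. = FALSE)
  levels_per_marker <- lapply(markers, function(mk) {
    v <- data[[mk]]
    if (max(v) == min(v)) stop("marker '", mk, "' is constant; split undefined",
                               call. = FALSE)
    cut <- if (!is.null(thresholds) && mk %in% names(thresholds)) {
      thresholds[[mk]]
    } else stats::median(v)
    ifelse(v > cut, "hi", "lo")
  })
  data[[paste0(markers[1], "_level")]] <- levels_per_marker[[1]]
  data[[paste0(markers[2], "_level")]] <- levels_per_marker[[2]]
  data$group <- paste(levels_per_marker[[1]], levels_per_marker[[2]], sep = "/")
  data
}
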