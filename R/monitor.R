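#' Welch two-sample t-test
#'
#' Unpaired two-tailed independent-samples t-test with Welch's correction,
#' always applied (no data-dependent switch on a variance-equality pretest):
#' \deqn{t = (\bar x_a - \bar x_b) / \sqrt{s_a^2/n_a + s_b^2/n_b}} with
#' Welch--Satterthwaite degrees of freedom and a two-tailed p-value from the
#' Student-t distribution. Standard deviations use the sample (n - 1)
#' denominator.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values;
#'   at least one group must have nonzero variance.
#' @return A `welch_ttest` object (`t_statistic`, `degrees_of_freedom`,
#'   `p_value`, group means/sds/sizes); see [tidy()].
#' @examples
#' welch_ttest(rnorm(10), rnorm(10, mean = 2))
#' @export
welch_ttest <- function(group_a, group_b) {
  for (g in list(a = group_a, b = group_b)) {
    if (!is.numeric(g) || length(g) < 2L || anyNA(g)) {
      vca_stop("each group needs >= 2 non-missing numeric values")
    }
  }
  na <- length(group_a); nb <- length(group_b)
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    vca_stop(if (ma == mb) {
      "degenerate samples: both variances are zero and the means are equal"
    } else {
      "degenerate samples: both variances are zero"
    })
  }
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t_statistic = t, degrees_of_freedom = df, p_value = p,
                 mean_1 = ma, mean_2 = mb,
                 sd_1 = sqrt(va), sd_2 = sqrt(vb), n_1 = na, n_2 = nb),
            class = "welch_ttest")
}

#' @export
print.welch_ttest <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.4g, p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  cat(sprintf("  group 1: mean %.4g (sd %.4g, n %d); group 2: mean %.4g (sd %.4g, n %d)\n",
              x$mean_1, x$sd_1, x$n_1, x$mean_2, x$sd_2, x$n_2))
  invisible(x)
}

#' @export
tidy.welch_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_1 - x$mean_2, mean_1 = x$mean_1, mean_2 = x$mean_2,
    statistic = x$t_statistic, df = x$degrees_of_freedom,
    p.value = x$p_value, method = "Welch two-sample t-test")
}

#' Significance label for a p-value
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `"ns"` otherwise.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

#' Longitudinal treatment-monitoring summary
#'
#' Summarises per-image vessel morphometry across subjects and days of
#' treatment: per-day cross-subject arithmetic mean and standard deviation
#' of length and width, the percent change of the `day_to` mean relative to
#' the `day_from` mean, and an unpaired Welch test of `day_from` vs `day_to`
#' values for each parameter (the unpaired comparison is deliberate even
#' though subjects repeat across days; a paired variant is available via
#' `paired = TRUE`).
#'
#' @param metrics Data frame with columns `subject_id`, `day` (integer,
#'   0 = pre-treatment), `length_px`, `width_px`; one row per (subject, day).
#' @param day_from,day_to Days compared (defaults 1 and 7).
#' @param paired Use a paired comparison (t-test on within-subject
#'   differences of subjects observed on both days) instead of the unpaired
#'   Welch test. Default `FALSE`.
#' @return A `vca_monitor` object: `per_day` (tibble: day, parameter, n,
#'   mean, sd), `changes` (tibble: parameter, mean_from, mean_to,
#'   percent_change, percent_of_reference), `tests` (tibble: parameter,
#'   t_statistic, df, p_value, label).
#' @export
monitor_study <- function(metrics, day_from = 1L, day_to = 7L, paired = FALSE) {
  metrics <- tibble::as_tibble(metrics)
  req <- c("subject_id", "day", "length_px", "width_px")
  miss <- setdiff(req, names(metrics))
  if (length(miss)) {
    vca_stop(paste0("`metrics` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(metrics) == 0L) vca_stop("`metrics` is empty")
  if (anyNA(metrics$day) || any(metrics$day < 0)) {
    vca_stop("`day` must be integers >= 0 (0 = pre-treatment)")
  }
  dup <- metrics |>
    dplyr::count(.data$subject_id, .data$day) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    vca_stop(sprintf("duplicate (subject_id, day) rows: %s",
                     paste(sprintf("(%s, %s)", dup$subject_id, dup$day),
                           collapse = ", ")))
  }
  for (d in c(day_from, day_to)) {
    if (!d %in% metrics$day) {
      vca_stop(sprintf("day %d is absent for all subjects", as.integer(d)))
    }
  }

  long <- metrics |>
    tidyr::pivot_longer(c("length_px", "width_px"), names_to = "parameter",
                        values_to = "value") |>
    dplyr::mutate(parameter = sub("_px$", "", .data$parameter))
  per_day <- long |>
    dplyr::group_by(.data$day, .data$parameter) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$day, .data$parameter)

  grp <- function(param, d) {
    long$value[long$parameter == param & long$day == d]
  }
  params <- c("length", "width")
  changes <- tibble::tibble(
    parameter = params,
    mean_from = unname(vapply(params, function(p) mean(grp(p, day_from)), numeric(1))),
    mean_to = unname(vapply(params, function(p) mean(grp(p, day_to)), numeric(1))))
  changes$percent_change <- percent_change(changes$mean_from, changes$mean_to)
  changes$percent_of_reference <-
    percent_of_reference(changes$mean_from, changes$mean_to)

  tests <- purrr::map_dfr(params, function(p) {
    a <- grp(p, day_from)
    b <- grp(p, day_to)
    res <- tryCatch({
      tt <- if (paired) {
        wide <- metrics[metrics$day %in% c(day_from, day_to),
                        c("subject_id", "day", paste0(p, "_px"))]
        w <- tidyr::pivot_wider(wide, names_from = "day",
                                values_from = paste0(p, "_px"))
        diffs <- w[[as.character(day_to)]] - w[[as.character(day_from)]]
        diffs <- diffs[!is.na(diffs)]
        one_sample_t(diffs)
      } else {
        welch_ttest(a, b)
      }
      tibble::tibble(parameter = p, t_statistic = tt$t_statistic,
                     df = tt$degrees_of_freedom, p_value = tt$p_value,
                     label = significance_label(tt$p_value), note = NA_character_)
    }, octavca_validation_error = function(e) {
      tibble::tibble(parameter = p, t_statistic = NA_real_, df = NA_real_,
                     p_value = NA_real_, label = NA_character_,
                     note = paste0("test skipped: ", conditionMessage(e)))
    })
    res
  })

  structure(list(per_day = per_day, changes = changes, tests = tests,
                 day_from = as.integer(day_from), day_to = as.integer(day_to),
                 paired = paired),
            class = "vca_monitor")
}

one_sample_t <- function(x) {
  if (length(x) < 2L) vca_stop("paired comparison needs >= 2 complete subject pairs")
  if (stats::sd(x) == 0 && mean(x) == 0) vca_stop("degenerate paired differences")
  n <- length(x)
  t <- mean(x) / (stats::sd(x) / sqrt(n))
  list(t_statistic = t, degrees_of_freedom = n - 1,
       p_value = 2 * stats::pt(-abs(t), n - 1))
}

#' @export
print.vca_monitor <- function(x, ...) {
  cat(sprintf("<vca_monitor> day %d vs day %d\n", x$day_from, x$day_to))
  print(x$changes)
  print(x$tests)
  invisible(x)
}

#' @export
tidy.vca_monitor <- function(x, ...) {
  dplyr::left_join(x$changes, x$tests, by = "parameter")
}

#' @export
glance.vca_monitor <- function(x, ...) {
  ch <- x$changes
  ts <- x$tests
  tibble::tibble(
    day_from = x$day_from, day_to = x$day_to,
    length_change_pct = ch$percent_change[ch$parameter == "length"],
    width_change_pct = ch$percent_change[ch$parameter == "width"],
    p_length = ts$p_value[ts$parameter == "length"],
    p_width = ts$p_value[ts$parameter == "width"],
    label_length = ts$label[ts$parameter == "length"],
    label_width = ts$label[ts$parameter == "width"])
}

#' Plot a monitoring summary
#'
#' Line plot of the per-day cross-subject mean with +/- one standard
#' deviation error bars, faceted by parameter (length, width).
#'
#' @param object A [monitor_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vca_monitor <- function(object, ...) {
  ggplot2::ggplot(object$per_day,
                  ggplot2::aes(x = .data$day, y = .data$mean)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2, color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "day of treatment", y = "mean ± sd (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
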