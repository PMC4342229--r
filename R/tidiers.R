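# broom-style tidiers and plots for fitted ERR models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ERR model fit
#'
#' @param x An `err_fit`.
#' @param conf_int Compute profile-likelihood confidence intervals for the
#'   ERR parameters (slower).
#' @param conf_level Confidence level for `conf_int`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std_error` (Wald, from the observed information), and with
#'   `conf_int = TRUE` profile `conf_low`/`conf_high` plus open-bound
#'   flags for ERR parameters.
#' @export
tidy.err_fit <- function(x, conf_int = FALSE, conf_level = 0.95, ...) {
  out <- tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params),
    std_error = sqrt(pmax(diag(x$vcov), 0)))
  if (conf_int) {
    err_par <- setdiff(seq_along(x$params), seq_len(x$n_base))
    cis <- purrr::map_dfr(err_par, function(j) {
      profile_ci(x, j, level = conf_level)
    })
    out <- dplyr::left_join(
      out,
      dplyr::select(cis, term = "param", conf_low = "lower",
                    conf_high = "upper", "lower_open", "upper_open"),
      by = "term")
  }
  out
}

#' Glance at an ERR model fit
#'
#' @param x An `err_fit`.
#' @param ... Unused.
#' @return One-row tibble: log-likelihood, parameter counts, AIC,
#'   convergence diagnostics, totals of observed and fitted deaths.
#' @export
glance.err_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * length(x$params),
    nobs = nrow(x$table),
    npar = length(x$params),
    converged = x$converged,
    boundary = isTRUE(x$boundary),
    iterations = x$iterations,
    gradient_norm = x$gradient_norm,
    rank_deficient = x$rank_deficient,
    observed = sum(x$table$events),
    fitted = sum(x$fitted$total))
}

#' Plot the fitted external dose response
#'
#' Draws the fitted ERR as a function of external dose over the observed
#' dose range, with dose-category points (category-specific crude ERR
#' estimates `observed / background - 1` at the category mean dose) when
#' the table carries an `ext_dose` axis.
#'
#' @param object An `err_fit` whose first ERR term uses the external dose.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.err_fit <- function(object, ...) {
  tab <- object$table
  dmax <- max(tab$mean_dose_ext) / 1000
  grid <- tibble::tibble(dose_gy = seq(0, dmax, length.out = 200))
  tm <- object$model$terms[[1]]
  th <- object$params[object$prep$idx[[1]]]
  bd <- tm$build(tibble::tibble(mean_dose_ext = grid$dose_gy * 1000,
                                sex = "male",
                                mean_age = stats::median(tab$mean_age)))
  grid$err <- tm$E(unname(th), bd)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$dose_gy, y = .data$err)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "External dose (Gy)", y = "Excess relative risk") +
    ggplot2::theme_minimal()
  if ("ext_dose" %in% names(tab)) {
    pts <- dplyr::bind_cols(tab, object$fitted) |>
      dplyr::group_by(.data$ext_dose) |>
      dplyr::summarise(
        dose_gy = stats::weighted.mean(.data$mean_dose_ext, .data$py) / 1000,
        err_hat = sum(.data$events) / sum(.data$background) - 1,
        .groups = "drop")
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(y = .data$err_hat),
                                 colour = "steelblue")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed versus fitted deaths by group
#'
#' @param attribution Output of [attribute_cases()] with a grouping.
#' @return A ggplot bar chart of observed deaths with fitted background
#'   and excess stacked per group (the `Total` row is dropped).
#' @export
plot_attribution <- function(attribution) {
  body <- dplyr::filter(attribution, .data$group != "Total")
  long <- body |>
    dplyr::select("group", "background",
                  dplyr::starts_with("excess_")) |>
    tidyr::pivot_longer(-"group", names_to = "component",
                        values_to = "deaths")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$deaths,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(data = body,
                        mapping = ggplot2::aes(x = .data$group,
                                               y = .data$observed),
                        inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = "Deaths",
                  title = "Observed (points) vs fitted (bars)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
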