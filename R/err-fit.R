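# Maximum-likelihood fitting of ERR models: damped Newton with analytic
# gradient/Hessian, likelihood-ratio tests, profile-likelihood CIs,
# background/excess attribution.

# Likelihood-only evaluation (cheap; used inside step-halving).
ll_only <- function(model, prep, params) {
  mp <- mu_parts(model, prep, params, deriv = FALSE)
  if (any(1 + mp$E <= 1e-12)) return(list(ok = FALSE))
  e <- prep$data$events
  list(ok = TRUE,
       ll = sum(ifelse(e > 0, e * log(mp$mu), 0) - mp$mu))
}

ll_grad_hess <- function(model, prep, params) {
  mp <- mu_parts(model, prep, params, deriv = TRUE)
  e <- prep$data$events
  if (any(1 + mp$E <= 1e-12)) return(list(ok = FALSE))
  ll <- sum(ifelse(e > 0, e * log(mp$mu), 0) - mp$mu)
  n_base <- prep$n_base
  n_err <- prep$n_par - n_base
  g <- numeric(prep$n_par)
  H <- matrix(0, prep$n_par, prep$n_par)
  resid <- e - mp$mu
  g[seq_len(n_base)] <- drop(crossprod(prep$X, resid))
  H[seq_len(n_base), seq_len(n_base)] <-
    -crossprod(prep$X, prep$X * mp$mu)
  HE <- H   # expected (Fisher) information: negative semidefinite
  HE[seq_len(n_base), seq_len(n_base)] <- H[seq_len(n_base), seq_len(n_base)]
  if (n_err > 0) {
    w <- e / (1 + mp$E) - mp$B
    ie <- n_base + seq_len(n_err)
    g[ie] <- drop(crossprod(mp$dE, w))
    Hgt <- -crossprod(prep$X, mp$dE * mp$B)
    H[seq_len(n_base), ie] <- Hgt
    H[ie, seq_len(n_base)] <- t(Hgt)
    a <- e / (1 + mp$E)^2
    Htt <- -crossprod(mp$dE, mp$dE * a)
    if (!is.null(mp$d2E) && any(mp$d2E != 0)) {
      for (j in seq_len(n_err)) {
        for (k in seq_len(n_err)) {
          Htt[j, k] <- Htt[j, k] + sum(w * mp$d2E[, j, k])
        }
      }
    }
    H[ie, ie] <- Htt
    HE[seq_len(n_base), ie] <- Hgt
    HE[ie, seq_len(n_base)] <- t(Hgt)
    HE[ie, ie] <- -crossprod(mp$dE, mp$dE * (mp$B / (1 + mp$E)))
  }
  list(ok = TRUE, ll = ll, g = g, H = H, HE = HE, mp = mp)
}

admissible <- function(model, prep, params) {
  ec <- err_components(model, prep, params)
  all(1 + ec$E > 1e-12)
}

# Damped Newton maximization with optional fixed parameters.
newton_maximize <- function(model, prep, start, fixed = integer(0),
                            control = fit_control()) {
  free <- setdiff(seq_len(prep$n_par), fixed)
  params <- start
  cur <- ll_grad_hess(model, prep, params)
  if (!cur$ok) stop("inadmissible start values: 1 + ERR <= 0; ",
                    "supply start values with 1 + ERR > 0 on every cell",
                    call. = FALSE)
  iter <- 0L
  converged <- FALSE
  scaled_gn <- function(st) {
    if (length(free) == 0L) return(0)
    max(abs(st$g[free]))
  }
  if (scaled_gn(cur) < control$grad_tol) converged <- TRUE
  n_tiny <- 0L
  while (!converged && iter < control$max_iter) {
    iter <- iter + 1L
    g <- cur$g[free]
    H <- cur$H[free, free, drop = FALSE]
    HE <- cur$HE[free, free, drop = FALSE]
    scale <- max(abs(diag(HE)), 1)
    improved <- FALSE
    # direction candidates: observed-Hessian Newton (quadratic near the
    # optimum), Fisher scoring (expected information, always an ascent
    # system), then ridged Fisher (Levenberg) as a last resort
    dirs <- c(list(H, HE),
              lapply(10^seq(-6, 6, by = 2) * scale,
                     function(r) HE - r * diag(length(free))))
    for (Hm in dirs) {
      step <- tryCatch(solve(Hm, -g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step)) ||
          sum(step * g) <= 0) next
      lam <- 1
      for (h in seq_len(control$max_halving)) {
        cand <- params
        cand[free] <- params[free] + lam * step
        cheap <- ll_only(model, prep, cand)
        if (cheap$ok && is.finite(cheap$ll) && cheap$ll > cur$ll) {
          improved <- TRUE
          break
        }
        lam <- lam / 2
      }
      if (improved) break
    }
    if (!improved) {
      # coordinate fallback: with one parameter pinned at the
      # admissibility edge the joint gradient direction is blocked, but
      # the remaining parameters can still be improved one at a time
      for (j in free) {
        hjj <- cur$HE[j, j]
        stepj <- if (is.finite(hjj) && hjj < 0) -cur$g[j] / hjj else
          sign(cur$g[j]) * 0.1
        lam <- 1
        for (h in seq_len(control$max_halving)) {
          cand <- params
          cand[j] <- params[j] + lam * stepj
          cheap <- ll_only(model, prep, cand)
          if (cheap$ok && is.finite(cheap$ll) && cheap$ll > cur$ll) {
            improved <- TRUE
            break
          }
          lam <- lam / 2
        }
        if (improved) break
      }
    }
    if (!improved) break   # no ascent found: at (or stuck near) optimum
    trial <- ll_grad_hess(model, prep, cand)
    dll <- trial$ll - cur$ll
    params <- cand
    cur <- trial
    if (scaled_gn(cur) < control$grad_tol) converged <- TRUE
    # persistent negligible improvements mean the iteration is crawling
    # along the admissibility edge (or is numerically exhausted): stop
    # and let the stall probe below classify the end point
    n_tiny <- if (dll < control$ll_tol * max(1, abs(cur$ll)))
      n_tiny + 1L else 0L
    if (n_tiny >= 5L) break
  }
  # after a stall with ERR parameters in play, polish the baseline
  # coefficients with the ERR block pinned: that subproblem is a concave
  # Poisson GLM, so its scores (including the intercept score that makes
  # fitted totals equal observed totals) are driven to zero exactly
  if (!converged && any(free > prep$n_base) && any(free <= prep$n_base)) {
    sub <- newton_maximize(model, prep, params,
                           fixed = union(fixed,
                                         seq(prep$n_base + 1L, prep$n_par)),
                           control = control)
    if (sub$loglik >= cur$ll) {
      params <- sub$params
      cur <- ll_grad_hess(model, prep, params)
    }
  }
  gn_abs <- if (length(free)) max(abs(cur$g[free])) else 0
  # a stall is either numeric exhaustion at the optimum (improvements
  # below machine precision) or an MLE pressed against the admissibility
  # edge (1 + ERR -> 0 in some cell), where the gradient need not vanish
  boundary <- FALSE
  if (!converged && length(free)) {
    g <- cur$g[free]
    tiny <- params
    tiny[free] <- tiny[free] + 1e-7 * g / max(abs(g))
    probe <- ll_grad_hess(model, prep, tiny)
    if (!probe$ok) {
      boundary <- TRUE           # ascent direction leaves the admissible set
    } else if (probe$ll <= cur$ll + 1e-11 * max(1, abs(cur$ll))) {
      converged <- TRUE          # no measurable ascent remains
    }
  }
  list(params = params, loglik = cur$ll, grad = cur$g, H = cur$H,
       gradient_norm = gn_abs, iterations = iter, boundary = boundary,
       converged = converged || boundary ||
         scaled_gn(cur) < control$grad_tol)
}

#' Fitter control settings
#'
#' @param ll_tol Relative log-likelihood change declaring convergence
#'   (default 1e-8).
#' @param grad_tol Scaled gradient-norm tolerance (default 1e-6).
#' @param max_iter Maximum Newton iterations (default 100).
#' @param max_halving Maximum step-halvings per iteration (default 40).
#' @return A list of control values.
#' @export
fit_control <- function(ll_tol = 1e-8, grad_tol = 1e-6, max_iter = 100L,
                        max_halving = 20L) {
  list(ll_tol = ll_tol, grad_tol = grad_tol, max_iter = max_iter,
       max_halving = max_halving)
}

#' Fit an ERR model to a person-year table by maximum likelihood
#'
#' Maximizes the grouped-Poisson log-likelihood with a damped Newton
#' algorithm using the analytic gradient and Hessian; step-halving keeps
#' every iterate admissible (`1 + ERR > 0` on all cells). Baseline
#' coefficients are initialized from a Poisson GLM of the background
#' model; ERR parameters start at 0 unless `start` is given.
#'
#' @param model An [err_model()].
#' @param table Person-year table (`py`, `events`, covariate columns).
#' @param start Optional named full-length start vector.
#' @param control A [fit_control()].
#' @return An object of class `err_fit`: estimates, log-likelihood,
#'   convergence diagnostics, the observed information, per-cell fitted
#'   background and excess components, and an identifiability flag.
#' @export
fit_err <- function(model, table, start = NULL, control = fit_control()) {
  table <- table[table$py > 0, , drop = FALSE]
  assert_that(nrow(table) > 0, "empty person-year table")
  prep <- prepare_model(model, table)
  # identifiability screen at the start values
  if (qr(prep$X)$rank < ncol(prep$X)) {
    stop("baseline design is rank deficient; drop collinear terms",
         call. = FALSE)
  }
  if (is.null(start)) {
    g0 <- suppressWarnings(
      stats::glm.fit(prep$X, table$events, offset = log(table$py),
                     family = stats::poisson()))
    start <- c(g0$coefficients, rep(0, prep$n_par - prep$n_base))
    start[!is.finite(start)] <- 0
  } else {
    assert_that(length(start) == prep$n_par,
                sprintf("`start` must have %d parameters", prep$n_par))
    if (!admissible(model, prep, start)) {
      stop("inadmissible start values: 1 + ERR <= 0; ",
           "shrink the ERR start values toward 0", call. = FALSE)
    }
  }
  res <- newton_maximize(model, prep, start, control = control)
  params <- stats::setNames(res$params, prep$par_names)
  info <- -res$H
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  rank_deficient <- any(ev < max(ev) * 1e-10)
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, prep$n_par, prep$n_par)
  })
  dimnames(vcov) <- list(prep$par_names, prep$par_names)
  mp <- mu_parts(model, prep, res$params)
  fitted <- tibble::tibble(background = mp$B)
  for (lab in names(mp$parts)) {
    fitted[[paste0("excess_", lab)]] <- mp$B * mp$parts[[lab]]
  }
  fitted$total <- mp$mu
  structure(list(model = model, params = params, loglik = res$loglik,
                 gradient_norm = res$gradient_norm,
                 iterations = res$iterations, converged = res$converged,
                 boundary = res$boundary,
                 rank_deficient = rank_deficient, vcov = vcov,
                 table = table, prep = prep, fitted = fitted,
                 n_base = prep$n_base, control = control),
            class = "err_fit")
}

#' @export
print.err_fit <- function(x, ...) {
  cat("<err_fit> loglik:", format(x$loglik, digits = 8),
      if (x$converged) "(converged" else "(NOT converged",
      "in", x$iterations, "iterations)\n")
  if (x$rank_deficient) cat("  note: information matrix is rank deficient\n")
  if (isTRUE(x$boundary)) {
    cat("  note: optimum lies on the admissibility edge (1 + ERR -> 0)\n")
  }
  print(tidy.err_fit(x), n = Inf)
  invisible(x)
}

#' Likelihood-ratio test between nested ERR model fits
#'
#' @param fit_null,fit_alt Fits of nested models on the same table.
#' @return A tibble with `statistic` (2 * loglik difference, clamped at 0
#'   within optimizer tolerance), `df` (parameter-count difference; 1 when
#'   the models have equal counts but differ, flagged), and the two-sided
#'   chi-square `p_value`. A rank-deficient alternative is reported with
#'   `flag = "rank_deficient"`.
#' @export
lrt <- function(fit_null, fit_alt) {
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < -1e-4) {
    stop("negative LRT statistic (", format(stat),
         "): optimizer failure in the alternative fit", call. = FALSE)
  }
  stat <- max(stat, 0)
  df <- length(fit_alt$params) - length(fit_null$params)
  flag <- NA_character_
  if (fit_alt$rank_deficient) flag <- "rank_deficient"
  if (df <= 0) {
    df <- max(df, 1L)
    if (stat <= 1e-8) flag <- paste(stats::na.omit(c(flag, "saturated")),
                                    collapse = ";")
  }
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 flag = flag)
}

# Profile log-likelihood at a fixed value of one parameter.
profile_ll <- function(fit, j, value) {
  prep <- fit$prep
  start <- unname(fit$params)
  start[j] <- value
  if (!admissible(fit$model, prep, start)) {
    # try again from a shrunken nuisance start
    start[-j] <- start[-j] * 0.5
    if (!admissible(fit$model, prep, start)) return(NA_real_)
  }
  ctrl <- fit$control
  ctrl$max_iter <- 50L
  res <- tryCatch(
    newton_maximize(fit$model, prep, start, fixed = j, control = ctrl),
    error = function(e) NULL)
  if (is.null(res)) NA_real_ else res$loglik
}

#' Profile-likelihood confidence interval
#'
#' Endpoints are the parameter values at which the profile log-likelihood
#' (re-maximized over all other parameters) drops by half the chi-square
#' critical value below the maximum (1.921 at 95%). When the edge of the
#' admissible region (`1 + ERR -> 0`) is reached before the drop, the
#' endpoint is reported as an open bound (`lower_open`/`upper_open`),
#' rendered in tables as `"<x"`. A non-monotone profile (log-likelihood
#' rising above the maximum along the search) is reported via `flag`.
#'
#' @param fit A converged [fit_err()] result.
#' @param param Parameter name (or index).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `param`, `estimate`, `lower`, `upper`,
#'   `lower_open`, `upper_open`, `level`, `flag`.
#' @export
profile_ci <- function(fit, param, level = 0.95) {
  assert_that(isTRUE(fit$converged), "fit has not converged")
  j <- if (is.character(param)) match(param, names(fit$params)) else param
  assert_that(is.finite(j) && j >= 1 && j <= length(fit$params),
              "unknown parameter")
  drop_ll <- stats::qchisq(level, 1) / 2
  mle <- unname(fit$params[j])
  llmax <- fit$loglik
  target <- llmax - drop_ll
  se <- sqrt(fit$vcov[j, j])
  step0 <- if (is.finite(se) && se > 0) se else abs(mle) * 0.5 + 0.1
  flag <- NA_character_

  search_side <- function(sgn) {
    step <- step0
    last_ok <- mle
    val <- mle
    for (k in 1:60) {
      val <- val + sgn * step
      pl <- profile_ll(fit, j, val)
      if (is.na(pl)) {
        # admissibility edge between last_ok and val: bisect to the edge
        loe <- last_ok; hie <- val
        for (b in 1:40) {
          midv <- (loe + hie) / 2
          plm <- profile_ll(fit, j, midv)
          if (is.na(plm)) hie <- midv else {
            loe <- midv
            if (plm <= target) {
              # the drop occurs inside the admissible region after all
              r <- stats::uniroot(function(v) profile_ll(fit, j, v) - target,
                                  lower = min(last_ok, midv),
                                  upper = max(last_ok, midv),
                                  tol = 1e-7)
              return(list(value = r$root, open = FALSE))
            }
          }
        }
        return(list(value = loe, open = TRUE))
      }
      if (pl > llmax + 1e-6) flag <<- "non_monotone_profile"
      if (pl <= target) {
        r <- stats::uniroot(function(v) {
          p <- profile_ll(fit, j, v)
          if (is.na(p)) -Inf else p - target
        }, lower = min(last_ok, val), upper = max(last_ok, val), tol = 1e-7)
        return(list(value = r$root, open = FALSE))
      }
      last_ok <- val
      step <- step * 1.6
    }
    list(value = sgn * Inf, open = TRUE)
  }

  lo <- search_side(-1)
  hi <- search_side(+1)
  tibble::tibble(param = names(fit$params)[j], estimate = mle,
                 lower = lo$value, upper = hi$value,
                 lower_open = lo$open, upper_open = hi$open,
                 level = level, flag = flag)
}

#' Profile a threshold dose over a grid
#'
#' The linear-threshold model `beta * (d - c)+` is non-smooth in the
#' threshold `c`, so `c` is profiled over a grid rather than jointly
#' Newton-optimized: each grid value refits the remaining parameters and
#' records the profile log-likelihood.
#'
#' @param baseline Baseline formula.
#' @param table Person-year table.
#' @param thresholds Grid of threshold doses (Gy).
#' @param var,scale Dose column and scale passed to [err_threshold()].
#' @param control A [fit_control()].
#' @return Tibble with `threshold`, `beta`, `loglik`, plus the maximum-
#'   likelihood threshold and a 95% profile set as attributes
#'   (`mle_threshold`, `ci_set`).
#' @export
profile_threshold <- function(baseline, table,
                              thresholds = seq(0, 1.5, by = 0.05),
                              var = "mean_dose_ext", scale = 1e-3,
                              control = fit_control()) {
  rows <- purrr::map_dfr(thresholds, function(cc) {
    m <- err_model(baseline, err_threshold(var, scale, threshold = cc))
    f <- tryCatch(fit_err(m, table, control = control),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    tibble::tibble(threshold = cc,
                   beta = unname(f$params[length(f$params)]),
                   loglik = f$loglik)
  })
  best <- rows$threshold[which.max(rows$loglik)]
  keep <- rows$threshold[rows$loglik >= max(rows$loglik) -
                           stats::qchisq(0.95, 1) / 2]
  attr(rows, "mle_threshold") <- best
  attr(rows, "ci_set") <- range(keep)
  rows
}

#' Observed, background and excess deaths by group
#'
#' Decomposes fitted deaths per cell into background
#' (`py * baseline rate`) and one excess component per ERR term
#' (`py * baseline * ERR_term`), then sums them over the levels of a
#' grouping column. With a free baseline intercept the grand total of
#' background plus all excess components equals the observed total (the
#' intercept's score equation).
#'
#' @param fit An [fit_err()] result.
#' @param grouping Name of a column of the fitted table to group by
#'   (e.g. `"ext_dose"`), or `NULL` for a single overall row.
#' @return Tibble with observed, background, one `excess_*` column per
#'   ERR term, and fitted totals, plus a `Total` row.
#' @export
attribute_cases <- function(fit, grouping = NULL) {
  tab <- dplyr::bind_cols(fit$table[, intersect(grouping, names(fit$table)),
                                    drop = FALSE],
                          tibble::tibble(observed = fit$table$events),
                          fit$fitted)
  if (is.null(grouping)) {
    out <- tab |>
      dplyr::summarise(dplyr::across(dplyr::everything(), sum)) |>
      dplyr::mutate(group = "Total", .before = 1)
    return(out)
  }
  body <- tab |>
    dplyr::group_by(group = .data[[grouping]]) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum),
                     .groups = "drop")
  tot <- body |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum)) |>
    dplyr::mutate(group = "Total", .before = 1)
  dplyr::bind_rows(body, tot)
}
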