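# ERR model specification: baseline terms, ERR terms and their
# derivatives, composite ERR evaluation, expected counts, log-likelihood.
#
# Rates are modelled as lambda0(cell) * (1 + ERR(cell)), with a log-linear
# baseline lambda0 = exp(X gamma) and a composite excess
# ERR = ERR_ext + I_mon * ERR_int + I_unmon * ERR_pusur.

#' ERR dose-response terms
#'
#' Constructors for the excess-relative-risk terms of an [err_model()].
#' Dose variables refer to columns of the person-year table (person-year-
#' weighted mean lagged doses in mGy); `scale` converts them to the unit
#' the coefficient is reported in (default per Gy).
#'
#' * `err_linear()`: beta * d, optionally modified by a female:male ratio
#'   on the identity scale and/or a power of attained age `(a/60)^alpha`.
#' * `err_linear_quadratic()`: beta1 * d + beta2 * d^2.
#' * `err_quadratic()`: beta2 * d^2.
#' * `err_cell_killing()`: beta1 * d * exp(-beta2 * d), allowing the
#'   response to flatten or turn over at high dose.
#' * `err_threshold()`: beta * (d - c)+ with fixed threshold `c` (profiled
#'   over a grid by [profile_threshold()], not jointly optimized).
#' * `err_windows()`: sum_i beta_i * d_i over window dose columns.
#' * `err_surrogate()`: category-level excess for unmonitored person-time,
#'   one level per surrogate category 1-5 (category 0 is the reference).
#'
#' @param var Dose column name.
#' @param scale Multiplier applied to the dose column (default 1e-3:
#'   mGy to Gy).
#' @param label Prefix for parameter names.
#' @param indicator Optional 0/1 column multiplying the term (e.g.
#'   `".I_mon"` for an internal-dose term applying to monitored
#'   person-time).
#' @param sex_ratio Add a female:male ERR ratio parameter (identity
#'   scale, so the ratio may be negative when the female ERR is).
#' @param age_power Add an attained-age power modifier `(a/60)^alpha`.
#' @param threshold Fixed threshold dose `c`, in the scaled unit (Gy).
#' @param vars Window dose columns (for `err_windows`).
#' @param by_sex Estimate separate surrogate levels by sex.
#' @return An object of class `err_term`.
#' @name err_terms
NULL

new_err_term <- function(type, label, par_names, build, E, dE, d2E) {
  structure(list(type = type, label = label, par_names = par_names,
                 build = build, E = E, dE = dE, d2E = d2E),
            class = "err_term")
}

#' @rdname err_terms
#' @export
err_linear <- function(var = "mean_dose_ext", scale = 1e-3, label = "ext",
                       indicator = NULL, sex_ratio = FALSE,
                       age_power = FALSE) {
  pn <- paste0(label, ":beta")
  if (sex_ratio) pn <- c(pn, paste0(label, ":sex_ratio"))
  if (age_power) pn <- c(pn, paste0(label, ":age_power"))
  p <- length(pn)
  build <- function(data) {
    d <- data[[var]] * scale
    if (!is.null(indicator)) d <- d * data[[indicator]]
    list(d = d,
         If = if (sex_ratio) as.numeric(data$sex == "female") else NULL,
         la = if (age_power) log(pmax(data$mean_age, 1) / 60) else NULL)
  }
  unpack <- function(th) {
    i <- 1L
    beta <- th[i]; i <- i + 1L
    ratio <- if (sex_ratio) { v <- th[i]; i <- i + 1L; v } else NULL
    alpha <- if (age_power) th[i] else NULL
    list(beta = beta, ratio = ratio, alpha = alpha)
  }
  mods <- function(u, bd) {
    ms <- if (sex_ratio) 1 + (u$ratio - 1) * bd$If else 1
    ma <- if (age_power) exp(u$alpha * bd$la) else 1
    list(ms = ms, ma = ma)
  }
  E <- function(th, bd) {
    u <- unpack(th); m <- mods(u, bd)
    u$beta * bd$d * m$ms * m$ma
  }
  dE <- function(th, bd) {
    u <- unpack(th); m <- mods(u, bd)
    out <- matrix(0, length(bd$d), p)
    out[, 1] <- bd$d * m$ms * m$ma
    j <- 2L
    if (sex_ratio) { out[, j] <- u$beta * bd$d * bd$If * m$ma; j <- j + 1L }
    if (age_power) out[, j] <- u$beta * bd$d * m$ms * m$ma * bd$la
    out
  }
  d2E <- function(th, bd) {
    u <- unpack(th); m <- mods(u, bd)
    n <- length(bd$d)
    out <- array(0, c(n, p, p))
    j <- 2L
    if (sex_ratio) {
      out[, 1, j] <- out[, j, 1] <- bd$d * bd$If * m$ma
      j <- j + 1L
    }
    if (age_power) {
      out[, 1, j] <- out[, j, 1] <- bd$d * m$ms * m$ma * bd$la
      if (sex_ratio) {
        out[, 2, j] <- out[, j, 2] <- u$beta * bd$d * bd$If * m$ma * bd$la
      }
      out[, j, j] <- u$beta * bd$d * m$ms * m$ma * bd$la^2
    }
    out
  }
  new_err_term("linear", label, pn, build, E, dE, d2E)
}

#' @rdname err_terms
#' @export
err_linear_quadratic <- function(var = "mean_dose_ext", scale = 1e-3,
                                 label = "ext") {
  pn <- paste0(label, c(":beta", ":quad"))
  build <- function(data) list(d = data[[var]] * scale)
  new_err_term(
    "linear_quadratic", label, pn, build,
    E = function(th, bd) th[1] * bd$d + th[2] * bd$d^2,
    dE = function(th, bd) cbind(bd$d, bd$d^2, deparse.level = 0),
    d2E = function(th, bd) array(0, c(length(bd$d), 2, 2)))
}

#' @rdname err_terms
#' @export
err_quadratic <- function(var = "mean_dose_ext", scale = 1e-3,
                          label = "ext") {
  pn <- paste0(label, ":quad")
  build <- function(data) list(d = data[[var]] * scale)
  new_err_term(
    "quadratic", label, pn, build,
    E = function(th, bd) th[1] * bd$d^2,
    dE = function(th, bd) cbind(bd$d^2, deparse.level = 0),
    d2E = function(th, bd) array(0, c(length(bd$d), 1, 1)))
}

#' @rdname err_terms
#' @export
err_cell_killing <- function(var = "mean_dose_ext", scale = 1e-3,
                             label = "ext") {
  pn <- paste0(label, c(":beta", ":kill"))
  build <- function(data) list(d = data[[var]] * scale)
  new_err_term(
    "cell_killing", label, pn, build,
    E = function(th, bd) th[1] * bd$d * exp(-th[2] * bd$d),
    dE = function(th, bd) {
      ek <- exp(-th[2] * bd$d)
      cbind(bd$d * ek, -th[1] * bd$d^2 * ek, deparse.level = 0)
    },
    d2E = function(th, bd) {
      n <- length(bd$d)
      ek <- exp(-th[2] * bd$d)
      out <- array(0, c(n, 2, 2))
      out[, 1, 2] <- out[, 2, 1] <- -bd$d^2 * ek
      out[, 2, 2] <- th[1] * bd$d^3 * ek
      out
    })
}

#' @rdname err_terms
#' @export
err_threshold <- function(var = "mean_dose_ext", scale = 1e-3,
                          threshold = 0, label = "ext") {
  pn <- paste0(label, ":beta")
  build <- function(data) list(d = pmax(data[[var]] * scale - threshold, 0))
  new_err_term(
    "threshold", label, pn, build,
    E = function(th, bd) th[1] * bd$d,
    dE = function(th, bd) cbind(bd$d, deparse.level = 0),
    d2E = function(th, bd) array(0, c(length(bd$d), 1, 1)))
}

#' @rdname err_terms
#' @export
err_windows <- function(vars, scale = 1e-3, label = "win") {
  pn <- paste0(label, ":", vars)
  k <- length(vars)
  build <- function(data) {
    list(D = as.matrix(data[, vars, drop = FALSE]) * scale)
  }
  new_err_term(
    "windows", label, pn, build,
    E = function(th, bd) drop(bd$D %*% th),
    dE = function(th, bd) bd$D,
    d2E = function(th, bd) array(0, c(nrow(bd$D), k, k)))
}

#' @rdname err_terms
#' @export
err_surrogate <- function(var = "surrogate", indicator = ".I_unmon",
                          label = "pusur", by_sex = FALSE) {
  build <- function(data) {
    cat <- data[[var]]
    lev <- sort(unique(cat[cat > 0]))
    Iu <- data[[indicator]]
    cols <- list()
    nms <- character(0)
    for (l in lev) {
      if (by_sex) {
        cols[[length(cols) + 1L]] <- (cat == l) * Iu * (data$sex == "male")
        cols[[length(cols) + 1L]] <- (cat == l) * Iu * (data$sex == "female")
        nms <- c(nms, paste0(label, ":cat", l, ":m"),
                 paste0(label, ":cat", l, ":f"))
      } else {
        cols[[length(cols) + 1L]] <- (cat == l) * Iu
        nms <- c(nms, paste0(label, ":cat", l))
      }
    }
    Z <- if (length(cols)) do.call(cbind, cols) else
      matrix(0, length(cat), 0)
    colnames(Z) <- nms
    # a level with no matching person-time is unidentifiable: drop it
    keep <- colSums(abs(Z)) > 0
    list(Z = Z[, keep, drop = FALSE])
  }
  term <- new_err_term(
    "surrogate", label, character(0), build,
    E = function(th, bd) if (ncol(bd$Z)) drop(bd$Z %*% th) else
      rep(0, nrow(bd$Z)),
    dE = function(th, bd) bd$Z,
    d2E = function(th, bd) array(0, c(nrow(bd$Z), ncol(bd$Z), ncol(bd$Z))))
  term$dynamic_pars <- TRUE  # parameter set depends on levels in the data
  term
}

#' Declare an ERR rate model
#'
#' Combines a log-linear baseline (a formula over person-year-table
#' columns) with a list of ERR terms. The fitted rate for a cell is
#' `exp(X gamma) * (1 + sum of term ERRs)`; terms carrying an `indicator`
#' (such as an internal-dose term applying to monitored person-time, or
#' surrogate-category levels applying to unmonitored person-time) realize
#' the composite ERR split across monitoring status.
#'
#' @param baseline One-sided formula for the log baseline rate, e.g.
#'   `~ log(mean_age / 60) + sex + smoking`.
#' @param terms A single `err_term` or list of terms (possibly empty for
#'   a background-only model).
#' @return An object of class `err_model`.
#' @examples
#' err_model(~ log(mean_age / 60) + sex, err_linear("mean_dose_ext"))
#' @export
err_model <- function(baseline = ~1, terms = list()) {
  stopifnot(inherits(baseline, "formula"))
  if (inherits(terms, "err_term")) terms <- list(terms)
  stopifnot(all(vapply(terms, inherits, logical(1), "err_term")))
  structure(list(baseline = baseline, terms = terms), class = "err_model")
}

#' @export
print.err_model <- function(x, ...) {
  cat("<err_model> baseline:", deparse(x$baseline), "\n terms:",
      if (length(x$terms)) paste(vapply(x$terms, `[[`, character(1), "type"),
                                 collapse = " + ") else "(none)", "\n")
  invisible(x)
}

# Add derived helper columns used by baseline formulas and indicators.
augment_cells <- function(data) {
  if (!".I_mon" %in% names(data)) {
    data$.I_mon <- if ("monitoring" %in% names(data)) {
      as.numeric(data$monitoring != "unmonitored")
    } else 0
  }
  data$.I_unmon <- 1 - data$.I_mon
  if (!"birth_year_c" %in% names(data) &&
      all(c("mean_year", "mean_age") %in% names(data))) {
    data$birth_year_c <- (data$mean_year - data$mean_age - 1915) / 10
  }
  if (!"migrant" %in% names(data) && "migration" %in% names(data)) {
    data$migrant <- as.numeric(data$migration == "migrant")
  }
  data
}

# Prepare model matrices and term data for a person-year table.
prepare_model <- function(model, data) {
  data <- augment_cells(data)
  X <- stats::model.matrix(model$baseline, data)
  built <- lapply(model$terms, function(tm) tm$build(data))
  par_names <- colnames(X)
  idx <- list()
  pos <- ncol(X)
  for (i in seq_along(model$terms)) {
    tm <- model$terms[[i]]
    pn <- if (isTRUE(tm$dynamic_pars)) colnames(built[[i]]$Z) else tm$par_names
    idx[[i]] <- if (length(pn)) pos + seq_along(pn) else integer(0)
    pos <- pos + length(pn)
    par_names <- c(par_names, pn)
  }
  list(data = data, X = X, built = built, idx = idx,
       par_names = paste0(ifelse(seq_along(par_names) <= ncol(X), "b:", ""),
                          par_names),
       n_base = ncol(X), n_par = pos)
}

# Composite ERR vector and its derivative blocks at theta.
err_components <- function(model, prep, params, deriv = FALSE) {
  n <- nrow(prep$X)
  E <- rep(0, n)
  parts <- list()
  dE <- if (deriv) matrix(0, n, prep$n_par - prep$n_base)
  d2 <- if (deriv) array(0, c(n, prep$n_par - prep$n_base,
                              prep$n_par - prep$n_base))
  for (i in seq_along(model$terms)) {
    tm <- model$terms[[i]]
    id <- prep$idx[[i]]
    th <- params[id]
    Ei <- if (length(id)) tm$E(th, prep$built[[i]]) else
      tm$E(numeric(0), prep$built[[i]])
    E <- E + Ei
    parts[[tm$label]] <- Ei
    if (deriv && length(id)) {
      loc <- id - prep$n_base
      dE[, loc] <- tm$dE(th, prep$built[[i]])
      d2[, loc, loc] <- tm$d2E(th, prep$built[[i]])
    }
  }
  list(E = E, parts = parts, dE = dE, d2E = d2)
}

#' Evaluate the composite ERR for table cells
#'
#' @param model An [err_model()].
#' @param params Named or positional parameter vector (baseline
#'   coefficients first, then ERR parameters in term order).
#' @param data Person-year table (or any data frame with the required
#'   columns).
#' @return Numeric vector of ERR values, one per row; an error is raised
#'   if `1 + ERR <= 0` anywhere (inadmissible point).
#' @export
evaluate_err <- function(model, params, data) {
  prep <- prepare_model(model, data)
  n_err <- prep$n_par - prep$n_base
  full <- if (length(params) == prep$n_par) {
    params
  } else if (length(params) == n_err) {
    c(rep(0, prep$n_base), params)
  } else {
    stop("`params` must supply all ", prep$n_par, " parameters or the ",
         n_err, " ERR parameters", call. = FALSE)
  }
  E <- err_components(model, prep, full)$E
  if (any(1 + E <= 0)) {
    stop("inadmissible parameters: 1 + ERR <= 0 for some cells",
         call. = FALSE)
  }
  E
}

#' Expected deaths for table cells
#'
#' `py * exp(X gamma) * (1 + ERR)`.
#'
#' @inheritParams evaluate_err
#' @return Numeric vector of expected counts.
#' @export
expected_count <- function(model, params, data) {
  prep <- prepare_model(model, data)
  mu_parts(model, prep, params)$mu
}

mu_parts <- function(model, prep, params, deriv = FALSE) {
  gamma <- params[seq_len(prep$n_base)]
  ec <- err_components(model, prep, params, deriv = deriv)
  B <- as.numeric(prep$data$py * exp(drop(prep$X %*% gamma)))
  list(B = B, E = ec$E, parts = ec$parts, dE = ec$dE, d2E = ec$d2E,
       mu = B * (1 + ec$E))
}

#' Grouped-Poisson log-likelihood of an ERR model
#'
#' `sum(events * log(mu) - mu)` over cells with positive person-years
#' (dropping the parameter-free `log(events!)` constant).
#'
#' @inheritParams evaluate_err
#' @param table Person-year table with `py` and `events`.
#' @return Scalar log-likelihood; inadmissible parameters
#'   (`1 + ERR <= 0` on a cell with person-time) raise an error.
#' @export
loglik <- function(model, params, table) {
  table <- table[table$py > 0, , drop = FALSE]
  prep <- prepare_model(model, table)
  mp <- mu_parts(model, prep, params)
  if (any(1 + mp$E <= 0)) {
    stop("inadmissible parameters: 1 + ERR <= 0 for some cells",
         call. = FALSE)
  }
  sum(ifelse(table$events > 0, table$events * log(mp$mu), 0) - mp$mu)
}
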