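R_KCAL <- 1.9872e-3  # gas constant, kcal/(mol K)

#' Describe an ITC titration protocol
#'
#' @param cell_volume Active cell volume in litres (default 1.4e-3, a
#'   VP-ITC class instrument).
#' @param cell_conc Macromolecule concentration in the cell, mol/L.
#' @param syringe_conc Ligand concentration in the syringe, mol/L.
#' @param injection_volumes Per-injection volumes in litres.
#' @param temperature Kelvin (default 298.15, i.e. 25 C).
#' @return A `titration_protocol` list.
#' @export
titration_protocol <- function(cell_volume = 1.4e-3, cell_conc, syringe_conc,
                               injection_volumes, temperature = 298.15) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            temperature > 0, all(injection_volumes > 0))
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature),
            class = "titration_protocol")
}

#' Binding parameters of the one-set-of-sites model
#'
#' @param n Stoichiometry (sites per macromolecule, > 0).
#' @param Kd Dissociation constant in mol/L (> 0); `Ka = 1/Kd`.
#' @param dH Binding enthalpy in kcal/mol.
#' @return A `binding_params` list.
#' @export
binding_params <- function(n, Kd, dH) {
  stopifnot(n > 0, Kd > 0, is.finite(dH))
  structure(list(n = n, Kd = Kd, dH = dH), class = "binding_params")
}

# Fractional saturation of a single class of n identical sites:
# Theta solves Ka = Theta / ((1 - Theta) * (X - n * Theta * M)), i.e. the
# root in [0, 1] of the binding quadratic.
wiseman_theta <- function(M, X, n, Ka) {
  if (M <= 0 || X <= 0) return(0)
  r <- 1 / (n * Ka * M)
  x <- X / (n * M)
  disc <- (1 + x + r)^2 - 4 * x
  if (disc < 0) {
    warning("negative discriminant clamped to 0", call. = FALSE)
    disc <- 0
  }
  theta <- (1 + x + r - sqrt(disc)) / 2
  min(max(theta, 0), 1)
}

#' Cumulative binding heat of the one-set-of-sites isotherm
#'
#' Total heat content of the cell at total concentrations `M_t`
#' (macromolecule) and `X_t` (ligand):
#' `Q = n * Theta * M_t * dH * V0`, where `Theta` is the fractional
#' saturation solving the single-site binding quadratic.
#'
#' @param M_t Total macromolecule concentration, mol/L (>= 0).
#' @param X_t Total ligand concentration, mol/L (>= 0).
#' @param params A [binding_params()].
#' @param V0 Cell volume, litres.
#' @return Cumulative heat in kcal.
#' @export
cumulative_heat <- function(M_t, X_t, params, V0) {
  stopifnot(M_t >= 0, X_t >= 0, V0 > 0)
  theta <- wiseman_theta(M_t, X_t, params$n, 1 / params$Kd)
  params$n * theta * M_t * params$dH * V0
}

# Total concentrations in the cell after each injection under the
# instantaneous-mixing displacement model: injecting volume v displaces a
# fraction f = v/V0 of well-mixed cell contents.
itc_concentrations <- function(protocol) {
  V0 <- protocol$cell_volume
  M <- protocol$cell_conc
  X <- 0
  k <- length(protocol$injection_volumes)
  out <- data.frame(injection = seq_len(k), M = numeric(k), X = numeric(k))
  for (i in seq_len(k)) {
    f <- protocol$injection_volumes[i] / V0
    M <- M * (1 - f)
    X <- X * (1 - f) + protocol$syringe_conc * f
    out$M[i] <- M
    out$X[i] <- X
  }
  out$molar_ratio <- out$X / out$M
  out
}

# Model-predicted per-injection heats. The measured heat of injection i is
# the change in cell heat content plus the half-volume correction for heat
# carried out by displaced liquid:
#   q_i = Q_i - Q_{i-1} + (v_i/V0) * (Q_i + Q_{i-1}) / 2 + q_dil
predict_injection_heats <- function(protocol, params, q_dil = 0) {
  conc <- itc_concentrations(protocol)
  V0 <- protocol$cell_volume
  Qprev <- 0
  q <- numeric(nrow(conc))
  for (i in seq_len(nrow(conc))) {
    Qi <- cumulative_heat(conc$M[i], conc$X[i], params, V0)
    f <- protocol$injection_volumes[i] / V0
    q[i] <- Qi - Qprev + f * (Qi + Qprev) / 2 + q_dil
    Qprev <- Qi
  }
  q
}

#' Simulate a thermogram from the one-set-of-sites model
#'
#' Forward-simulates per-injection heats under the displacement dilution
#' model, adding a constant dilution-heat offset and Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param protocol A [titration_protocol()].
#' @param params A [binding_params()].
#' @param noise_sd Gaussian noise standard deviation, kcal (>= 0).
#' @param q_dil Constant dilution-heat offset per injection, kcal.
#' @param seed Optional integer seed.
#' @return A `thermogram`: list with `heats` (kcal per injection) and
#'   `protocol`.
#' @export
simulate_titration <- function(protocol, params, noise_sd = 0, q_dil = 0,
                               seed = NULL) {
  stopifnot(noise_sd >= 0)
  q <- predict_injection_heats(protocol, params, q_dil)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- q + stats::rnorm(length(q), 0, noise_sd)
  }
  thermogram(q, protocol)
}

#' Bundle per-injection heats with their protocol
#'
#' @param heats Numeric vector, kcal per injection; length must match the
#'   protocol's injection count.
#' @param protocol A [titration_protocol()].
#' @return A `thermogram` object.
#' @export
thermogram <- function(heats, protocol) {
  heats <- as.numeric(heats)
  if (length(heats) != length(protocol$injection_volumes)) {
    stop("heats length must match protocol injection count", call. = FALSE)
  }
  if (any(!is.finite(heats))) stop("heats must be finite", call. = FALSE)
  structure(list(heats = heats, protocol = protocol), class = "thermogram")
}

#' Fit the one-set-of-sites model to a thermogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) over stoichiometry `n`,
#' association constant `Ka` (fitted as log10 Ka), enthalpy `dH` and a
#' constant per-injection dilution offset `q_dil`. Derived quantities:
#' `Kd = 1/Ka`, `dG = R T ln Kd`, `-TdS = dG - dH`, and the Wiseman
#' c-value `c = n * M0 / Kd` (a warning is attached when c falls outside
#' the reliable window of about 1 to 1000). Multiple log-spaced Ka starts
#' are tried and the best-SSE converged fit is kept.
#'
#' @param tg A `thermogram`.
#' @param init Optional [binding_params()] used as the starting point.
#' @param fit_dilution Fit `q_dil` as a free constant (default `TRUE`); if
#'   `FALSE` it is fixed at 0 (use after control subtraction).
#' @param discard_first Drop the first injection before fitting (common
#'   practice for syringe-diffusion artefacts; default `FALSE`).
#' @return An `itc_fit`: list with `params` ([binding_params()]), `q_dil`,
#'   `dG`, `minus_TdS`, `c_value`, `se` (named vector: `n`, `Kd`, `dH`),
#'   `converged`, `warnings`, `fitted`, `residuals`.
#' @export
fit_one_set_of_sites <- function(tg, init = NULL, fit_dilution = TRUE,
                                 discard_first = FALSE) {
  stopifnot(inherits(tg, "thermogram"))
  protocol <- tg$protocol
  q <- tg$heats
  keep <- seq_along(q)
  if (discard_first) keep <- keep[-1L]
  n_par <- 3L + as.integer(fit_dilution)
  if (length(keep) < n_par) {
    stop("under-determined: fewer usable injections than parameters",
         call. = FALSE)
  }
  if (length(keep) < 4L) stop("need >= 4 usable injections", call. = FALSE)

  model_fn <- function(n, logKa, dH, q0) {
    p <- list(n = n, Kd = 10^(-logKa), dH = dH)
    class(p) <- "binding_params"
    predict_injection_heats(protocol, p)[keep] + q0
  }

  conc <- itc_concentrations(protocol)
  # starts: stoichiometric first-injection guess for dH, grid over Ka
  dH0 <- q[keep[1L]] / (conc$X[keep[1L]] * protocol$cell_volume)
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1
  q0_0 <- if (fit_dilution) stats::median(utils::tail(q[keep], 3L)) else 0
  logKa_grid <- if (is.null(init)) {
    log10(c(1, 10, 100, 1000) / protocol$cell_conc)
  } else {
    log10(1 / init$Kd)
  }
  if (!is.null(init)) dH0 <- init$dH

  best <- NULL
  warns <- character(0)
  for (lka in logKa_grid) {
    start <- list(n = if (is.null(init)) 1 else init$n, logKa = lka,
                  dH = dH0, q0 = q0_0)
    if (!fit_dilution) start$q0 <- NULL
    fml <- if (fit_dilution) {
      qq ~ model_fn(n, logKa, dH, q0)
    } else {
      qq ~ model_fn(n, logKa, dH, 0)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = list(qq = q[keep]), start = start,
                        lower = c(n = 1e-3, logKa = 0, dH = -1e3,
                                  q0 = -Inf)[names(start)],
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warns <- c(warns, conditionMessage(fit))
      next
    }
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }

  T <- protocol$temperature
  if (is.null(best)) {
    return(structure(list(params = NULL, q_dil = NA_real_, dG = NA_real_,
                          minus_TdS = NA_real_, c_value = NA_real_,
                          se = c(n = NA, Kd = NA, dH = NA),
                          converged = FALSE, warnings = unique(warns),
                          fitted = NULL, residuals = NULL),
                     class = "itc_fit"))
  }
  fit <- best$fit
  cf <- stats::coef(fit)
  Kd <- 10^(-cf[["logKa"]])
  params <- binding_params(cf[["n"]], Kd, cf[["dH"]])
  q_dil <- if (fit_dilution) cf[["q0"]] else 0
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  se_out <- c(n = NA_real_, Kd = NA_real_, dH = NA_real_)
  if (!is.null(se)) {
    se_out["n"] <- se[["n"]]
    se_out["Kd"] <- Kd * log(10) * se[["logKa"]]  # delta method on log10 Ka
    se_out["dH"] <- se[["dH"]]
  }
  c_value <- params$n * protocol$cell_conc / Kd
  if (c_value < 1 || c_value > 1000) {
    warns <- c(warns, sprintf(
      "c-value %.3g outside the reliable window [1, 1000]", c_value))
    warning(warns[length(warns)], call. = FALSE)
  }
  dG <- delta_g(Kd, T)
  structure(list(params = params, q_dil = q_dil, dG = dG,
                 minus_TdS = dG - params$dH, c_value = c_value,
                 se = se_out, converged = TRUE, warnings = unique(warns),
                 fitted = stats::fitted(fit), residuals = stats::resid(fit)),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("itc_fit: did not converge\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf(
    "itc_fit: n = %.3f, Kd = %.3g M, dH = %.2f kcal/mol (c = %.3g)\n",
    p$n, p$Kd, p$dH, x$c_value))
  cat(sprintf("  dG = %.2f kcal/mol, -TdS = %.2f kcal/mol, q_dil = %.3g kcal\n",
              x$dG, x$minus_TdS, x$q_dil))
  invisible(x)
}

#' Read a thermogram CSV
#'
#' Expects columns `injection_index`, `volume_uL`, `heat_ucal`; volumes and
#' heats are converted to litres and kcal.
#'
#' @param path CSV path.
#' @param cell_volume,cell_conc,syringe_conc,temperature Protocol fields
#'   (see [titration_protocol()]) not stored in the CSV.
#' @return A `thermogram`.
#' @export
read_thermogram_csv <- function(path, cell_volume = 1.4e-3, cell_conc,
                                syringe_conc, temperature = 298.15) {
  df <- utils::read.csv(path)
  df <- df[order(df$injection_index), , drop = FALSE]
  protocol <- titration_protocol(cell_volume, cell_conc, syringe_conc,
                                 df$volume_uL * 1e-6, temperature)
  thermogram(df$heat_ucal * 1e-9, protocol)  # 1 kcal = 1e9 ucal
}

#' Write a thermogram to CSV (volumes in uL, heats in ucal)
#'
#' @param tg A `thermogram`.
#' @param path Output CSV path.
#' @return `tg`, invisibly.
#' @export
write_thermogram_csv <- function(tg, path) {
  df <- data.frame(injection_index = seq_along(tg$heats),
                   volume_uL = tg$protocol$injection_volumes * 1e6,
                   heat_ucal = tg$heats * 1e9)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(tg)
}
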