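#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(Kd)` with `R = 1.9872e-3` kcal/(mol K) and `Kd` in mol/L
#' (so `Kd = 1` M is the zero reference state).
#'
#' @param Kd Dissociation constant, mol/L (> 0). Vectorised.
#' @param T Temperature in Kelvin (default 298.15).
#' @return Free energy in kcal/mol (negative for sub-molar Kd).
#' @export
delta_g <- function(Kd, T = 298.15) {
  if (any(!is.finite(Kd)) || any(Kd <= 0)) {
    stop("Kd must be finite and > 0 (mol/L)", call. = FALSE)
  }
  R_KCAL * T * log(Kd)
}

#' Ligand efficiency
#'
#' `LE = -dG / N_heavy` in (kcal/mol) per heavy atom: binding free energy
#' normalised by ligand size, the standard currency for comparing fragment
#' hits with elaborated leads.
#'
#' @inheritParams delta_g
#' @param n_heavy Number of non-hydrogen atoms in the ligand (>= 1).
#' @return Ligand efficiency, (kcal/mol)/heavy atom. Vectorised.
#' @export
ligand_efficiency <- function(Kd, n_heavy, T = 298.15) {
  if (any(n_heavy < 1) || any(n_heavy != as.integer(n_heavy))) {
    stop("n_heavy must be a positive integer count", call. = FALSE)
  }
  -delta_g(Kd, T) / n_heavy
}

#' Tabulate Kd, dG and ligand efficiency for a compound series
#'
#' @param compound Compound labels.
#' @inheritParams ligand_efficiency
#' @return Data frame `compound`, `Kd_molar`, `dG_kcal_mol`, `LE`
#'   (full precision) and `LE_2dp` (presentation rounding, 2 decimals).
#' @export
le_table <- function(compound, Kd, n_heavy, T = 298.15) {
  le <- ligand_efficiency(Kd, n_heavy, T)
  data.frame(compound = as.character(compound), Kd_molar = Kd,
             n_heavy = as.integer(n_heavy), dG_kcal_mol = delta_g(Kd, T),
             LE = le, LE_2dp = round(le, 2), stringsAsFactors = FALSE)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits `y = bottom + (top - bottom) / (1 + (EC50/c)^hill)` by nonlinear
#' least squares on log10 concentration (self-starting logistic). A flat
#' response, or any fit failure, returns `ec50 = NA` with
#' `converged = FALSE` rather than an error; an EC50 outside the tested
#' concentration range is flagged via `in_range`.
#'
#' @param concentrations Dose values, mol/L (> 0); at least 5 points
#'   spanning at least 2 log units.
#' @param responses Observed responses, same length.
#' @return List: `bottom`, `top`, `ec50` (mol/L), `hill`, `converged`,
#'   `in_range`, `fitted`.
#' @export
fit_4pl <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(concentrations) < 5L) {
    stop("need >= 5 dose points", call. = FALSE)
  }
  lx <- log10(concentrations)
  if (diff(range(lx)) < 2) {
    stop("doses must span >= 2 log units", call. = FALSE)
  }
  df <- data.frame(x = lx, y = responses)
  # scaleOffset keeps the convergence test meaningful on noise-free data
  fit <- tryCatch(
    stats::nls(y ~ stats::SSfpl(x, A, B, xmid, scal), data = df,
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    start <- tryCatch(
      stats::getInitial(y ~ stats::SSfpl(x, A, B, xmid, scal), data = df),
      error = function(e) NULL)
    if (!is.null(start)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A + (B - A) / (1 + exp((xmid - x) / scal)),
                          data = df, start = as.list(start)),
        error = function(e) e)
    }
  }
  if (inherits(fit, "error")) {
    return(list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                hill = NA_real_, converged = FALSE, in_range = FALSE,
                fitted = NULL))
  }
  cf <- stats::coef(fit)
  ec50 <- 10^cf[["xmid"]]
  # SSfpl: y = A + (B-A)/(1+exp((xmid-x)/scal));  hill = 1/(scal ln10)
  hill <- 1 / (cf[["scal"]] * log(10))
  in_range <- ec50 >= min(concentrations) && ec50 <= max(concentrations)
  if (!in_range) {
    warning("EC50 outside tested concentration range", call. = FALSE)
  }
  # flag fits whose residual scale rivals the response range (e.g. strongly
  # non-monotone data) without failing them
  rmse <- sqrt(mean(stats::resid(fit)^2))
  if (rmse > 0.25 * max(abs(cf[["B"]] - cf[["A"]]), .Machine$double.eps)) {
    warning("poor 4PL fit: residual scale comparable to response range",
            call. = FALSE)
  }
  list(bottom = cf[["A"]], top = cf[["B"]], ec50 = ec50, hill = hill,
       converged = TRUE, in_range = in_range,
       fitted = as.numeric(stats::fitted(fit)))
}
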