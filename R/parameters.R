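#' Population parameters of the platelet reconstitution model
#'
#' Constructs the population prior: typical values of all structural
#' parameters, inter-individual variability (IIV) as percent coefficients of
#' variation, the residual-error model and the ATG kinetic-pharmacodynamic
#' settings. Defaults are the published typical values of the model; they are
#' also shipped as a JSON profile in `inst/extdata/population_parameters.json`.
#'
#' Structural parameters (units):
#' \describe{
#'   \item{baseline_plt_pat}{pre-HCT baseline platelet count, 1e9/L (90.5)}
#'   \item{mmt_pat}{mean maturation time pre-HCT, days (6.1)}
#'   \item{rho}{fractional inhibition of patient HSC proliferation during
#'     conditioning, in \[0, 1\] (0.945)}
#'   \item{day1_boost}{platelet bolus at transplant, 1e9/L (20.1)}
#'   \item{sibling_boost_ratio}{multiplier on `day1_boost` for related donors
#'     (2.75)}
#'   \item{transfusion_boost}{platelet bolus per transfusion, 1e9/L (10.6)}
#'   \item{atg_alpha}{linear ATG concentration-effect slope on platelet
#'     elimination, 1/mg (0.01; calibrated, see the methods vignette)}
#'   \item{atg_kint}{first-order ATG elimination rate, 1/day (0.35)}
#'   \item{graft10}{graft-cell dose / post-HCT baseline, 1e9/L (72.4)}
#'   \item{mmt_gt}{mean maturation time post-HCT, days (7.0)}
#'   \item{gamma}{feedback exponent on Graft1_0/PLT_GT (0.19)}
#'   \item{ttbm}{time to bone marrow, days (1.5)}
#'   \item{kel}{HCT-effect elimination rate, 1/day (0.353)}
#'   \item{hct0}{HCT-effect magnitude at day 0, dimensionless (4.22)}
#'   \item{tp_median}{total-protein centering constant, g/dL (5.43)}
#'   \item{tp_exponent}{total-protein effect exponent (0.197)}
#'   \item{n_transit}{transit compartments per submodel (3)}
#' }
#'
#' IIV is log-normal: a parameter with coefficient of variation CV gets
#' variance `omega^2 = log(1 + CV^2)` on the log scale, so all realized
#' parameters stay positive. Parameters without a published CV are fixed.
#'
#' @param ... named overrides of any structural parameter (e.g. `gamma = 0`).
#' @param iiv_cv named numeric vector of percent CVs; overrides are merged
#'   into the published defaults. Set a value to 0 to fix a parameter.
#' @param residual_error list with elements `prop` (proportional SD as a
#'   fraction) and `add` (additive SD, 1e9/L). Default 20% + 2e9/L combined.
#' @return an object of class `plt_population` with elements `theta`,
#'   `iiv_cv` and `residual_error`.
#' @examples
#' pop <- population_parameters()
#' pop$theta[["baseline_plt_pat"]]
#' population_parameters(gamma = 0, iiv_cv = c(graft10 = 0))
#' @export
population_parameters <- function(..., iiv_cv = NULL, residual_error = NULL) {
  theta <- c(
    baseline_plt_pat = 90.5,
    mmt_pat = 6.1,
    rho = 0.945,
    day1_boost = 20.1,
    sibling_boost_ratio = 2.75,
    transfusion_boost = 10.6,
    atg_alpha = 0.01,
    atg_kint = 0.35,
    graft10 = 72.4,
    mmt_gt = 7.0,
    gamma = 0.19,
    ttbm = 1.5,
    kel = 0.353,
    hct0 = 4.22,
    tp_median = 5.43,
    tp_exponent = 0.197,
    n_transit = 3
  )
  cv <- setNames(numeric(length(theta)), names(theta))
  cv[c("baseline_plt_pat", "rho", "day1_boost", "transfusion_boost",
       "graft10", "mmt_gt", "gamma", "hct0")] <-
    c(115.0, 152.3, 289.7, 67.9, 82.9, 90.9, 48.7, 87.1)

  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(theta))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    theta[names(dots)] <- unlist(dots)
  }
  if (!is.null(iiv_cv)) {
    bad <- setdiff(names(iiv_cv), names(theta))
    if (length(bad))
      stop("unknown IIV parameter(s): ", paste(bad, collapse = ", "))
    cv[names(iiv_cv)] <- iiv_cv
  }
  err <- list(prop = 0.2, add = 2.0)
  if (!is.null(residual_error)) err <- modifyList(err, residual_error)

  pop <- structure(list(theta = theta, iiv_cv = cv, residual_error = err),
                   class = "plt_population")
  validate_population(pop)
  pop
}

validate_population <- function(pop) {
  th <- pop$theta
  pos <- c("baseline_plt_pat", "mmt_pat", "day1_boost", "sibling_boost_ratio",
           "transfusion_boost", "graft10", "mmt_gt", "ttbm", "kel",
           "tp_median")
  if (any(th[pos] <= 0))
    stop("parameters must be strictly positive: ",
         paste(pos[th[pos] <= 0], collapse = ", "))
  if (th[["rho"]] < 0 || th[["rho"]] > 1)
    stop("rho must lie in [0, 1]")
  if (th[["n_transit"]] < 1 || th[["n_transit"]] != round(th[["n_transit"]]))
    stop("n_transit must be a positive integer")
  if (any(pop$iiv_cv < 0)) stop("IIV %CVs must be non-negative")
  if (pop$residual_error$prop < 0 || pop$residual_error$add < 0)
    stop("residual-error components must be non-negative")
  invisible(pop)
}

#' @export
print.plt_population <- function(x, ...) {
  cat("Platelet reconstitution model: population parameters\n")
  tab <- data.frame(value = signif(x$theta, 4), iiv_cv = x$iiv_cv)
  print(tab)
  cat(sprintf("Residual error: proportional %.0f%% + additive %.3g x10^9/L\n",
              100 * x$residual_error$prop, x$residual_error$add))
  invisible(x)
}

#' Names of the parameters carrying inter-individual variability
#'
#' @param pop a `plt_population` object.
#' @return character vector of parameter names with CV > 0 (in the default
#'   prior: the eight published ones).
#' @export
iiv_parameters <- function(pop) {
  names(pop$iiv_cv)[pop$iiv_cv > 0]
}

#' Log-normal IIV standard deviations (omega) from percent CVs
#'
#' Maps `CV%` to `omega = sqrt(log(1 + (CV/100)^2))`, the standard deviation
#' of the log-normal random effect.
#'
#' @param pop a `plt_population` object.
#' @return named numeric vector of omegas for [iiv_parameters()].
#' @export
iiv_omega <- function(pop) {
  nm <- iiv_parameters(pop)
  sqrt(log(1 + (pop$iiv_cv[nm] / 100)^2))
}

#' Realize individual parameters from random effects
#'
#' Applies a log-normal random-effect vector `eta` to the population typical
#' values: `theta_i = theta * exp(eta)` for every parameter carrying IIV.
#' The conditioning inhibition `rho` is truncated at 1 so the realized value
#' respects its \[0, 1\] domain.
#'
#' @param pop a `plt_population` object.
#' @param eta named numeric vector of random effects on the log scale; names
#'   must be a subset of [iiv_parameters()]. Missing entries are taken as 0.
#' @return an object of class `plt_individual`: list with `values` (full
#'   realized parameter vector) and `eta`.
#' @examples
#' pop <- population_parameters()
#' realize_parameters(pop, c(graft10 = 0.5))$values[["graft10"]]
#' @export
realize_parameters <- function(pop, eta = NULL) {
  nm <- iiv_parameters(pop)
  full_eta <- setNames(numeric(length(nm)), nm)
  if (!is.null(eta) && length(eta)) {
    if (is.null(names(eta)) && length(eta) == length(nm)) names(eta) <- nm
    bad <- setdiff(names(eta), nm)
    if (length(bad))
      stop("eta given for fixed parameter(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(eta))) stop("eta must be finite")
    full_eta[names(eta)] <- eta
  }
  values <- pop$theta
  values[nm] <- values[nm] * exp(full_eta)
  values[["rho"]] <- min(values[["rho"]], 1)
  structure(list(values = values, eta = full_eta,
                 residual_error = pop$residual_error),
            class = "plt_individual")
}

#' Sample individual parameters from the population prior
#'
#' Draws one log-normal random-effect vector per subject
#' (`eta ~ N(0, omega^2)`, independent across parameters) and realizes the
#' individual parameter set via [realize_parameters()].
#'
#' @param pop a `plt_population` object.
#' @param seed integer seed; required for reproducibility.
#' @param n number of subjects.
#' @return a single `plt_individual` if `n == 1`, else a list of them.
#' @examples
#' pop <- population_parameters()
#' ind <- sample_individual_parameters(pop, seed = 1)
#' ind$values[["graft10"]]
#' @export
sample_individual_parameters <- function(pop, seed, n = 1) {
  if (!missing(seed) && !is.null(seed)) set.seed(as.integer(seed))
  omega <- iiv_omega(pop)
  draws <- lapply(seq_len(n), function(i) {
    eta <- rnorm(length(omega), 0, omega)
    names(eta) <- names(omega)
    realize_parameters(pop, eta)
  })
  if (n == 1) draws[[1]] else draws
}

#' @export
print.plt_individual <- function(x, ...) {
  cat("Individual parameter realization\n")
  nm <- names(x$eta)
  tab <- data.frame(value = signif(x$values[nm], 4), eta = signif(x$eta, 3))
  print(tab)
  invisible(x)
}

#' Write / read a population-parameter profile as JSON
#'
#' The JSON document mirrors the `plt_population` structure (`theta`,
#' `iiv_cv`, `residual_error`) and round-trips exactly.
#'
#' @param pop a `plt_population` object.
#' @param path file path.
#' @return `read_parameters()` returns a `plt_population`;
#'   `write_parameters()` returns `path` invisibly.
#' @export
write_parameters <- function(pop, path) {
  jsonlite::write_json(
    list(theta = as.list(pop$theta), iiv_cv = as.list(pop$iiv_cv),
         residual_error = pop$residual_error),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pop <- structure(list(theta = unlist(x$theta), iiv_cv = unlist(x$iiv_cv),
                        residual_error = x$residual_error),
                   class = "plt_population")
  validate_population(pop)
  pop
}

# Deterministic per-subject seed derivation: counter-based so population
# results do not depend on execution order or on a shared RNG stream.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 16807) %% 2147483399) + 1L
}
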