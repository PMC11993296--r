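#' @name model_core
#' @title Core quantities of the 14-compartment model
#' @description
#' The model tracks platelets of patient (PAT) and graft (GT) origin through
#' two transit-compartment chains. The total platelet count is
#' `PLT(t) = PLT_PAT(t) + PLT_GT(t)`. State order:
#' `HSC_PAT, TR1..TR3_PAT, PLT_PAT, ATG, HCT, Graft1, Graft2, HSC_GT,
#' TR1..TR3_GT, PLT_GT`.
NULL

plt_state_names <- c("HSC_PAT", "TR1_PAT", "TR2_PAT", "TR3_PAT", "PLT_PAT",
                     "ATG", "HCT", "Graft1", "Graft2",
                     "HSC_GT", "TR1_GT", "TR2_GT", "TR3_GT", "PLT_GT")

#' Transit rate from a mean maturation time
#'
#' `K = (n + 1) / MMT` where `n` is the number of transit compartments.
#'
#' @param mmt mean maturation time in days (> 0).
#' @param n_transit number of transit compartments (>= 1).
#' @return transit rate, 1/day.
#' @examples
#' transit_rate(6.1, 3)   # patient chain, 0.6557
#' transit_rate(7.0, 3)   # graft chain, 0.5714
#' @export
transit_rate <- function(mmt, n_transit = 3) {
  if (any(mmt <= 0)) stop("mmt must be positive")
  if (any(n_transit < 1)) stop("n_transit must be >= 1")
  (n_transit + 1) / mmt
}

#' Conditioning drug effect
#'
#' The fractional inhibition of patient HSC proliferation is `rho` while
#' conditioning is administered (closed interval
#' `[conditioning_start, conditioning_stop]`) and 0 elsewhere.
#'
#' @param t time in days.
#' @param regimen a [treatment_regimen()].
#' @param rho fractional inhibition in \[0, 1\].
#' @return the inhibition fraction at `t` (vectorized over `t`).
#' @examples
#' reg <- treatment_regimen(-6, -2)
#' drug_effect(c(-10, -4, 3), reg, 0.945)
#' @export
drug_effect <- function(t, regimen, rho) {
  ifelse(t >= regimen$conditioning_start & t <= regimen$conditioning_stop,
         rho, 0)
}

#' Initial state of the model
#'
#' The pre-HCT baseline platelet count initializes the proliferating HSC
#' compartment, the three transit compartments and the circulating platelet
#' compartment of the patient submodel (a steady state of the patient chain);
#' all other compartments start at 0.
#'
#' @param params a `plt_individual` (or `plt_population`, in which case the
#'   typical values are used).
#' @return named state vector of length 14.
#' @examples
#' initialize_state(population_parameters())
#' @export
initialize_state <- function(params) {
  values <- param_values(params)
  y <- setNames(numeric(14), plt_state_names)
  y[c("HSC_PAT", "TR1_PAT", "TR2_PAT", "TR3_PAT", "PLT_PAT")] <-
    values[["baseline_plt_pat"]]
  y
}

param_values <- function(params) {
  if (inherits(params, "plt_population")) params$theta
  else if (inherits(params, "plt_individual")) params$values
  else if (is.numeric(params) && !is.null(names(params))) params
  else stop("params must be a plt_population or plt_individual")
}

#' Bolus event schedule
#'
#' All instantaneous inputs of the model: on day 0 the graft-cell dose enters
#' `Graft1`, the transplant-associated platelet boost (times the sibling
#' ratio for related donors) enters `PLT_PAT`, and the HCT-effect magnitude
#' enters `HCT` (the limit of a short zero-order input); each ATG dose enters
#' the virtual `ATG` compartment (in mg, kinetic-pharmacodynamic convention);
#' each platelet transfusion adds `transfusion_boost` to `PLT_PAT`.
#'
#' @param params a `plt_individual` or `plt_population`.
#' @param regimen a [treatment_regimen()].
#' @return data frame with columns `time`, `compartment`, `amount`, `type`,
#'   sorted by time.
#' @examples
#' event_schedule(population_parameters(),
#'                treatment_regimen(donor_relation = "related"))
#' @export
event_schedule <- function(params, regimen) {
  values <- param_values(params)
  t0 <- regimen$transplant_time
  ev <- data.frame(
    time = t0,
    compartment = c("Graft1", "PLT_PAT", "HCT"),
    amount = c(values[["graft10"]],
               day1_boost_amount(regimen$donor_relation, params),
               values[["hct0"]]),
    type = c("graft", "day1_boost", "hct"))
  if (!is.null(regimen$atg_doses) && nrow(regimen$atg_doses))
    ev <- rbind(ev, data.frame(time = regimen$atg_doses$time,
                               compartment = "ATG",
                               amount = regimen$atg_doses$dose,
                               type = "atg"))
  if (length(regimen$transfusion_times))
    ev <- rbind(ev, data.frame(time = regimen$transfusion_times,
                               compartment = "PLT_PAT",
                               amount = values[["transfusion_boost"]],
                               type = "transfusion"))
  ev[order(ev$time), , drop = FALSE]
}

#' Right-hand side of the 14-compartment ODE system
#'
#' Reference implementation in R of the model derivatives; the integrator
#' normally uses the identical compiled version. Patient chain: HSC
#' proliferation inhibited by the conditioning drug effect, platelet
#' elimination accelerated by `1 + alpha * ATG(t)`. Graft chain: HSC
#' proliferation carries the feedback `(Graft1_0 / PLT_GT)^gamma` (with
#' `PLT_GT` floored at `clamp` inside the ratio), the HCT-effect factor
#' `1 - HCT(t)`, and the total-protein multiplier; graft cells home to the
#' marrow through `Graft1 -> Graft2 -> HSC_GT` at rate `K_GR = 2 / TTBM`.
#'
#' @param t time, days.
#' @param state named state vector (see [initialize_state()]); must be
#'   non-negative and finite.
#' @param params a `plt_individual` or `plt_population`.
#' @param regimen a [treatment_regimen()].
#' @param covariates optional [covariate_series()].
#' @param clamp feedback floor for `PLT_GT` inside the ratio (1e9/L).
#' @param fb_cap upper bound on the feedback multiplier (numerical guard
#'   against explosive stiffness for extreme `gamma` draws).
#' @return named vector of derivatives, 1e9/L per day.
#' @examples
#' pop <- population_parameters()
#' reg <- treatment_regimen()
#' derivatives(-10, initialize_state(pop), pop, reg)  # steady state: all 0
#' @export
derivatives <- function(t, state, params, regimen, covariates = NULL,
                        clamp = 1e-3, fb_cap = 1000) {
  if (any(!is.finite(state)) || any(state < 0))
    stop("state must be finite and non-negative")
  v <- param_values(params)
  k_pat <- transit_rate(v[["mmt_pat"]], v[["n_transit"]])
  k_gt <- transit_rate(v[["mmt_gt"]], v[["n_transit"]])
  k_gr <- 2 / v[["ttbm"]]
  drug <- drug_effect(t, regimen, v[["rho"]])
  fb <- min((v[["graft10"]] / max(state[["PLT_GT"]], clamp))^v[["gamma"]],
            fb_cap)
  tpm <- tp_multiplier_at(t, covariates, v[["tp_median"]], v[["tp_exponent"]])
  s <- state
  d <- c(
    HSC_PAT = k_pat * (1 - drug) * s[["HSC_PAT"]] - k_pat * s[["HSC_PAT"]],
    TR1_PAT = k_pat * s[["HSC_PAT"]] - k_pat * s[["TR1_PAT"]],
    TR2_PAT = k_pat * s[["TR1_PAT"]] - k_pat * s[["TR2_PAT"]],
    TR3_PAT = k_pat * s[["TR2_PAT"]] - k_pat * s[["TR3_PAT"]],
    PLT_PAT = k_pat * s[["TR3_PAT"]] -
      k_pat * s[["PLT_PAT"]] * platelet_elimination_multiplier(s[["ATG"]],
                                                               v[["atg_alpha"]]),
    ATG = -v[["atg_kint"]] * s[["ATG"]],
    HCT = -v[["kel"]] * s[["HCT"]],
    Graft1 = -k_gr * s[["Graft1"]],
    Graft2 = k_gr * s[["Graft1"]] - k_gr * s[["Graft2"]],
    HSC_GT = k_gt * fb * (1 - s[["HCT"]]) * tpm * s[["HSC_GT"]] -
      k_gt * s[["HSC_GT"]] + k_gr * s[["Graft2"]],
    TR1_GT = k_gt * s[["HSC_GT"]] - k_gt * s[["TR1_GT"]],
    TR2_GT = k_gt * s[["TR1_GT"]] - k_gt * s[["TR2_GT"]],
    TR3_GT = k_gt * s[["TR2_GT"]] - k_gt * s[["TR3_GT"]],
    PLT_GT = k_gt * s[["TR3_GT"]] - k_gt * s[["PLT_GT"]]
  )
  d
}

# Parameter vector handed to the compiled RHS; layout documented in
# src/plt_model.c. The total-protein series is passed as a precomputed step
# function of multipliers and the ATG dose history as arrays evaluated in
# closed form.
plt_parms_vector <- function(values, regimen, covariates, clamp,
                             fb_cap = 1000) {
  max_tp <- 512L
  max_atg <- 32L
  p <- numeric(13 + 2 * max_tp + 1 + 2 * max_atg + 1)
  p[1] <- transit_rate(values[["mmt_pat"]], values[["n_transit"]])
  p[2] <- transit_rate(values[["mmt_gt"]], values[["n_transit"]])
  p[3] <- 2 / values[["ttbm"]]
  p[4] <- values[["rho"]]
  p[5] <- values[["atg_alpha"]]
  p[6] <- values[["atg_kint"]]
  p[7] <- values[["kel"]]
  p[8] <- values[["gamma"]]
  p[9] <- values[["graft10"]]
  p[10] <- regimen$conditioning_start
  p[11] <- regimen$conditioning_stop
  p[12] <- clamp
  st <- tp_step(covariates, values[["tp_median"]], values[["tp_exponent"]])
  n <- length(st$time)
  if (n > max_tp)
    stop("total-protein series longer than ", max_tp, " points")
  p[13] <- n
  if (n) {
    p[13 + seq_len(n)] <- st$time
    p[13 + max_tp + seq_len(n)] <- st$mult
  }
  base <- 13 + 2 * max_tp
  doses <- regimen$atg_doses
  if (!is.null(doses) && nrow(doses)) {
    if (nrow(doses) > max_atg)
      stop("more than ", max_atg, " ATG doses")
    p[base + 1] <- nrow(doses)
    p[base + 1 + seq_len(nrow(doses))] <- doses$time
    p[base + 1 + max_atg + seq_len(nrow(doses))] <- doses$dose
  }
  p[length(p)] <- fb_cap
  p
}
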