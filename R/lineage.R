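#' Four-stage epidermal lineage model
#'
#' The non-spatial population model tracks four stages of the keratinocyte
#' lineage: basal stem cells (`c0`), proliferative spinous cells (`c1`),
#' mature spinous cells (`c2`) and granular cells (`c3`). Basal cells divide
#' at rate `v0` and self-renew with probability `p0`; proliferative spinous
#' cells divide at rate `v1` and stay in cycle with probability `p1`; mature
#' spinous cells convert to granular cells at rate `d2`; granular cells are
#' removed at rate `d3`:
#'
#' \deqn{dc_0/dt = (2p_0-1)v_0 c_0}
#' \deqn{dc_1/dt = 2(1-p_0)v_0 c_0 + (2p_1-1)v_1 c_1}
#' \deqn{dc_2/dt = 2(1-p_1)v_1 c_1 - d_2 c_2}
#' \deqn{dc_3/dt = d_2 c_2 - d_3 c_3}
#'
#' Proliferation rates have the form `ln(2)/cycle length` so a rate of
#' `log(2)/24` corresponds to a 24-hour cell cycle.
#'
#' @param p0,p1 self-renewal probabilities in `[0, 1]`.
#' @param v0,v1 proliferation rates (1/hour), non-negative.
#' @param d2,d3 differentiation and removal rates (1/hour), non-negative.
#' @return `lineage_params()` returns a validated `epistrat_lineage_params`
#'   list.
#' @examples
#' lp <- lineage_params(p0 = 0.6, v0 = log(2) / 24)
#' lineage_rhs(c(c0 = 100, c1 = 0, c2 = 0, c3 = 0), lp)
#' @export
lineage_params <- function(p0 = 0.515, p1 = 0.2,
                           v0 = log(2) / 24, v1 = log(2) / 24,
                           d2 = 0.027, d3 = log(2) / 30) {
  for (nm in c("p0", "p1")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      abort(sprintf("`%s` must be a probability in [0, 1], got %s", nm, format(x)))
  }
  for (nm in c("v0", "v1", "d2", "d3")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      abort(sprintf("`%s` must be a non-negative rate (1/hour), got %s", nm, format(x)))
  }
  structure(list(p0 = p0, p1 = p1, v0 = v0, v1 = v1, d2 = d2, d3 = d3),
            class = "epistrat_lineage_params")
}

#' Ovol regulation of lineage rates
#'
#' Ovol1 (level `alpha`) and Ovol2 (level `beta`) inhibit basal proliferation
#' `v0` and self-renewal `p0` and stimulate spinous differentiation `d2`
#' through saturating inhibition / linear stimulation:
#'
#' \deqn{v_0 = v_{min} + v_T / (1 + \omega\alpha + \chi\beta)}
#' \deqn{p_0 = p_{min} + p_T / (1 + \lambda\alpha + \mu\beta)}
#' \deqn{d_2 = d_{DKO} + \varsigma\alpha + \xi\beta}
#'
#' The shipped defaults are calibrated so that the wild type maintains its
#' basal compartment (`p0 > 1/2`) and the qualitative layer-size phenotypes
#' of all Ovol mutant genotypes are reproduced at the default evaluation
#' horizon (see [genotype_phenotype()]); `p1`, `v1` and `d3` are not under
#' Ovol control and are carried in `base`.
#'
#' @param alpha,beta effective Ovol1 / Ovol2 levels (dimensionless, >= 0).
#' @param vmin,vT floor and saturating span of `v0` (1/hour).
#' @param omega,chi inhibition weights of Ovol1/Ovol2 on `v0`.
#' @param pmin,pT floor and span of `p0` (dimensionless; `pmin + pT <= 1`).
#' @param lam,mu_reg inhibition weights of Ovol1/Ovol2 on `p0` (this `mu_reg`
#'   is the regulatory weight, unrelated to the intracellular spring constant
#'   of [mechanics_params()]).
#' @param dDKO baseline `d2` with no Ovol input (1/hour).
#' @param sigma_c,xi stimulation weights of Ovol1/Ovol2 on `d2` (1/hour per
#'   unit level).
#' @param base an `epistrat_lineage_params` carrying the unregulated rates
#'   `p1`, `v1`, `d3`.
#' @return `ovol_regulation()` returns a validated `epistrat_ovol_regulation`
#'   list; `ovol_modulate()` returns the resulting [lineage_params()].
#' @examples
#' reg <- ovol_regulation(alpha = 1, beta = 1)
#' ovol_modulate(reg)
#' @export
ovol_regulation <- function(alpha = 1, beta = 1,
                            vmin = 0.01, vT = 0.03, omega = 0.3, chi = 0.3,
                            pmin = 0.495, pT = 0.04, lam = 0.5, mu_reg = 0.5,
                            dDKO = 0.001, sigma_c = 0.02, xi = 0.006,
                            base = lineage_params()) {
  fields <- c("alpha", "beta", "vmin", "vT", "omega", "chi",
              "pmin", "pT", "lam", "mu_reg", "dDKO", "sigma_c", "xi")
  for (nm in fields) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      abort(sprintf("regulation field `%s` must be a non-negative number, got %s",
                    nm, format(x)))
  }
  if (pmin + pT > 1 + 1e-12)
    abort("`pmin + pT` must not exceed 1: p0 is a probability")
  stopifnot(inherits(base, "epistrat_lineage_params"))
  structure(list(alpha = alpha, beta = beta, vmin = vmin, vT = vT,
                 omega = omega, chi = chi, pmin = pmin, pT = pT,
                 lam = lam, mu_reg = mu_reg, dDKO = dDKO,
                 sigma_c = sigma_c, xi = xi, base = base),
            class = "epistrat_ovol_regulation")
}

#' @rdname ovol_regulation
#' @param reg an `epistrat_ovol_regulation` object.
#' @export
ovol_modulate <- function(reg, alpha = reg$alpha, beta = reg$beta) {
  stopifnot(inherits(reg, "epistrat_ovol_regulation"))
  if (alpha < 0 || beta < 0) abort("Ovol levels `alpha`, `beta` must be >= 0")
  lineage_params(
    p0 = reg$pmin + reg$pT / (1 + reg$lam * alpha + reg$mu_reg * beta),
    p1 = reg$base$p1,
    v0 = reg$vmin + reg$vT / (1 + reg$omega * alpha + reg$chi * beta),
    v1 = reg$base$v1,
    d2 = reg$dDKO + reg$sigma_c * alpha + reg$xi * beta,
    d3 = reg$base$d3
  )
}

#' Genotype presets for effective Ovol levels
#'
#' Effective Ovol1 (`alpha`) and Ovol2 (`beta`) levels for the wild type and
#' the four mutant genotypes. Because Ovol1 and Ovol2 repress one another,
#' losing one de-represses the other: the Ovol1 knockout carries more Ovol2
#' than wild type, the Ovol2 skin-specific knockout more Ovol1, and the
#' Ovol2-overexpressing (BT) genotype has high Ovol2 and depressed Ovol1.
#' The double knockout has neither.
#'
#' @return a tibble with columns `genotype`, `alpha`, `beta`.
#' @examples
#' genotype_presets()
#' @export
genotype_presets <- function() {
  tibble(
    genotype = c("WT", "Ovol1KO", "Ovol2SSKO", "Ovol2BT", "OvolDKO"),
    alpha    = c(1,    0,         1.6,         0.5,       0),
    beta     = c(1,    1.25,      0,           10,        0)
  )
}

#' Lineage right-hand side
#'
#' Time derivatives of the four compartments under the lineage model; see
#' [lineage_params()] for the equations.
#'
#' @param state numeric vector `c(c0, c1, c2, c3)` (non-negative).
#' @param params an `epistrat_lineage_params` object.
#' @return named numeric 4-vector of derivatives (cells/hour).
#' @export
lineage_rhs <- function(state, params) {
  stopifnot(inherits(params, "epistrat_lineage_params"))
  state <- unname(as.numeric(state))
  if (length(state) != 4L || anyNA(state))
    abort("`state` must be a numeric 4-vector (c0, c1, c2, c3)")
  if (any(state < 0)) abort("`state` components must be non-negative")
  with(params, c(
    c0 = (2 * p0 - 1) * v0 * state[1],
    c1 = 2 * (1 - p0) * v0 * state[1] + (2 * p1 - 1) * v1 * state[2],
    c2 = 2 * (1 - p1) * v1 * state[2] - d2 * state[3],
    c3 = d2 * state[3] - d3 * state[4]
  ))
}

#' Integrate the lineage model
#'
#' Solves the four-compartment lineage system with an adaptive solver
#' (relative tolerance `1e-8`; the system is linear and non-stiff) and
#' returns the trajectory at multiples of `dt`.
#'
#' @param init numeric 4-vector of initial populations (non-negative), or a
#'   named vector with names `c0..c3`.
#' @param reg either an [ovol_regulation()] object (modulated rates are
#'   derived from its Ovol levels) or a [lineage_params()] object used as-is.
#' @param t_end duration (hours, >= 0).
#' @param dt output interval (hours, > 0).
#' @return a tibble with columns `t`, `c0`, `c1`, `c2`, `c3`, of class
#'   `epistrat_lineage_sim`.
#' @examples
#' traj <- simulate_lineage(c(100, 0, 0, 0), ovol_regulation(), t_end = 240)
#' tail(traj)
#' @export
simulate_lineage <- function(init, reg = ovol_regulation(), t_end = 240, dt = 1) {
  if (dt <= 0) abort("`dt` must be > 0")
  if (t_end < 0) abort("`t_end` must be >= 0")
  params <- if (inherits(reg, "epistrat_ovol_regulation")) ovol_modulate(reg)
            else if (inherits(reg, "epistrat_lineage_params")) reg
            else abort("`reg` must be an ovol_regulation or lineage_params object")
  init <- unname(as.numeric(init))
  if (length(init) != 4L || anyNA(init) || any(init < 0))
    abort("`init` must be a non-negative numeric 4-vector")
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  deriv <- function(t, y, p) list(unname(lineage_rhs(pmax(y, 0), p)))
  out <- deSolve::ode(y = init, times = times, func = deriv, parms = params,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (!all(is.finite(out)))
    abort(paste0("non-finite values during lineage integration near t = ",
                 format(max(out[stats::complete.cases(out), 1]))))
  traj <- tibble(t = out[, 1], c0 = out[, 2], c1 = out[, 3],
                 c2 = out[, 4], c3 = out[, 5])
  attr(traj, "params") <- params
  class(traj) <- c("epistrat_lineage_sim", class(traj))
  traj
}

#' Critical self-renewal probability
#'
#' The basal compartment grows when `(2 p0 - 1) v0 > 0` and shrinks when the
#' factor is negative: for any positive proliferation rate the sign change —
#' the boundary between basal-layer maintenance and loss — sits at
#' `p0 = 1/2`.
#'
#' @return the threshold probability, `0.5`.
#' @export
critical_self_renewal <- function() 0.5

#' Classify genotype phenotypes against wild type
#'
#' Simulates the lineage model for each genotype's effective Ovol levels and
#' calls the direction of change of each marker layer relative to wild type
#' at `t_eval`: the K14+ basal layer is `c0`, the K1+ spinous layer is
#' `c1 + c2`, and the Lor+ granular layer is `c3`. A relative change beyond
#' `theta` is called `up`/`down`, otherwise `same`.
#'
#' @param genotypes a tibble with columns `genotype`, `alpha`, `beta`; must
#'   include a `WT` row (the reference). Defaults to [genotype_presets()].
#' @param reg_base an [ovol_regulation()] carrying the regulation weights
#'   (its `alpha`/`beta` are overridden per genotype).
#' @param t_eval evaluation time (hours).
#' @param theta direction-call threshold (relative change; default 20%).
#' @param init initial populations shared by all genotypes.
#' @return a tibble with columns `genotype`, `layer`, `WT_value`,
#'   `mutant_value`, `relative_change`, `direction`.
#' @examples
#' genotype_phenotype()
#' @export
genotype_phenotype <- function(genotypes = genotype_presets(),
                               reg_base = ovol_regulation(),
                               t_eval = 240, theta = 0.2,
                               init = c(100, 0, 0, 0)) {
  stopifnot(is.data.frame(genotypes),
            all(c("genotype", "alpha", "beta") %in% names(genotypes)))
  if (!"WT" %in% genotypes$genotype)
    abort("`genotypes` must include a WT reference row")
  finals <- purrr::pmap(genotypes, function(genotype, alpha, beta, ...) {
    params <- ovol_modulate(reg_base, alpha = alpha, beta = beta)
    traj <- simulate_lineage(init, params, t_end = t_eval, dt = t_eval)
    last <- traj[nrow(traj), ]
    tibble(genotype = genotype,
           layer = c("basal", "spinous", "granular"),
           value = c(last$c0, last$c1 + last$c2, last$c3))
  }) %>% bind_rows()
  wt <- finals %>% filter(.data$genotype == "WT") %>%
    select(layer = "layer", WT_value = "value")
  finals %>%
    left_join(wt, by = "layer") %>%
    mutate(relative_change = (.data$value - .data$WT_value) / .data$WT_value,
           direction = ifelse(.data$relative_change > theta, "up",
                       ifelse(.data$relative_change < -theta, "down", "same"))) %>%
    select("genotype", "layer", "WT_value", mutant_value = "value",
           "relative_change", "direction")
}
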