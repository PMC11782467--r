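#' Integration and equilibrium settings
#'
#' @param t_max integration horizon, years.
#' @param convergence_tol equilibrium threshold on the relative derivative
#'   norm \eqn{\max_i |dS_i/dt| / (\Sigma_j |S_j| + 10^{-12})}, which must
#'   stay below this value over a sustained 50-year window.
#' @param extinction_threshold a strategy lineage whose male total falls
#'   below this fraction of the whole population is classed extinct; must be
#'   below 0.5.
#' @param rtol,atol relative/absolute tolerances for the adaptive integrator.
#' @param sustain_window length, in years, of the window over which the
#'   convergence criterion must hold.
#' @param lineage_rate_tol relative rate (per year) below which a strategy
#'   lineage counts as stationary. A losing lineage declines exponentially at
#'   a slow but steady rate; the overall derivative norm alone can fall below
#'   \code{convergence_tol} while that decline is still under way, so
#'   equilibrium additionally requires every lineage to be either extinct or
#'   relatively stationary. See the methods vignette.
#' @return A list of class \code{"integration_settings"}.
#' @export
integration_settings <- function(t_max = 2e5,
                                 convergence_tol = 1e-8,
                                 extinction_threshold = 1e-6,
                                 rtol = 1e-9,
                                 atol = 1e-12,
                                 sustain_window = 50,
                                 lineage_rate_tol = 1e-6) {
  stopifnot(t_max > 0, convergence_tol > 0, extinction_threshold > 0,
            extinction_threshold < 0.5, rtol > 0, atol > 0,
            sustain_window > 0, lineage_rate_tol > 0)
  structure(list(t_max = t_max, convergence_tol = convergence_tol,
                 extinction_threshold = extinction_threshold,
                 rtol = rtol, atol = atol, sustain_window = sustain_window,
                 lineage_rate_tol = lineage_rate_tol),
            class = "integration_settings")
}

# parameter vector handed to the compiled RHS, in its fixed order
parm_vector <- function(params, derived = derive_rates(params)) {
  c(params$rho, params$beta, params$chi, params$delta_g, derived$delta_m,
    derived$omega_F, derived$omega_M, params$L,
    params$male_mortality_factor, params$q_star)
}

# one deSolve call over 'times'; returns the raw matrix (t + 17 columns)
integrate_raw <- function(params, init, times, settings, derived) {
  use_compiled <- is.loaded("guardmate_derivs", PACKAGE = "guardmate")
  if (use_compiled) {
    out <- deSolve::ode(y = as.numeric(init), times = times,
                        func = "guardmate_derivs", parms = parm_vector(params, derived),
                        dllname = "guardmate", initfunc = "guardmate_init",
                        method = "lsoda",
                        rtol = settings$rtol, atol = settings$atol)
  } else {
    fn <- function(t, y, p) list(unname(rhs_core(y, params, derived)))
    out <- deSolve::ode(y = as.numeric(init), times = times, func = fn,
                        parms = NULL, method = "lsoda",
                        rtol = settings$rtol, atol = settings$atol)
  }
  out <- unclass(out)
  if (nrow(out) < length(times) || any(!is.finite(out)))
    stop(sprintf("integration failed near t = %g yr",
                 out[nrow(out), 1]), call. = FALSE)
  y <- out[, -1, drop = FALSE]
  # round-off negatives scale with the solver's absolute tolerance; real
  # integration failures overshoot far beyond it
  neg_tol <- max(NEG_CLAMP_TOL, 1e3 * settings$atol)
  if (any(y < -neg_tol)) {
    bad <- which(y < -neg_tol, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "integration produced %s = %g < -%g at t = %g yr (integration failure)",
      compartment_names()[bad[2L]], y[bad[1L], bad[2L]], neg_tol,
      out[bad[1L], 1]), call. = FALSE)
  }
  y[y < 0] <- 0
  out[, -1] <- y
  colnames(out) <- c("t", compartment_names())
  out
}

#' Integrate the model over time
#'
#' Solves the 17-equation system with an adaptive stiff/non-stiff integrator
#' (\code{deSolve::lsoda}) using the package's compiled right-hand side.
#' Components driven marginally negative by round-off (above \code{-1e-10})
#' are clamped to 0; larger negatives abort with the time of failure.
#'
#' @param params a \code{\link{parameter_set}}.
#' @param init initial \code{\link{population_state}}; defaults to the
#'   canonical state (\code{FM = FG = M = G = 0.5}, total 2.0).
#' @param settings an \code{\link{integration_settings}}.
#' @param t_max horizon in years (defaults to \code{settings$t_max}).
#' @param n_out number of equally spaced output times (at least 200 for
#'   plotting resolution).
#' @return A data.frame with column \code{t} and one column per compartment.
#' @examples
#' traj <- integrate_model(parameter_set(), t_max = 200)
#' tail(traj[, 1:5])
#' @export
integrate_model <- function(params, init = default_state(),
                            settings = integration_settings(),
                            t_max = settings$t_max, n_out = 201) {
  validate_parameter_set(params)
  init <- validate_state(init)
  n_out <- max(200L, as.integer(n_out))
  derived <- derive_rates(params)
  times <- seq(0, t_max, length.out = n_out)
  as.data.frame(integrate_raw(params, init, times, settings, derived))
}

#' Classify the dominant strategy of a state
#'
#' The guarding lineage is tracked through its males: unpaired guarders plus
#' all paired males (\code{G + PGg + PG + PMm + PMg + PM}); the
#' multiple-mating lineage through \code{M}. A lineage is extinct when its
#' male total falls below \code{extinction_threshold} times the whole
#' population. Returns \code{"guarding"} or \code{"multiple_mating"} when
#' exactly one lineage survives, \code{"coexistence"} when both do, and
#' \code{"extinct"} when neither.
#'
#' @param state a \code{\link{population_state}}.
#' @param extinction_threshold fraction of total population below which a
#'   lineage counts as extinct.
#' @return One of \code{"multiple_mating"}, \code{"guarding"},
#'   \code{"coexistence"}, \code{"extinct"}.
#' @export
classify_dominance <- function(state, extinction_threshold = 1e-6) {
  s <- validate_state(state)
  total <- sum(s)
  guard <- s[["G"]] + sum(s[PAIR_COMPARTMENTS])
  mult <- s[["M"]]
  cut <- extinction_threshold * total
  g_alive <- total > 0 && guard >= cut
  m_alive <- total > 0 && mult >= cut
  if (g_alive && m_alive) "coexistence"
  else if (g_alive) "guarding"
  else if (m_alive) "multiple_mating"
  else "extinct"
}

#' Adult and operational sex ratios
#'
#' The operational sex ratio (OSR) counts only adults currently able to
#' conceive: unpaired fertile males over free females,
#' \code{(M + G) / (FM + FG)}. The adult sex ratio (ASR) counts all males and
#' females in the fertile ages, paired or not (each pair contributes one male
#' and one female); post-fertile females and retired males are excluded.
#' A zero denominator sets the corresponding \code{*_defined} flag to
#' \code{FALSE} and the ratio to \code{NA}.
#'
#' @param state a \code{\link{population_state}}.
#' @return List with \code{osr}, \code{asr}, \code{osr_defined},
#'   \code{asr_defined}.
#' @examples
#' sex_ratios(population_state(M = 3, G = 1, FM = 0.5, FG = 0.5))$osr # 4
#' @export
sex_ratios <- function(state) {
  s <- validate_state(state)
  osr_num <- s[["M"]] + s[["G"]]
  osr_den <- s[["FM"]] + s[["FG"]]
  asr_num <- osr_num + sum(s[PAIR_COMPARTMENTS])
  asr_den <- s[["FM"]] + s[["FG"]] + s[["FGm"]] + s[["FMm"]] + s[["FGg"]] +
    s[["FMg"]] + sum(s[PAIR_COMPARTMENTS])
  list(osr = if (osr_den > 0) osr_num / osr_den else NA_real_,
       asr = if (asr_den > 0) asr_num / asr_den else NA_real_,
       osr_defined = osr_den > 0,
       asr_defined = asr_den > 0)
}

#' Integrate to equilibrium and classify the outcome
#'
#' Integrates from \code{init} until equilibrium or \code{settings$t_max}.
#' Equilibrium requires the relative derivative norm
#' \eqn{\max_i |dS_i/dt| / (\Sigma_j |S_j| + 10^{-12})} to stay below
#' \code{settings$convergence_tol} over a sustained trailing window
#' (default 50 years) \emph{and} each strategy lineage (males of each
#' strategy) to be either extinct or relatively stationary
#' (\code{lineage_rate_tol}); the second condition prevents declaring
#' equilibrium while a losing lineage is still declining exponentially
#' towards extinction. The returned result carries the final state, the
#' dominance classification, the sex ratios, and the initial total population
#' (the model's reference scale). Integration proceeds in geometrically
#' growing chunks so long approaches to equilibrium stay cheap.
#'
#' @inheritParams integrate_model
#' @return An object of class \code{"equilibrium_result"}: a list with
#'   \code{final_state}, \code{t_final}, \code{converged}, \code{residual},
#'   \code{dominance}, \code{ratios}, \code{initial_total}.
#' @examples
#' \donttest{
#' find_equilibrium(parameter_set(L = 38, beta = 0.25))$dominance # guarding
#' }
#' @export
find_equilibrium <- function(params, init = default_state(),
                             settings = integration_settings()) {
  validate_parameter_set(params)
  init <- validate_state(init)
  derived <- derive_rates(params)
  window <- settings$sustain_window
  t0 <- 0
  y <- as.numeric(init)
  converged <- at_equilibrium(y, params, derived, settings)
  residual <- residual_norm(y, params, derived)
  chunk <- 2 * window
  while (!converged && t0 < settings$t_max) {
    t1 <- min(t0 + chunk, settings$t_max)
    n_out <- max(3L, ceiling((t1 - t0) / window) + 1L)
    times <- seq(t0, t1, length.out = n_out)
    out <- integrate_raw(params, y, times, settings, derived)
    res <- apply(out[, -1, drop = FALSE], 1L, residual_norm,
                 params = params, derived = derived)
    y <- out[nrow(out), -1]
    residual <- res[length(res)]
    t0 <- t1
    # sustained: every check point in the trailing window below tol
    trailing <- which(times >= t1 - window)
    if (all(res[trailing] < settings$convergence_tol) &&
        at_equilibrium(y, params, derived, settings)) {
      converged <- TRUE
    }
    chunk <- min(2 * chunk, 1e4)
  }
  final <- population_state(values = stats::setNames(y, compartment_names()))
  # a population that has decayed below the extinction threshold relative to
  # its own initial scale is extinct as a whole, whatever its composition
  dominance <- if (sum(final) < settings$extinction_threshold * sum(init))
    "extinct"
  else classify_dominance(final, settings$extinction_threshold)
  structure(
    list(final_state = final,
         t_final = t0,
         converged = converged,
         residual = residual,
         dominance = dominance,
         ratios = sex_ratios(final),
         initial_total = sum(init)),
    class = "equilibrium_result")
}

residual_norm <- function(y, params, derived) {
  d <- rhs_core(y, params, derived)
  max(abs(d)) / (sum(abs(y)) + 1e-12)
}

# residual small and every strategy lineage settled (extinct or stationary)
at_equilibrium <- function(y, params, derived, settings) {
  if (residual_norm(y, params, derived) >= settings$convergence_tol)
    return(FALSE)
  d <- rhs_core(y, params, derived)
  nm <- compartment_names()
  total <- sum(pmax(y, 0))
  pair_idx <- match(PAIR_COMPARTMENTS, nm)
  lineages <- rbind(
    c(sum(pmax(y, 0)[c(match("G", nm), pair_idx)]),
      sum(d[c(match("G", nm), pair_idx)])),
    c(max(y[match("M", nm)], 0), d[match("M", nm)]))
  for (r in seq_len(nrow(lineages))) {
    size <- lineages[r, 1]; rate <- lineages[r, 2]
    extinct <- size < settings$extinction_threshold * total
    stationary <- abs(rate) / (size + 1e-12) < settings$lineage_rate_tol
    if (!extinct && !stationary) return(FALSE)
  }
  TRUE
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("<equilibrium_result>\n")
  cat(sprintf("  dominance: %s (converged: %s, t = %g yr, residual = %.3g)\n",
              x$dominance, x$converged, x$t_final, x$residual))
  cat(sprintf("  OSR = %s, ASR = %s\n",
              if (x$ratios$osr_defined) format(x$ratios$osr) else "undefined",
              if (x$ratios$asr_defined) format(x$ratios$asr) else "undefined"))
  cat(sprintf("  total population %g (initial %g)\n",
              sum(x$final_state), x$initial_total))
  invisible(x)
}
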