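#' Model parameters
#'
#' Construct and validate the full parameter set of the mating-strategy
#' model. All rates are per year. Two fertility cases are supported:
#' \code{"case1"} has no end of female fertility (\eqn{\omega_F = 0}, hence no
#' post-fertile stage), while \code{"case2"} ends fertility at age 45, giving
#' \eqn{\omega_F = 2/(90 - L)} for an expected adult lifespan \eqn{L}.
#'
#' Either \code{beta} (rate at which dependants reach independence) or its
#' reciprocal alias \code{interbirth_interval} may be given, and either
#' \code{chi} (pair-bond break-up rate) or its reciprocal alias
#' \code{pair_bond_duration}; supplying both members of a pair with
#' inconsistent values is an error. \code{chi = 0} means unbreakable pair
#' bonds, so the duration alias refuses 0 (use \code{chi = 0} or
#' \code{pair_bond_duration = Inf}).
#'
#' @param rho female productive-mating (conception) rate, per year.
#' @param delta_g death rate of guarded dependants, per year.
#' @param k relative guarding-advantage multiplier (dimensionless);
#'   multiple-mating dependants die at rate \code{k * delta_g}. Values outside
#'   \eqn{[1, 2]} trigger a warning, not an error.
#' @param beta rate at which dependants reach independence, per year; the
#'   interbirth interval is \code{1/beta}.
#' @param q_star success rate of multiple-mating paternity thieves, in
#'   \eqn{[0, 1]}.
#' @param chi pair-bond break-up rate, per year; 0 means bonds never break.
#' @param L expected adult lifespan, years.
#' @param fertility_case \code{"case1"} or \code{"case2"} (default).
#' @param male_mortality_factor multiplier applied to the female death rate to
#'   obtain the male death rate (default 1.09, a 9\% higher minimum).
#' @param male_frailty_scale scale in the male frailty rate
#'   \code{omega_M = 1/(male_frailty_scale * L)} (default 1.6).
#' @param interbirth_interval optional alias for \code{1/beta}, years.
#' @param pair_bond_duration optional alias for \code{1/chi}, years; must be
#'   positive (\code{Inf} means unbreakable bonds).
#'
#' @return An object of class \code{"parameter_set"}: a named list of the
#'   resolved parameter values.
#' @examples
#' human <- parameter_set() # default human life-history estimates
#' chimp <- parameter_set(L = 22, interbirth_interval = 5)
#' @export
parameter_set <- function(rho = 3,
                          delta_g = 0.11,
                          k = 1,
                          beta = 0.25,
                          q_star = 0,
                          chi = 0,
                          L = 38,
                          fertility_case = c("case2", "case1"),
                          male_mortality_factor = 1.09,
                          male_frailty_scale = 1.6,
                          interbirth_interval = NULL,
                          pair_bond_duration = NULL) {
  fertility_case <- match.arg(fertility_case)
  beta <- resolve_rate_alias(beta, interbirth_interval, "beta",
                             "interbirth_interval",
                             beta_given = !missing(beta))
  chi <- resolve_rate_alias(chi, pair_bond_duration, "chi",
                            "pair_bond_duration",
                            beta_given = !missing(chi),
                            allow_zero_rate = TRUE)
  p <- structure(
    list(rho = rho, delta_g = delta_g, k = k, beta = beta,
         q_star = q_star, chi = chi, L = L,
         fertility_case = fertility_case,
         male_mortality_factor = male_mortality_factor,
         male_frailty_scale = male_frailty_scale),
    class = "parameter_set")
  validate_parameter_set(p)
  p
}

resolve_rate_alias <- function(rate, interval, rate_name, interval_name,
                               beta_given, allow_zero_rate = FALSE) {
  if (!is.null(interval)) {
    if (!is.numeric(interval) || length(interval) != 1L || interval <= 0)
      stop(sprintf("'%s' must be a single positive number (Inf allowed)",
                   interval_name), call. = FALSE)
    from_interval <- if (is.infinite(interval)) 0 else 1 / interval
    if (beta_given && !isTRUE(all.equal(rate, from_interval)))
      stop(sprintf("inconsistent '%s' (%g) and '%s' (%g): %s implies %s = %g",
                   rate_name, rate, interval_name, interval,
                   interval_name, rate_name, from_interval), call. = FALSE)
    rate <- from_interval
  }
  rate
}

validate_parameter_set <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("rho", "delta_g", "k", "beta", "q_star", "chi", "L",
              "male_mortality_factor", "male_frailty_scale")) {
    if (!num1(p[[f]]))
      stop(sprintf("parameter '%s' must be a single finite number", f),
           call. = FALSE)
    if (p[[f]] < 0)
      stop(sprintf("parameter '%s' must be non-negative (got %g)", f, p[[f]]),
           call. = FALSE)
  }
  if (p$q_star > 1)
    stop(sprintf("'q_star' is a probability and must lie in [0, 1] (got %g)",
                 p$q_star), call. = FALSE)
  if (p$L <= 0) stop("'L' (expected adult lifespan) must be positive",
                     call. = FALSE)
  if (p$k < 1 || p$k > 2)
    warning(sprintf("'k' = %g lies outside the usual range [1, 2]", p$k),
            call. = FALSE)
  if (identical(p$fertility_case, "case2") && p$L >= 90)
    stop(sprintf(
      "omega_F = 2/(90 - L) is undefined for case2 with L = %g >= 90", p$L),
      call. = FALSE)
  invisible(p)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  d <- derive_rates(x)
  cat(sprintf("  rho = %g /yr, beta = %g /yr (interbirth interval %s yr)\n",
              x$rho, x$beta,
              if (x$beta > 0) format(1 / x$beta) else "Inf"))
  cat(sprintf("  delta_g = %g /yr, k = %g (delta_m = %g /yr)\n",
              x$delta_g, x$k, d$delta_m))
  cat(sprintf("  q_star = %g, chi = %g /yr (pair-bond duration %s yr)\n",
              x$q_star, x$chi,
              if (x$chi > 0) format(1 / x$chi) else "Inf"))
  cat(sprintf("  L = %g yr, %s: omega_F = %g /yr, omega_M = %g /yr\n",
              x$L, x$fertility_case, d$omega_F, d$omega_M))
  cat(sprintf("  male mortality factor = %g, frailty scale = %g\n",
              x$male_mortality_factor, x$male_frailty_scale))
  invisible(x)
}

#' Rates derived from a parameter set
#'
#' Computes the three rates the model derives from its primary parameters:
#' the female fertility-loss rate \eqn{\omega_F} (0 in case 1, otherwise
#' \eqn{2/(90 - L)}), the male frailty rate
#' \eqn{\omega_M = 1/(\mathrm{scale} \cdot L)}, and the death rate of
#' multiple-mating dependants \eqn{\delta_m = k \delta_g}.
#'
#' @param params a \code{\link{parameter_set}}.
#' @return An object of class \code{"derived_rates"} with fields
#'   \code{omega_F}, \code{omega_M} and \code{delta_m}, all per year.
#' @examples
#' derive_rates(parameter_set(L = 38)) # omega_F = 2/52
#' @export
derive_rates <- function(params) {
  validate_parameter_set(params)
  omega_F <- if (identical(params$fertility_case, "case1")) 0
             else 2 / (90 - params$L)
  structure(
    list(omega_F = omega_F,
         omega_M = 1 / (params$male_frailty_scale * params$L),
         delta_m = params$k * params$delta_g),
    class = "derived_rates")
}

#' @export
print.derived_rates <- function(x, ...) {
  cat(sprintf("<derived_rates> omega_F = %g, omega_M = %g, delta_m = %g (all /yr)\n",
              x$omega_F, x$omega_M, x$delta_m))
  invisible(x)
}
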