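#' Compartment names of the population state
#'
#' The model tracks 17 population densities. Superscripts in the field's
#' notation (female trait) come first, subscripts (dependant trait) second:
#' \code{FMm} is a female carrying the multiple-mating trait caring for a
#' dependant with the multiple-mating trait, i.e. \eqn{F^M_m}.
#'
#' \itemize{
#'   \item \code{FM}, \code{FG}: free (conceivable) females with the
#'     multiple-mating / guarding trait.
#'   \item \code{M}: multiple-mating males; \code{G}: unpaired guarding males.
#'   \item \code{FMm}, \code{FGg}, \code{FGm}, \code{FMg}: unpaired caring
#'     females.
#'   \item \code{PGg}, \code{PG}, \code{PMm}, \code{PMg}, \code{PM}: pairs of
#'     a guarding male and a female (superscript = her trait, subscript =
#'     dependant trait; \code{PG}/\code{PM} are dependant-free).
#'   \item \code{X}, \code{Xm}, \code{Xg}: post-fertile females (free /
#'     caring for an m- or g-dependant).
#'   \item \code{Y}: retired males.
#' }
#' @return Character vector of the 17 compartment names, in model order.
#' @export
compartment_names <- function() {
  c("FM", "FG", "M", "G",
    "FMm", "FGg", "FGm", "FMg",
    "PGg", "PG", "PMm", "PMg", "PM",
    "X", "Xm", "Xg", "Y")
}

# carers: the nine compartments whose dependant matures at rate beta;
# they drive the density-dependent death rate
CARER_COMPARTMENTS <- c("FMm", "FGg", "FGm", "FMg",
                        "PGg", "PMm", "PMg", "Xg", "Xm")
PAIR_COMPARTMENTS <- c("PGg", "PG", "PMm", "PMg", "PM")

# tolerance below which a slightly negative density is treated as an
# integration round-off and clamped to zero
NEG_CLAMP_TOL <- 1e-10

#' Construct a population state
#'
#' Builds a named, validated 17-compartment state vector. Unspecified
#' compartments default to 0. Small negative entries (above \code{-1e-10}),
#' as can arise from numerical integration, are clamped to 0; anything more
#' negative is an error naming the offending compartment.
#'
#' @param ... named compartment densities (see
#'   \code{\link{compartment_names}}).
#' @param values optionally, a full named numeric vector of all 17
#'   compartments (in any order) instead of \code{...}.
#' @return Named numeric vector of length 17, class \code{"population_state"}.
#' @examples
#' population_state(FM = 0.5, FG = 0.5, M = 0.5, G = 0.5)
#' @export
population_state <- function(..., values = NULL) {
  nm <- compartment_names()
  s <- stats::setNames(numeric(17L), nm)
  if (!is.null(values)) {
    if (is.null(names(values)) || !setequal(names(values), nm))
      stop("'values' must be a named vector covering all 17 compartments",
           call. = FALSE)
    s[names(values)] <- as.numeric(values)
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("compartment values must be named", call. = FALSE)
    bad <- setdiff(names(dots), nm)
    if (length(bad))
      stop("unknown compartment(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    s[names(dots)] <- vapply(dots, as.numeric, numeric(1))
  }
  validate_state(s)
}

#' @rdname population_state
#' @details \code{default_state()} is the canonical initial condition used
#'   throughout: \code{FM = FG = M = G = 0.5} and all other compartments 0,
#'   for a total population of 2.0. The density-dependent death rate makes
#'   trajectories scale-dependent, so this total is the model's reference
#'   scale.
#' @export
default_state <- function() {
  population_state(FM = 0.5, FG = 0.5, M = 0.5, G = 0.5)
}

validate_state <- function(s) {
  nm <- compartment_names()
  if (length(s) != 17L)
    stop("a population state has exactly 17 compartments", call. = FALSE)
  if (is.null(names(s))) names(s) <- nm else s <- s[nm]
  if (any(!is.finite(s))) {
    bad <- nm[!is.finite(s)][1L]
    stop(sprintf("compartment '%s' is not finite", bad), call. = FALSE)
  }
  if (any(s < -NEG_CLAMP_TOL)) {
    i <- which(s < -NEG_CLAMP_TOL)[1L]
    stop(sprintf("compartment '%s' is negative (%g) beyond tolerance %g",
                 nm[i], s[i], -NEG_CLAMP_TOL), call. = FALSE)
  }
  s[s < 0] <- 0
  structure(s, class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> total =", format(sum(x)), "\n")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Density-dependent adult death rates
#'
#' The female death rate has a constant floor \code{1/L} and a variable
#' density-dependent part that holds the population at its initial scale:
#' \deqn{\mu_F = \max\{1/L,\; (\beta/2)\,\Sigma_{\mathrm{carers}}\}}
#' where the sum runs over the nine carer compartments (\code{FMm}, \code{FGg},
#' \code{FGm}, \code{FMg}, \code{PGg}, \code{PMm}, \code{PMg}, \code{Xg},
#' \code{Xm}). Males die at \code{male_mortality_factor} times the female
#' rate (default 1.09: a 9\% higher minimum death rate).
#'
#' @param state a \code{\link{population_state}}.
#' @param params a \code{\link{parameter_set}}.
#' @return Death rate, per year.
#' @examples
#' female_death_rate(default_state(), parameter_set()) # carers empty: 1/38
#' @export
female_death_rate <- function(state, params) {
  state <- validate_state(state)
  max(1 / params$L,
      (params$beta / 2) * sum(state[CARER_COMPARTMENTS]))
}

#' @rdname female_death_rate
#' @export
male_death_rate <- function(state, params) {
  params$male_mortality_factor * female_death_rate(state, params)
}

#' Paternity-theft probability
#'
#' A multiple-mating male steals the paternity of a dependant cared for by a
#' female paired to (or sired by) a guarding male with probability
#' \deqn{q = \frac{M}{M + G}\, q^\ast,}
#' proportional to the multiple-maters' share of the unpaired male pool. When
#' no unpaired males exist (\code{M + G = 0}) the probability is 0.
#'
#' @inheritParams female_death_rate
#' @return Probability in \code{[0, q_star]}.
#' @export
theft_probability <- function(state, params) {
  state <- validate_state(state)
  tot <- state[["M"]] + state[["G"]]
  if (tot <= 0) return(0)
  (state[["M"]] / tot) * params$q_star
}

#' Right-hand side of the 17-equation model
#'
#' Evaluates the time derivative of every compartment. Mating is driven by
#' free females at rate \code{rho}; a free female mates a multiple-mating or
#' unpaired guarding male in proportion to their shares \code{M/(M+G)} and
#' \code{G/(M+G)} of the unpaired pool (both fractions taken as 0 when
#' \code{M + G = 0}, so all mating fluxes vanish without males). Offspring
#' inherit the paternal strategy; maturing dependants split half female, half
#' male, with sons of guarded dependants diverted to the multiple-mating pool
#' with the theft probability \code{q}. Death rates \eqn{\mu_F}, \eqn{\mu_M}
#' and \code{q} are evaluated from the current state.
#'
#' @inheritParams female_death_rate
#' @param derived optional \code{\link{derive_rates}} result; recomputed from
#'   \code{params} if missing.
#' @return Named numeric vector of 17 signed rates, per year.
#' @examples
#' rhs(default_state(), parameter_set())
#' @export
rhs <- function(state, params, derived = derive_rates(params)) {
  s <- validate_state(state)
  rhs_core(as.numeric(s), params, derived)
}

# core RHS on a bare numeric vector in compartment order; negative entries
# are floored at 0 so rate evaluation never sees round-off negatives
rhs_core <- function(y, params, derived) {
  y <- pmax(y, 0)
  FM <- y[1]; FG <- y[2]; M <- y[3]; G <- y[4]
  FMm <- y[5]; FGg <- y[6]; FGm <- y[7]; FMg <- y[8]
  PGg <- y[9]; PG <- y[10]; PMm <- y[11]; PMg <- y[12]; PM <- y[13]
  X <- y[14]; Xm <- y[15]; Xg <- y[16]; Y <- y[17]

  rho <- params$rho; beta <- params$beta; chi <- params$chi
  dg <- params$delta_g; dm <- derived$delta_m
  wF <- derived$omega_F; wM <- derived$omega_M

  carers <- FMm + FGg + FGm + FMg + PGg + PMm + PMg + Xg + Xm
  muF <- max(1 / params$L, (beta / 2) * carers)
  muM <- params$male_mortality_factor * muF

  tot_males <- M + G
  if (tot_males > 0) {
    fM <- M / tot_males; fG <- G / tot_males
  } else {
    fM <- 0; fG <- 0
  }
  q <- fM * params$q_star

  m_dep <- FMm + FGm + PMm + Xm          # dependants with the m trait
  g_dep <- FGg + FMg + PGg + PMg + Xg    # dependants with the g trait

  d <- numeric(17L)
  # free fertile females
  d[1] <- -rho * FM + 0.5 * beta * m_dep +
    (beta + dm) * FMm + (beta + dg) * FMg +
    (chi + muM) * PM - (wF + muF) * FM
  d[2] <- -rho * FG + 0.5 * beta * g_dep +
    (beta + dg) * FGg + (beta + dm) * FGm +
    (chi + muM) * PG - (wF + muF) * FG
  # unpaired males: maturing sons; guarded sons stolen with probability q
  d[3] <- 0.5 * beta * m_dep + 0.5 * q * beta * g_dep - (wM + muM) * M
  d[4] <- -rho * fG * (FM + FG) + 0.5 * (1 - q) * beta * g_dep +
    (chi + wF + muF) * (PM + PG + PMg + PGg + PMm) - (wM + muM) * G
  # unpaired caring females
  d[5] <- rho * fM * FM + (chi + muM) * PMm - (beta + dm + wF + muF) * FMm
  d[6] <- 0.5 * rho * fM * FG + (chi + muM) * PGg -
    (beta + dg + wF + muF) * FGg
  d[7] <- 0.5 * rho * fM * FG - (beta + dm + wF + muF) * FGm
  d[8] <- (chi + muM) * PMg - (beta + dg + wF + muF) * FMg
  # pairs
  d[9] <- rho * fG * FG + rho * PG -
    (beta + dg + chi + wF + muM + muF) * PGg
  d[10] <- -rho * PG + (beta + dg) * PGg - (chi + wF + muM + muF) * PG
  d[11] <- 0.5 * rho * fG * FM + 0.5 * rho * PM -
    (beta + dm + chi + wF + muM + muF) * PMm
  d[12] <- 0.5 * rho * fG * FM + 0.5 * rho * PM -
    (beta + dg + chi + wF + muM + muF) * PMg
  d[13] <- -rho * PM + (beta + dm) * PMm + (beta + dg) * PMg -
    (chi + wF + muM + muF) * PM
  # post-fertile females
  d[14] <- wF * (FM + FG + PM + PG) + (beta + dm) * Xm + (beta + dg) * Xg -
    muF * X
  d[15] <- wF * (FMm + FGm + PMm) - (beta + dm + muF) * Xm
  d[16] <- wF * (FMg + FGg + PGg + PMg) - (beta + dg + muF) * Xg
  # retired males
  d[17] <- wM * (M + G) - muM * Y

  stats::setNames(d, compartment_names())
}
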