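# Independent oracle: a plain transliteration of the printed rate equations
# evaluated compartment by compartment on a named list, plus a classic
# fixed-step 4th-order Runge-Kutta integrator. Deliberately kept separate
# from the package's rhs()/integrate_model() code paths.

oracle_rhs <- function(y, pars) {
  v <- as.list(stats::setNames(y, compartment_names()))
  rho <- pars$rho; beta <- pars$beta; chi <- pars$chi
  delta_g <- pars$delta_g
  delta_m <- pars$k * pars$delta_g
  omega_F <- if (pars$fertility_case == "case1") 0 else 2 / (90 - pars$L)
  omega_M <- 1 / (pars$male_frailty_scale * pars$L)

  with(v, {
    muF <- max(1 / pars$L,
               (beta / 2) * (FMm + FGg + FGm + FMg + PGg + PMm + PMg + Xg + Xm))
    muM <- pars$male_mortality_factor * muF
    MG <- M + G
    pM <- if (MG > 0) M / MG else 0
    pG <- if (MG > 0) G / MG else 0
    q <- pM * pars$q_star

    c(FM = -rho * FM + 0.5 * beta * (FMm + FGm + PMm + Xm) +
        (beta + delta_m) * FMm + (beta + delta_g) * FMg +
        (chi + muM) * PM - (omega_F + muF) * FM,
      FG = -rho * FG + 0.5 * beta * (FGg + FMg + PGg + PMg + Xg) +
        (beta + delta_g) * FGg + (beta + delta_m) * FGm +
        (chi + muM) * PG - (omega_F + muF) * FG,
      M = 0.5 * beta * (FMm + FGm + PMm + Xm) +
        0.5 * q * beta * (FGg + FMg + PGg + PMg + Xg) -
        (omega_M + muM) * M,
      G = -rho * pG * (FM + FG) +
        0.5 * (1 - q) * beta * (FGg + FMg + PGg + PMg + Xg) +
        (chi + omega_F + muF) * (PM + PG + PMg + PGg + PMm) -
        (omega_M + muM) * G,
      FMm = rho * pM * FM + (chi + muM) * PMm -
        (beta + delta_m + omega_F + muF) * FMm,
      FGg = 0.5 * rho * pM * FG + (chi + muM) * PGg -
        (beta + delta_g + omega_F + muF) * FGg,
      FGm = 0.5 * rho * pM * FG - (beta + delta_m + omega_F + muF) * FGm,
      FMg = (chi + muM) * PMg - (beta + delta_g + omega_F + muF) * FMg,
      PGg = rho * pG * FG + rho * PG -
        (beta + delta_g + chi + omega_F + muM + muF) * PGg,
      PG = -rho * PG + (beta + delta_g) * PGg -
        (chi + omega_F + muM + muF) * PG,
      PMm = 0.5 * rho * pG * FM + 0.5 * rho * PM -
        (beta + delta_m + chi + omega_F + muM + muF) * PMm,
      PMg = 0.5 * rho * pG * FM + 0.5 * rho * PM -
        (beta + delta_g + chi + omega_F + muM + muF) * PMg,
      PM = -rho * PM + (beta + delta_m) * PMm + (beta + delta_g) * PMg -
        (chi + omega_F + muM + muF) * PM,
      X = omega_F * (FM + FG + PM + PG) + (beta + delta_m) * Xm +
        (beta + delta_g) * Xg - muF * X,
      Xm = omega_F * (FMm + FGm + PMm) - (beta + delta_m) * Xm - muF * Xm,
      Xg = omega_F * (FMg + FGg + PGg + PMg) - (beta + delta_g) * Xg -
        muF * Xg,
      Y = omega_M * (M + G) - muM * Y)
  })
}

# classic RK4 with a fixed step; returns the state at t_end
oracle_rk4 <- function(y0, pars, t_end, dt = 1e-3) {
  y <- as.numeric(y0)
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- oracle_rhs(y, pars)
    k2 <- oracle_rhs(y + dt / 2 * k1, pars)
    k3 <- oracle_rhs(y + dt / 2 * k2, pars)
    k4 <- oracle_rhs(y + dt * k3, pars)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::setNames(y, compartment_names())
}

# explicit birth/death tally for the adult bookkeeping identity:
# d(adults)/dt must equal beta * carers - deaths
oracle_adult_balance <- function(y, pars) {
  v <- as.list(stats::setNames(y, compartment_names()))
  with(v, {
    carers <- FMm + FGg + FGm + FMg + PGg + PMm + PMg + Xg + Xm
    muF <- max(1 / pars$L, (pars$beta / 2) * carers)
    muM <- pars$male_mortality_factor * muF
    pairs <- PGg + PG + PMm + PMg + PM
    females <- FM + FG + FMm + FGg + FGm + FMg + X + Xm + Xg
    males <- M + G + Y
    births <- pars$beta * carers
    deaths <- muF * (females + pairs) + muM * (males + pairs)
    births - deaths
  })
}

random_state <- function() {
  population_state(values = stats::setNames(runif(17, 0, 2),
                                            compartment_names()))
}

# parameter draw across the tabulated ranges (lifespans between the chimp
# and human estimates and beyond, interbirth intervals 1-10 yr, k in [1,2])
random_params <- function() {
  parameter_set(L = runif(1, 20, 45),
                interbirth_interval = runif(1, 1, 10),
                k = runif(1, 1, 2),
                q_star = runif(1, 0, 0.3),
                chi = runif(1, 0, 0.5))
}
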