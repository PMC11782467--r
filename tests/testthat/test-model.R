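test_that("population states validate, clamp round-off and reject bad input", {
  s <- population_state(FM = 0.5, FG = 0.5, M = 0.5, G = 0.5)
  expect_length(s, 17)
  expect_equal(sum(s), 2)
  expect_error(population_state(FZ = 1), "unknown compartment")
  expect_error(population_state(FM = -1), "negative")
  # round-off negatives clamp to zero
  v <- stats::setNames(rep(0.1, 17), compartment_names())
  v["PG"] <- -5e-11
  expect_equal(population_state(values = v)[["PG"]], 0)
  v["PG"] <- -1e-9
  expect_error(population_state(values = v), "PG")
})

test_that("female death rate is the max of the floor and the carer term", {
  p <- parameter_set(L = 38, beta = 0.25)
  expect_equal(female_death_rate(default_state(), p), 1 / 38)
  # carer sum 1.0 spread over several carer compartments: variable term wins
  s <- population_state(FMm = 0.3, PGg = 0.4, Xg = 0.3)
  expect_equal(female_death_rate(s, p), 0.125)
  # small carer sum at a short lifespan: the floor wins
  p2 <- parameter_set(L = 22, beta = 0.2)
  s2 <- population_state(FGg = 0.1)
  expect_equal(female_death_rate(s2, p2), 1 / 22)
  # non-carer compartments (X, Y, PG, PM, free adults) do not enter
  s3 <- population_state(X = 5, Y = 5, PG = 5, PM = 5, FM = 5)
  expect_equal(female_death_rate(s3, p), 1 / 38)
})

test_that("male death rate scales the female rate by the mortality factor", {
  p <- parameter_set(L = 38)
  expect_equal(male_death_rate(default_state(), p), 1.09 / 38)
  s <- population_state(FMm = 1.0)
  expect_equal(male_death_rate(s, p), 1.09 * 0.125)
  p1 <- parameter_set(male_mortality_factor = 1)
  expect_equal(male_death_rate(s, p1), female_death_rate(s, p1))
})

test_that("theft probability is the multiple-mater share times q_star", {
  p <- parameter_set(q_star = 0.2)
  expect_equal(theft_probability(population_state(M = 0.5, G = 0.5), p), 0.1)
  expect_equal(theft_probability(population_state(M = 1, G = 0), p), 0.2)
  expect_equal(theft_probability(population_state(M = 0, G = 1), p), 0)
  expect_equal(theft_probability(population_state(), p), 0)
  # bounded by q_star for random states
  set.seed(11)
  for (i in 1:25) {
    q <- theft_probability(random_state(), p)
    expect_gte(q, 0)
    expect_lte(q, p$q_star)
  }
})

test_that("the rhs vanishes on the empty state and for isolated decay", {
  p <- parameter_set(L = 38)
  expect_equal(unname(rhs(population_state(), p)), rep(0, 17))
  # only retired males: pure exponential decay at the male floor rate
  d <- rhs(population_state(Y = 1), p)
  expect_equal(d[["Y"]], -1.09 / 38)
  expect_equal(unname(d[setdiff(compartment_names(), "Y")]), rep(0, 16))
})

test_that("rhs at the canonical initial state matches term-by-term arithmetic", {
  p <- parameter_set(L = 38, beta = 0.25)
  d <- rhs(default_state(), p)
  # frozen expectations from direct evaluation of each printed equation at
  # FM = FG = M = G = 0.5: muF = 1/38, muM = 1.09/38, omega_F = 2/52,
  # omega_M = 1/60.8, all carer/pair/post-fertile compartments empty
  expect_equal(d[["FM"]], -1.5 - (2 / 52 + 1 / 38) * 0.5)
  expect_equal(d[["FG"]], -1.5 - (2 / 52 + 1 / 38) * 0.5)
  expect_equal(d[["M"]], -(1 / 60.8 + 1.09 / 38) * 0.5)
  expect_equal(d[["G"]], -1.5 - (1 / 60.8 + 1.09 / 38) * 0.5)
  expect_equal(d[["FMm"]], 0.75)   # rho * (M share 1/2) * FM
  expect_equal(d[["FGg"]], 0.375)
  expect_equal(d[["FGm"]], 0.375)
  expect_equal(d[["FMg"]], 0)
  expect_equal(d[["PGg"]], 0.75)   # rho * (G share 1/2) * FG
  expect_equal(d[["PMm"]], 0.375)
  expect_equal(d[["PMg"]], 0.375)
  expect_equal(d[["PG"]], 0)
  expect_equal(d[["PM"]], 0)
  expect_equal(d[["X"]], 2 / 52)   # omega_F * (FM + FG)
  expect_equal(d[["Xm"]], 0)
  expect_equal(d[["Xg"]], 0)
  expect_equal(d[["Y"]], 1 / 60.8) # omega_M * (M + G)
})

test_that("rhs agrees with the independent equation-by-equation oracle", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_params()
    s <- random_state()
    expect_equal(unname(rhs(s, p)), unname(oracle_rhs(as.numeric(s), p)),
                 tolerance = 1e-12)
  }
})

test_that("adult bookkeeping balances births against deaths", {
  set.seed(7)
  p <- parameter_set(q_star = 0.15, chi = 0.1)
  for (i in 1:50) {
    s <- random_state()
    d <- rhs(s, p)
    pair_idx <- c("PGg", "PG", "PMm", "PMg", "PM")
    dN <- sum(d) + sum(d[pair_idx]) # pairs hold two adults
    expect_equal(dN, oracle_adult_balance(as.numeric(s), p),
                 tolerance = 1e-10)
  }
})

test_that("without theft no guarded son enters the multiple-mating pool", {
  p <- parameter_set(q_star = 0)
  # a state with only guarding-trait dependants in care and males present
  s <- population_state(M = 0.4, G = 0.6, FGg = 0.5, FMg = 0.3, PGg = 0.2,
                        PMg = 0.1, Xg = 0.2)
  d <- rhs(s, p)
  # dM/dt must show pure decay: no influx from the guarded dependants
  expect_equal(d[["M"]],
               -(derive_rates(p)$omega_M + male_death_rate(s, p)) * 0.4)
})
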