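test_that("axis specs validate names, monotonicity and aliases", {
  expect_silent(axis_spec("q_star", c(0, 0.1, 0.2)))
  expect_silent(axis_spec("interbirth_interval", 10:1))
  expect_error(axis_spec("banana", 1:3), "axis name")
  expect_error(axis_spec("L", c(1, 3, 2)), "monotone")
  expect_error(axis_spec("L", c(1, NA)), "finite")
})

test_that("a 1x1 grid reduces to a single equilibrium run", {
  p <- parameter_set(L = 38)
  m <- run_grid(p, axis_spec("L", 38), axis_spec("interbirth_interval", 4))
  eq <- find_equilibrium(parameter_set(L = 38, beta = 0.25))
  expect_identical(dim(m$dominance), c(1L, 1L))
  expect_identical(m$dominance[1, 1], eq$dominance)
  expect_equal(m$osr[1, 1], eq$ratios$osr)
  expect_equal(m$asr[1, 1], eq$ratios$asr)
})

test_that("the species-matched corner cells reproduce the two outcomes", {
  m <- run_grid(parameter_set(),
                axis_spec("L", c(22, 38)),
                axis_spec("interbirth_interval", c(4, 5)))
  expect_identical(m$dominance[1, 2], "multiple_mating") # L = 22, ib = 5
  expect_identical(m$dominance[2, 1], "guarding")        # L = 38, ib = 4
  expect_true(all(m$converged))
})

# a hand-built map for boundary-extraction logic, no simulation involved
fake_map <- function(dom, osr = NULL, asr = NULL, conv = NULL,
                     v1 = seq_len(nrow(dom)), v2 = seq_len(ncol(dom))) {
  if (is.null(osr)) osr <- matrix(1, nrow(dom), ncol(dom))
  if (is.null(asr)) asr <- osr
  if (is.null(conv)) conv <- matrix(TRUE, nrow(dom), ncol(dom))
  structure(list(axis1 = axis_spec("q_star", v1),
                 axis2 = axis_spec("pair_bond_duration", v2),
                 dominance = dom, osr = osr, asr = asr, converged = conv,
                 base = parameter_set(), settings = integration_settings(),
                 init = default_state()),
            class = "region_map")
}

test_that("boundary extraction averages adjacent differing cells", {
  m <- fake_map(matrix(c("multiple_mating", "guarding"), 2, 1),
                osr = matrix(c(8, 10), 2, 1))
  b <- extract_boundary(m)
  expect_equal(nrow(b), 1)
  expect_equal(b$osr, 9)
  expect_equal(b$a1_mid, 1.5)

  # uniform map: empty set, not an error
  b2 <- extract_boundary(fake_map(matrix("guarding", 3, 3)))
  expect_equal(nrow(b2), 0)

  # coexistence, extinct and unconverged cells never form records
  dom <- matrix(c("multiple_mating", "coexistence", "guarding",
                  "extinct", "multiple_mating", "guarding"), 3, 2)
  conv <- matrix(TRUE, 3, 2); conv[3, 1] <- FALSE
  b3 <- extract_boundary(fake_map(dom, conv = conv))
  # only the (2,2)-(3,2) vertical pair remains... (3,2) is guarding,
  # (2,2) multiple_mating, both converged
  expect_equal(nrow(b3), 1)
  expect_setequal(c(b3$label_lo, b3$label_hi),
                  c("multiple_mating", "guarding"))
})

test_that("guarding fraction counts converged single-strategy cells", {
  expect_equal(guarding_fraction(fake_map(matrix("guarding", 2, 2))), 1)
  expect_equal(guarding_fraction(fake_map(matrix("multiple_mating", 2, 2))), 0)
  dom <- matrix(c("guarding", "multiple_mating", "coexistence", "extinct"),
                2, 2)
  expect_equal(guarding_fraction(fake_map(dom)), 0.5)
  conv <- matrix(FALSE, 2, 2)
  expect_true(is.na(guarding_fraction(fake_map(dom, conv = conv))))
})

test_that("an osr curve with one point equals the single equilibrium", {
  cv <- osr_curve(parameter_set(), axis_spec("interbirth_interval", 4))
  eq <- find_equilibrium(parameter_set(beta = 0.25))
  expect_equal(nrow(cv), 1)
  expect_equal(cv$osr, eq$ratios$osr)
  expect_equal(cv$asr, eq$ratios$asr)
  expect_identical(cv$dominance, eq$dominance)
})

test_that("the boundary OSR rises with theft and falls as bonds lengthen", {
  ax_ib <- axis_spec("interbirth_interval", seq(1, 10, length.out = 9))
  ax_L <- axis_spec("L", seq(20, 45, length.out = 9))
  bosr <- function(p) mean(extract_boundary(run_grid(p, ax_ib, ax_L))$osr)
  # more theft: the sex ratio must be more male-biased before guarding pays
  expect_gte(bosr(parameter_set(q_star = 0.20)),
             bosr(parameter_set(q_star = 0.01)))
  # longer bonds: guarding pays at a lower male bias
  by_duration <- vapply(c(1, 5, 25),
                        function(d) bosr(parameter_set(pair_bond_duration = d)),
                        numeric(1))
  expect_true(all(diff(by_duration) <= 0))
})

test_that("boundary refinement tightens the bracket around the shift", {
  base <- parameter_set(L = 30, beta = 0.2)
  m <- run_grid(base,
                axis_spec("q_star", c(0, 0.05)),
                axis_spec("pair_bond_duration", c(15, 25)))
  b0 <- extract_boundary(m)
  expect_gt(nrow(b0), 0)
  b1 <- extract_boundary(m, refine = 3)
  # refined endpoints lie strictly inside the original cell pair
  w0 <- abs(b0$a1_hi - b0$a1_lo) + abs(b0$a2_hi - b0$a2_lo)
  w1 <- abs(b1$a1_hi - b1$a1_lo) + abs(b1$a2_hi - b1$a2_lo)
  expect_true(all(w1 <= w0 / 2))
})
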