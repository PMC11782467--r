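#' Sweep axis specification
#'
#' Declares a grid axis for a two-dimensional parameter sweep. The name may
#' be any \code{\link{parameter_set}} field or one of the reciprocal aliases
#' \code{interbirth_interval} (\code{= 1/beta}) or \code{pair_bond_duration}
#' (\code{= 1/chi}); aliases are resolved before simulation. Values must be
#' strictly monotone.
#'
#' @param name parameter name or alias.
#' @param values strictly monotone numeric vector of grid values.
#' @return An object of class \code{"axis_spec"}.
#' @examples
#' axis_spec("interbirth_interval", 1:10)
#' @export
axis_spec <- function(name, values) {
  valid <- c("rho", "delta_g", "k", "beta", "q_star", "chi", "L",
             "male_mortality_factor", "male_frailty_scale",
             "interbirth_interval", "pair_bond_duration")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("axis name must be one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("axis values must be finite numbers", call. = FALSE)
  if (length(values) > 1L) {
    dv <- diff(values)
    if (!(all(dv > 0) || all(dv < 0)))
      stop("axis values must be strictly monotone", call. = FALSE)
  }
  structure(list(name = name, values = values), class = "axis_spec")
}

# apply one axis value to a parameter set, resolving aliases
set_axis_value <- function(params, name, value) {
  if (name == "interbirth_interval") {
    params$beta <- 1 / value
  } else if (name == "pair_bond_duration") {
    if (value <= 0)
      stop("pair_bond_duration must be positive (Inf for unbreakable bonds)",
           call. = FALSE)
    params$chi <- if (is.infinite(value)) 0 else 1 / value
  } else {
    params[[name]] <- value
  }
  params
}

#' Run a two-dimensional parameter sweep
#'
#' Runs \code{\link{find_equilibrium}} on every cell of the grid defined by
#' two axes, with identical initial conditions across cells, and collects the
#' dominance classification and equilibrium sex ratios into matrices (axis 1
#' indexes rows, axis 2 columns). Cells where integration fails are recorded
#' as unconverged (\code{dominance = NA}) without aborting the sweep.
#'
#' @param base a \code{\link{parameter_set}} providing all non-swept values.
#' @param axis1,axis2 \code{\link{axis_spec}} objects.
#' @param settings an \code{\link{integration_settings}}.
#' @param init initial state used for every cell.
#' @return An object of class \code{"region_map"}: axes, \code{dominance}
#'   (character matrix), \code{osr}, \code{asr} (numeric matrices),
#'   \code{converged} (logical matrix), plus the base parameters, settings
#'   and initial state.
#' @examples
#' \donttest{
#' rm <- run_grid(parameter_set(),
#'                axis_spec("L", c(22, 38)),
#'                axis_spec("interbirth_interval", c(4, 5)))
#' rm$dominance
#' }
#' @export
run_grid <- function(base, axis1, axis2,
                     settings = integration_settings(),
                     init = default_state()) {
  validate_parameter_set(base)
  stopifnot(inherits(axis1, "axis_spec"), inherits(axis2, "axis_spec"))
  n1 <- length(axis1$values); n2 <- length(axis2$values)
  dom <- matrix(NA_character_, n1, n2)
  osr <- matrix(NA_real_, n1, n2)
  asr <- matrix(NA_real_, n1, n2)
  conv <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) {
    p_i <- set_axis_value(base, axis1$name, axis1$values[i])
    for (j in seq_len(n2)) {
      p <- set_axis_value(p_i, axis2$name, axis2$values[j])
      eq <- tryCatch(find_equilibrium(p, init = init, settings = settings),
                     error = function(e) NULL)
      if (is.null(eq)) next
      dom[i, j] <- eq$dominance
      osr[i, j] <- eq$ratios$osr
      asr[i, j] <- eq$ratios$asr
      conv[i, j] <- eq$converged
    }
  }
  structure(list(axis1 = axis1, axis2 = axis2,
                 dominance = dom, osr = osr, asr = asr, converged = conv,
                 base = base, settings = settings, init = init),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d x %d over %s x %s\n",
              length(x$axis1$values), length(x$axis2$values),
              x$axis1$name, x$axis2$name))
  print(table(x$dominance, useNA = "ifany"))
  invisible(x)
}

#' Extract the dominance boundary of a region map
#'
#' Scans all horizontally and vertically adjacent cell pairs and records each
#' pair whose cells carry differing single-strategy labels (guarding vs
#' multiple mating); cells labelled coexistence or extinct, and unconverged
#' cells, never form boundary records. The boundary OSR and ASR are the
#' arithmetic means of the two adjacent cells' values, matching the
#' resolution at which grid sweeps locate the strategy shift. An optional
#' refinement pass bisects each boundary segment in parameter space,
#' re-classifying midpoints to tighten the bracket before averaging.
#'
#' @param map a \code{\link{region_map}}.
#' @param refine number of bisection iterations along each boundary segment
#'   (0, the default, averages the original adjacent cells).
#' @return An object of class \code{"boundary_set"}: a data.frame with the
#'   two cell coordinates (\code{a1_lo}, \code{a2_lo}, \code{a1_hi},
#'   \code{a2_hi} in axis units), midpoint coordinates, the two labels, and
#'   the mean \code{osr} and \code{asr}. Zero rows if the map is uniform.
#' @export
extract_boundary <- function(map, refine = 0) {
  stopifnot(inherits(map, "region_map"))
  n1 <- length(map$axis1$values); n2 <- length(map$axis2$values)
  if (n1 < 2L && n2 < 2L)
    stop("boundary extraction needs at least 2 cells along one axis",
         call. = FALSE)
  single <- c("guarding", "multiple_mating")
  recs <- list()
  add_pair <- function(i1, j1, i2, j2) {
    d1 <- map$dominance[i1, j1]; d2 <- map$dominance[i2, j2]
    ok <- !is.na(d1) && !is.na(d2) && d1 %in% single && d2 %in% single &&
      d1 != d2 && map$converged[i1, j1] && map$converged[i2, j2]
    if (!ok) return(NULL)
    cell <- function(i, j) c(map$axis1$values[i], map$axis2$values[j])
    lo <- cell(i1, j1); hi <- cell(i2, j2)
    v_osr <- c(map$osr[i1, j1], map$osr[i2, j2])
    v_asr <- c(map$asr[i1, j1], map$asr[i2, j2])
    if (refine > 0) {
      ref <- refine_boundary_segment(map, lo, hi, d1, d2, refine)
      v_osr <- ref$osr; v_asr <- ref$asr
      lo <- ref$lo; hi <- ref$hi
    }
    data.frame(a1_lo = lo[1], a2_lo = lo[2], a1_hi = hi[1], a2_hi = hi[2],
               a1_mid = (lo[1] + hi[1]) / 2, a2_mid = (lo[2] + hi[2]) / 2,
               label_lo = d1, label_hi = d2,
               osr = mean(v_osr), asr = mean(v_asr))
  }
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (i < n1) recs[[length(recs) + 1L]] <- add_pair(i, j, i + 1L, j)
    if (j < n2) recs[[length(recs) + 1L]] <- add_pair(i, j, i, j + 1L)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(a1_lo = numeric(), a2_lo = numeric(), a1_hi = numeric(),
               a2_hi = numeric(), a1_mid = numeric(), a2_mid = numeric(),
               label_lo = character(), label_hi = character(),
               osr = numeric(), asr = numeric())
  class(out) <- c("boundary_set", "data.frame")
  out
}

# bisect the segment between two differently-labelled grid cells; keeps the
# bracket around the strategy shift and returns the final endpoints' ratios
refine_boundary_segment <- function(map, lo, hi, d_lo, d_hi, iters) {
  eq_at <- function(pt) {
    p <- set_axis_value(map$base, map$axis1$name, pt[1])
    p <- set_axis_value(p, map$axis2$name, pt[2])
    find_equilibrium(p, init = map$init, settings = map$settings)
  }
  r_lo <- NULL; r_hi <- NULL
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    eq <- tryCatch(eq_at(mid), error = function(e) NULL)
    if (is.null(eq) || !(eq$dominance %in% c(d_lo, d_hi))) break
    if (eq$dominance == d_lo) { lo <- mid; r_lo <- eq } else { hi <- mid; r_hi <- eq }
  }
  if (is.null(r_lo)) r_lo <- eq_at(lo)
  if (is.null(r_hi)) r_hi <- eq_at(hi)
  list(lo = lo, hi = hi,
       osr = c(r_lo$ratios$osr, r_hi$ratios$osr),
       asr = c(r_lo$ratios$asr, r_hi$ratios$asr))
}

#' Fraction of grid cells won by guarding
#'
#' Counts cells classified \code{"guarding"} over all converged cells with a
#' single-strategy label. Used to quantify how a dominance region grows or
#' shrinks as one parameter changes.
#'
#' @param map a \code{\link{region_map}}.
#' @return Fraction in \code{[0, 1]}, or \code{NA} if no converged
#'   single-strategy cells exist.
#' @export
guarding_fraction <- function(map) {
  stopifnot(inherits(map, "region_map"))
  ok <- map$converged & !is.na(map$dominance) &
    map$dominance %in% c("guarding", "multiple_mating")
  if (!any(ok)) return(NA_real_)
  sum(map$dominance[ok] == "guarding") / sum(ok)
}

#' Equilibrium sex ratios along one parameter axis
#'
#' Computes the equilibrium OSR and ASR at each value of a varying parameter,
#' optionally overriding one further parameter, holding everything else at
#' \code{base}. Used to trace how sex ratios respond to the interbirth
#' interval and to longevity.
#'
#' @param base a \code{\link{parameter_set}}.
#' @param varying an \code{\link{axis_spec}}.
#' @param fixed_name,fixed_value optional single parameter override (alias
#'   names allowed).
#' @param settings an \code{\link{integration_settings}}.
#' @param init initial state for every point.
#' @return A data.frame with columns \code{value}, \code{osr}, \code{asr},
#'   \code{dominance}, \code{converged}.
#' @export
osr_curve <- function(base, varying, fixed_name = NULL, fixed_value = NULL,
                      settings = integration_settings(),
                      init = default_state()) {
  validate_parameter_set(base)
  stopifnot(inherits(varying, "axis_spec"))
  if (!is.null(fixed_name)) base <- set_axis_value(base, fixed_name, fixed_value)
  rows <- lapply(varying$values, function(v) {
    p <- set_axis_value(base, varying$name, v)
    eq <- tryCatch(find_equilibrium(p, init = init, settings = settings),
                   error = function(e) NULL)
    if (is.null(eq))
      return(data.frame(value = v, osr = NA_real_, asr = NA_real_,
                        dominance = NA_character_, converged = FALSE))
    data.frame(value = v, osr = eq$ratios$osr, asr = eq$ratios$asr,
               dominance = eq$dominance, converged = eq$converged)
  })
  do.call(rbind, rows)
}
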