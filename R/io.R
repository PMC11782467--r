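# Config loading, validation and result writers. CSV dialect throughout:
# comma-separated, '.' decimal, UTF-8, header row, numbers at 12 significant
# digits. The model is deterministic, so identical configs give
# byte-identical outputs.

CSV_DIGITS <- 12L

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) format(v, digits = CSV_DIGITS),
                              character(1)))
}

write_csv_12 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration with up to five blocks:
#' \code{parameters} (fields of \code{\link{parameter_set}}, with the
#' \code{interbirth_interval} and \code{pair_bond_duration} aliases),
#' \code{initial_state} (compartment names; defaults to the canonical
#' initial condition), \code{settings} (fields of
#' \code{\link{integration_settings}}), \code{sweep} (\code{axis1}/
#' \code{axis2}, each with \code{name} and \code{values} or
#' \code{from}/\code{to}/\code{n}), and \code{curves} (\code{varying} axis
#' plus optional \code{fixed_name}/\code{fixed_value}). Optional scalar keys:
#' \code{output_dir}, \code{plots}. Unknown keys anywhere are rejected;
#' inconsistent aliases are an error. Applied defaults are echoed via
#' \code{message()}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A list of class \code{"run_config"} with elements \code{params},
#'   \code{init}, \code{settings}, \code{sweep}, \code{curves},
#'   \code{output_dir}, \code{plots}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("parameters", "initial_state", "settings", "sweep", "curves",
             "output_dir", "plots")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  par_block <- raw$parameters %||% list()
  par_ok <- c("rho", "delta_g", "k", "beta", "q_star", "chi", "L",
              "fertility_case", "male_mortality_factor", "male_frailty_scale",
              "interbirth_interval", "pair_bond_duration")
  bad <- setdiff(names(par_block), par_ok)
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  given <- names(par_block)
  if ("interbirth_interval" %in% given) given <- c(given, "beta")
  if ("pair_bond_duration" %in% given) given <- c(given, "chi")
  defaulted <- setdiff(setdiff(par_ok, c("interbirth_interval",
                                         "pair_bond_duration")),
                       given)
  params <- do.call(parameter_set, par_block)
  if (length(defaulted))
    message("config: parameter defaults applied for ",
            paste(defaulted, collapse = ", "))

  init <- if (is.null(raw$initial_state)) {
    message("config: canonical initial state applied (FM=FG=M=G=0.5)")
    default_state()
  } else {
    do.call(population_state, as.list(raw$initial_state))
  }

  set_block <- raw$settings %||% list()
  set_ok <- names(formals(integration_settings))
  bad <- setdiff(names(set_block), set_ok)
  if (length(bad))
    stop("unknown settings key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  settings <- do.call(integration_settings, set_block)

  sweep <- if (!is.null(raw$sweep)) parse_sweep_block(raw$sweep) else NULL
  curves <- if (!is.null(raw$curves)) parse_curves_block(raw$curves) else NULL

  structure(list(params = params, init = init, settings = settings,
                 sweep = sweep, curves = curves,
                 output_dir = raw$output_dir %||% ".",
                 plots = isTRUE(raw$plots)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_axis_block <- function(b, what) {
  bad <- setdiff(names(b), c("name", "values", "from", "to", "n"))
  if (length(bad))
    stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(b$name)) stop(what, " needs a 'name'", call. = FALSE)
  vals <- if (!is.null(b$values)) unlist(b$values)
  else if (!is.null(b$from) && !is.null(b$to) && !is.null(b$n))
    seq(b$from, b$to, length.out = b$n)
  else stop(what, " needs 'values' or 'from'/'to'/'n'", call. = FALSE)
  axis_spec(b$name, vals)
}

parse_sweep_block <- function(b) {
  bad <- setdiff(names(b), c("axis1", "axis2"))
  if (length(bad))
    stop("unknown sweep key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(b$axis1) || is.null(b$axis2))
    stop("sweep needs 'axis1' and 'axis2'", call. = FALSE)
  list(axis1 = parse_axis_block(b$axis1, "sweep axis1"),
       axis2 = parse_axis_block(b$axis2, "sweep axis2"))
}

parse_curves_block <- function(b) {
  bad <- setdiff(names(b), c("varying", "fixed_name", "fixed_value"))
  if (length(bad))
    stop("unknown curves key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(b$varying)) stop("curves needs a 'varying' axis", call. = FALSE)
  list(varying = parse_axis_block(b$varying, "curves varying axis"),
       fixed_name = b$fixed_name, fixed_value = b$fixed_value)
}

#' Write a trajectory to CSV
#'
#' Tidy CSV with a \code{t} column, the 17 compartments, and the
#' instantaneous \code{asr} and \code{osr} at each time point.
#'
#' @param traj data.frame from \code{\link{integrate_model}}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  ratios <- t(vapply(seq_len(nrow(traj)), function(i) {
    r <- sex_ratios(population_state(values = unlist(traj[i, -1])))
    c(asr = if (r$asr_defined) r$asr else NA_real_,
      osr = if (r$osr_defined) r$osr else NA_real_)
  }, numeric(2)))
  write_csv_12(cbind(traj, ratios), path)
}

#' Write an equilibrium result to JSON
#'
#' @param eq an \code{\link{find_equilibrium}} result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_equilibrium <- function(eq, path) {
  stopifnot(inherits(eq, "equilibrium_result"))
  out <- list(final_state = as.list(stats::setNames(as.numeric(eq$final_state),
                                                    names(eq$final_state))),
              t_final = eq$t_final,
              converged = eq$converged,
              residual = eq$residual,
              dominance = eq$dominance,
              ratios = eq$ratios,
              initial_total = eq$initial_total)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write and re-read a region map
#'
#' The map is written as a long-form CSV (one row per grid cell, columns
#' \code{axis1}, \code{axis2}, \code{dominance}, \code{osr}, \code{asr},
#' \code{converged}) plus a JSON metadata sidecar holding the axis names,
#' base parameters, settings and initial conditions. \code{read_region_map}
#' reconstructs an identical \code{\link{run_grid}} object from the pair.
#'
#' @param map a \code{\link{run_grid}} result.
#' @param csv_path path for the long-form CSV.
#' @param json_path path for the metadata JSON; defaults to the CSV path
#'   with extension \code{.json}.
#' @return The CSV path, invisibly.
#' @export
write_region_map <- function(map, csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(map, "region_map"))
  n1 <- length(map$axis1$values); n2 <- length(map$axis2$values)
  grid <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  df <- data.frame(axis1 = map$axis1$values[grid$i],
                   axis2 = map$axis2$values[grid$j],
                   dominance = map$dominance[cbind(grid$i, grid$j)],
                   osr = map$osr[cbind(grid$i, grid$j)],
                   asr = map$asr[cbind(grid$i, grid$j)],
                   converged = map$converged[cbind(grid$i, grid$j)])
  write_csv_12(df, csv_path)
  meta <- list(axis1 = list(name = map$axis1$name, values = map$axis1$values),
               axis2 = list(name = map$axis2$name, values = map$axis2$values),
               base = unclass(map$base),
               settings = unclass(map$settings),
               init = as.list(stats::setNames(as.numeric(map$init),
                                              names(map$init))))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv_path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(csv_path,
                            json_path = sub("\\.csv$", ".json", csv_path)) {
  df <- utils::read.csv(csv_path, fileEncoding = "UTF-8")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  a1 <- axis_spec(meta$axis1$name, meta$axis1$values)
  a2 <- axis_spec(meta$axis2$name, meta$axis2$values)
  n1 <- length(a1$values); n2 <- length(a2$values)
  shape <- function(x, mode) matrix(x, n1, n2)
  base_fields <- meta$base
  base <- do.call(parameter_set, base_fields)
  settings <- do.call(integration_settings, meta$settings)
  init <- population_state(values = unlist(meta$init))
  dom <- df$dominance
  dom[dom == ""] <- NA_character_
  structure(list(axis1 = a1, axis2 = a2,
                 dominance = shape(dom),
                 osr = shape(df$osr),
                 asr = shape(df$asr),
                 converged = shape(df$converged),
                 base = base, settings = settings, init = init),
            class = "region_map")
}

#' Write a boundary set to CSV
#'
#' @param boundary an \code{\link{extract_boundary}} result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_boundary <- function(boundary, path) {
  write_csv_12(as.data.frame(boundary), path)
}

#' Write an OSR/ASR curve to CSV
#'
#' @param curve an \code{\link{osr_curve}} result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_curve <- function(curve, path) {
  write_csv_12(curve, path)
}
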