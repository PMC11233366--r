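#' @title Simulation configuration
#' @name simulation-config
NULL

#' Simulator configuration with published defaults
#'
#' Every knob of the condensation simulator. The defaults are the stated
#' simulation conditions: a 400 x 400 periodic box (1 length unit = 10 nm),
#' 200 vesicles with normally distributed radii (mean 4.17, sd 1.08),
#' synapsin bead radius 0.5, tether stiffness `K = 100`, time step 5e-3,
#' 5e7 steps with a snapshot every 1e4 steps. Thermostat constants not
#' stated in the source are `kBT = 1`, `mass = 1`, `gamma = 1` (damping
#' time).
#'
#' @param model `"mono"` (single-bead synapsin) or `"bi"` (rigid N+C dimer).
#' @param box_length periodic box edge, reduced units.
#' @param n_vesicles number of vesicles.
#' @param vesicle_radius_mean,vesicle_radius_sd normal radius distribution,
#'   reduced units.
#' @param min_vesicle_radius truncation bound for the radius distribution.
#' @param synapsin_radius bead radius, reduced units.
#' @param lambda linear synapsin density (beads per unit tether-circle
#'   circumference).
#' @param eps attraction strength epsilon, kBT.
#' @param bond_K tether stiffness, kBT/length^2.
#' @param dimer_separation rigid N-C bead distance (bi model).
#' @param cc_same_vesicle_attract should C-C pairs on the same vesicle
#'   attract (bi model)? Default `FALSE`: same-vesicle C-C attraction makes
#'   each vesicle's linkers clump among themselves, reproducing the
#'   mono-domain pathology the two-bead model exists to avoid (see the
#'   methods vignette); set `TRUE` for the literal all-C-C-attract reading.
#' @param dt integration time step.
#' @param n_steps number of steps.
#' @param snapshot_interval steps between captured snapshots; must divide
#'   `n_steps`.
#' @param gamma Langevin damping time.
#' @param kBT thermal energy, reduced units.
#' @param mass per-bead mass.
#' @param seed integer seed controlling initialization and dynamics.
#' @return object of class `vc_config`.
#' @export
sim_config <- function(model = c("mono", "bi"),
                       box_length = 400,
                       n_vesicles = 200,
                       vesicle_radius_mean = 4.17,
                       vesicle_radius_sd = 1.08,
                       min_vesicle_radius = 1.0,
                       synapsin_radius = 0.5,
                       lambda = 0.7,
                       eps = 3.5,
                       bond_K = 100,
                       dimer_separation = 1,
                       cc_same_vesicle_attract = FALSE,
                       dt = 5e-3,
                       n_steps = 5e7,
                       snapshot_interval = 1e4,
                       gamma = 1,
                       kBT = 1,
                       mass = 1,
                       seed = 1L) {
  model <- match.arg(model)
  cfg <- list(model = model, box_length = box_length,
              n_vesicles = as.integer(n_vesicles),
              vesicle_radius_mean = vesicle_radius_mean,
              vesicle_radius_sd = vesicle_radius_sd,
              min_vesicle_radius = min_vesicle_radius,
              synapsin_radius = synapsin_radius,
              lambda = lambda, eps = eps, bond_K = bond_K,
              dimer_separation = dimer_separation,
              cc_same_vesicle_attract = isTRUE(cc_same_vesicle_attract),
              dt = dt, n_steps = n_steps,
              snapshot_interval = snapshot_interval,
              gamma = gamma, kBT = kBT, mass = mass,
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("box_length", "vesicle_radius_mean", "min_vesicle_radius",
           "synapsin_radius", "bond_K", "dimer_separation", "dt", "gamma",
           "mass")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be positive", f))
  nonneg <- c("vesicle_radius_sd", "lambda", "eps", "kBT", "n_steps")
  for (f in nonneg)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("config field '%s' must be non-negative", f))
  if (cfg$n_vesicles < 1) stop("n_vesicles must be at least 1")
  if (cfg$snapshot_interval < 1)
    stop("snapshot_interval must be a positive step count")
  if (cfg$n_steps > 0 && cfg$n_steps %% cfg$snapshot_interval != 0)
    stop("snapshot_interval must divide n_steps")
  structure(cfg, class = "vc_config")
}

#' @export
print.vc_config <- function(x, ...) {
  cat(sprintf("<vc_config> %s model: %d vesicles in %g x %g box\n",
              x$model, x$n_vesicles, x$box_length, x$box_length))
  cat(sprintf("  radii ~ N(%g, %g) truncated at %g; synapsin r = %g\n",
              x$vesicle_radius_mean, x$vesicle_radius_sd,
              x$min_vesicle_radius, x$synapsin_radius))
  cat(sprintf("  eps = %g kBT, lambda = %g, bond K = %g\n",
              x$eps, x$lambda, x$bond_K))
  cat(sprintf("  dt = %g, %g steps, snapshot every %g; kBT = %g, gamma = %g, seed = %d\n",
              x$dt, x$n_steps, x$snapshot_interval, x$kBT, x$gamma, x$seed))
  invisible(x)
}

# ---- minimal TOML-subset reader -------------------------------------------
# The run-config format is TOML restricted to [section] headers and scalar
# `key = value` lines (numbers, booleans, quoted strings, # comments). No
# TOML parser ships with the supported R environment, so this subset is
# parsed here.
parse_toml_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (k in seq_along(lines)) {
    line <- sub("#.*$", "", lines[k])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[A-Za-z0-9_.-]+\\]$", line)) {
      section <- sub("^\\[(.*)\\]$", "\\1", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3)
      stop(sprintf("%s:%d: cannot parse line: %s", path, k, lines[k]))
    key <- m[2]; raw <- trimws(m[3])
    value <-
      if (grepl('^".*"$', raw)) sub('^"(.*)"$', "\\1", raw)
      else if (raw %in% c("true", "false")) raw == "true"
      else {
        v <- suppressWarnings(as.numeric(raw))
        if (is.na(v)) stop(sprintf("%s:%d: bad value for '%s': %s",
                                   path, k, key, raw))
        v
      }
    if (is.null(section)) out[[key]] <- value else out[[section]][[key]] <- value
  }
  out
}

.config_sections <- list(
  model = c("model"),
  geometry = c("box_length", "n_vesicles", "vesicle_radius_mean",
               "vesicle_radius_sd", "min_vesicle_radius", "synapsin_radius",
               "dimer_separation"),
  interactions = c("eps", "lambda", "bond_K", "cc_same_vesicle_attract"),
  integration = c("dt", "n_steps", "gamma", "kBT", "mass", "seed"),
  output = c("snapshot_interval")
)

#' Load a simulator configuration from a TOML file
#'
#' Sections `[model]`, `[geometry]`, `[interactions]`, `[integration]`,
#' `[output]`; omitted keys take the published defaults; unknown sections
#' or keys are an error.
#'
#' @param path path to a TOML file.
#' @return a validated `vc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  toml <- parse_toml_subset(path)
  args <- list()
  for (sec in names(toml)) {
    if (!sec %in% names(.config_sections))
      stop(sprintf("unknown config section [%s]; allowed: %s", sec,
                   paste(names(.config_sections), collapse = ", ")))
    for (key in names(toml[[sec]])) {
      if (!key %in% .config_sections[[sec]])
        stop(sprintf("unknown key '%s' in section [%s]; allowed: %s",
                     key, sec,
                     paste(.config_sections[[sec]], collapse = ", ")))
      args[[key]] <- toml[[sec]][[key]]
    }
  }
  if (!is.null(args$model) && !args$model %in% c("mono", "bi"))
    stop(sprintf("model must be one of: mono, bi (got '%s')", args$model))
  do.call(sim_config, args)
}

#' Write a configuration to a TOML file
#'
#' Inverse of [load_config()]: the written file round-trips to an
#' identical resolved configuration.
#'
#' @param config a `vc_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vc_config"))
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  lines <- character(0)
  for (sec in names(.config_sections)) {
    lines <- c(lines, sprintf("[%s]", sec))
    for (key in .config_sections[[sec]])
      lines <- c(lines, sprintf("%s = %s", key, fmt(config[[key]])))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
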