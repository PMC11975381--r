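## Run configuration, serialization and the command-line entry point.

#' Full run configuration
#'
#' Bundles every parameter group of the model with defaults equal to the
#' published constants (lattice geometry, crossbridge springs, rate
#' constants, filament springs, titin, activation, work-loop protocol,
#' scaling, solver). All components can be replaced individually.
#'
#' @param lattice a [latticeConfig()].
#' @param xb a [crossbridgeParams()].
#' @param rates a [rateConstants()].
#' @param springs a [filamentSpringParams()].
#' @param titin a [titinParams()].
#' @param activation an [activationProfile()].
#' @param protocol a [workLoopProtocol()].
#' @param scaling list with `density` (kg/m^3); the stress area is derived
#'   from the run's d10 at run time.
#' @param solver a [solverSettings()].
#' @return an object of class `runConfig`.
#' @export
runConfig <- function(lattice = latticeConfig(),
                      xb = crossbridgeParams(),
                      rates = rateConstants(),
                      springs = filamentSpringParams(),
                      titin = titinParams(),
                      activation = activationProfile(),
                      protocol = workLoopProtocol(),
                      scaling = list(density = 1060),
                      solver = solverSettings()) {
  structure(list(lattice = lattice, xb = xb, rates = rates,
                 springs = springs, titin = titin, activation = activation,
                 protocol = protocol, scaling = scaling, solver = solver),
            class = "runConfig")
}

#' @export
print.runConfig <- function(x, ...) {
  cat("sarclat run configuration\n")
  cat(sprintf("  lattice: %d thick / %d thin, AM %.2f nm (%s)\n",
              x$lattice$n_thick, x$lattice$n_thin, x$lattice$am_spacing,
              x$lattice$muscle_type))
  cat(sprintf("  crossbridge: kr %.3g pN/nm, ktheta %.4g pN nm/rad^2\n",
              x$xb$kr, x$xb$ktheta))
  cat(sprintf("  rates: tau %.3g, A %.3g, C %.3g, D %.3g, G %.3g, H %.3g /ms; dG %.3g / %.3g kT\n",
              x$rates$tau, x$rates$A, x$rates$C, x$rates$D, x$rates$G,
              x$rates$H, x$rates$dG_weak, x$rates$dG_strong))
  cat(sprintf("  titin: a %.3g pN, b %.4g /nm; solver tol %.2g pN\n",
              x$titin$a, x$titin$b, x$solver$tol))
  invisible(x)
}

.classMap <- list(lattice = "latticeConfig", xb = "crossbridgeParams",
                  rates = "rateConstants", springs = "filamentSpringParams",
                  titin = "titinParams", activation = "activationProfile",
                  protocol = "workLoopProtocol", solver = "solverSettings")

# strip classes recursively for serialization
.plainConfig <- function(x) {
  x <- unclass(x)
  lapply(x, function(el) if (is.list(el)) .plainConfig(el) else el)
}

.checkKeys <- function(user, ref, path = "") {
  for (k in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(ref))
      stop(sprintf("unknown configuration key: %s", here), call. = FALSE)
    if (is.list(user[[k]]) && is.list(ref[[k]]))
      .checkKeys(user[[k]], ref[[k]], here)
  }
}

#' Load a run configuration from a YAML file
#'
#' Missing keys fall back to the defaults of [runConfig()]; unknown keys are
#' rejected with their path. Values are taken verbatim (the file stores the
#' internal representation: angles in radians, lengths nm, times ms, forces
#' pN). An empty file yields the full default configuration. The protocol
#' may carry a `lattice_trajectory` sub-map (`mode`, `nu`, `d_rest`,
#' optional `samples_file`).
#'
#' @param path YAML file path.
#' @return a validated [runConfig()].
#' @seealso [saveConfig()]
#' @export
loadConfig <- function(path) {
  user <- yaml::read_yaml(path)
  def <- runConfig()
  if (is.null(user) || length(user) == 0) return(def)
  ref <- .plainConfig(def)
  ref$protocol$lattice <- NULL
  ref$protocol$lattice_trajectory <-
    list(mode = "", nu = 0, d_rest = 0, samples_file = "")
  .checkKeys(user, ref)
  traj <- user$protocol$lattice_trajectory
  if (!is.null(user$protocol)) user$protocol$lattice_trajectory <- NULL
  plain <- .plainConfig(def)
  plain$protocol$lattice <- NULL
  merged <- modifyList(plain, user)
  cfg <- def
  for (k in setdiff(names(.classMap), "protocol")) {
    fields <- names(unclass(def[[k]]))
    cfg[[k]] <- structure(merged[[k]][fields], class = .classMap[[k]])
  }
  p <- merged$protocol
  lat <- NULL
  if (!is.null(traj)) {
    lat <- if (!is.null(traj$samples_file))
      readLatticeTrajectory(traj$samples_file)
    else latticeTrajectory(traj$mode %||% "constant",
                           nu = traj$nu %||%
                             if (identical(traj$mode, "poisson")) 0.5 else 0,
                           d_rest = traj$d_rest %||% 47.5)
  }
  cfg$protocol <- workLoopProtocol(p$frequency, p$strain_pp, p$phase,
                                   p$n_cycles, p$dt, lattice = lat)
  cfg$scaling <- merged$scaling
  validateLatticeConfig(cfg$lattice)
  stopifnot(cfg$xb$kr > 0, cfg$xb$ktheta > 0, cfg$solver$tol > 0)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration to YAML
#'
#' Writes the internal representation (see [loadConfig()]); a save/load
#' round trip reproduces the configuration exactly.
#'
#' @param config a [runConfig()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  stopifnot(inherits(config, "runConfig"))
  plain <- .plainConfig(config)
  traj <- plain$protocol$lattice
  plain$protocol$lattice <- NULL
  if (!is.null(traj))
    plain$protocol$lattice_trajectory <-
      list(mode = traj$mode, nu = traj$nu, d_rest = traj$d_rest)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' Write a work-loop (or twitch/tetanus) time series to CSV
#'
#' @param x a `workLoopResult` or `sarcTrace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSeriesCsv <- function(x, path) {
  write.csv(x$series, path, row.names = FALSE)
  invisible(path)
}

#' Write a work-loop summary to JSON
#'
#' Per-cycle net work, mean and s.d., the protocol, seed, version stamp and
#' a configuration echo.
#'
#' @param x a `workLoopResult`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWorkLoopJson <- function(x, path) {
  stopifnot(inherits(x, "workLoopResult"))
  prot <- .plainConfig(x$protocol)
  prot$lattice <- if (is.null(x$protocol$lattice)) "constant"
                  else x$protocol$lattice$mode
  out <- list(
    sarclat_version = as.character(packageVersion("sarclat")),
    kind = "workloop",
    seed = x$seed,
    protocol = prot,
    d10_rest = x$scaling$d10,
    work_per_cycle = x$work_per_cycle,
    work_mean = x$work_mean,
    work_sd = x$work_sd,
    config = .plainConfig(x$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## ---- command-line interface ----------------------------------------------

.cliUsage <- function() {
  message("usage: sarclat <twitch|tetanus|workloop|sweep> [kind] [options]")
  message("  sweep kinds: phase lattice stiffness titin")
  message("  options: --config FILE --phase P --am-spacing NM --poisson NU")
  message("           --lattice-file FILE --freq HZ --amp PP --cycles N")
  message("           --dt MS --duration MS --seed S --out PREFIX")
}

#' Command-line entry point
#'
#' Thin driver behind the `inst/cli/sarclat` script: subcommands `twitch`,
#' `tetanus`, `workloop` and `sweep <phase|lattice|stiffness|titin>`.
#' Writes `<out>.csv` (time series or tidy sweep table) and, for work loops,
#' `<out>.json` (summary); logs parameters and per-cycle work.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  subs <- c("twitch", "tetanus", "workloop", "sweep")
  if (length(args) < 1 || !args[1] %in% subs) {
    .cliUsage()
    return(invisible(1L))
  }
  if (!requireNamespace("optparse", quietly = TRUE)) {
    message("the command-line interface needs the 'optparse' package")
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  kind <- NULL
  if (sub == "sweep") {
    if (length(rest) < 1 ||
        !rest[1] %in% c("phase", "lattice", "stiffness", "titin")) {
      .cliUsage()
      return(invisible(1L))
    }
    kind <- rest[1]
    rest <- rest[-1]
  }
  olist <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--phase", type = "double", default = NULL),
    optparse::make_option("--am-spacing", type = "double", default = NULL,
                          dest = "am_spacing"),
    optparse::make_option("--poisson", type = "double", default = NULL),
    optparse::make_option("--lattice-file", type = "character",
                          default = NULL, dest = "lattice_file"),
    optparse::make_option("--freq", type = "double", default = NULL),
    optparse::make_option("--amp", type = "double", default = NULL),
    optparse::make_option("--cycles", type = "integer", default = NULL),
    optparse::make_option("--dt", type = "double", default = NULL),
    optparse::make_option("--duration", type = "double", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "sarclat_run"))
  opt <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = olist),
                         args = rest),
    error = function(e) e)
  if (inherits(opt, "error")) {
    message(conditionMessage(opt))
    .cliUsage()
    return(invisible(1L))
  }
  if (!is.null(opt$poisson) && !is.null(opt$lattice_file)) {
    message("--poisson and --lattice-file are mutually exclusive")
    return(invisible(1L))
  }
  cfg <- if (!is.null(opt$config)) loadConfig(opt$config) else runConfig()
  if (!is.null(opt$am_spacing)) cfg$lattice$am_spacing <- opt$am_spacing
  prot <- cfg$protocol
  if (!is.null(opt$phase)) prot$phase <- opt$phase
  if (!is.null(opt$freq)) prot$frequency <- opt$freq
  if (!is.null(opt$amp)) prot$strain_pp <- opt$amp
  if (!is.null(opt$cycles)) prot$n_cycles <- opt$cycles
  if (!is.null(opt$dt)) {
    prot$dt <- opt$dt
    cfg$protocol$dt <- opt$dt
  }
  prot$period <- 1000 / prot$frequency
  if (!is.null(opt$poisson))
    prot$lattice <- latticeTrajectory(
      "poisson", nu = opt$poisson,
      d_rest = d10FromAm(cfg$lattice$am_spacing, cfg$lattice$muscle_type))
  if (!is.null(opt$lattice_file))
    prot$lattice <- readLatticeTrajectory(opt$lattice_file)
  cfg$protocol <- prot
  message(sprintf("sarclat %s | seed %d | AM %.2f nm",
                  as.character(packageVersion("sarclat")), opt$seed,
                  cfg$lattice$am_spacing))
  if (sub == "twitch" || sub == "tetanus") {
    dur <- opt$duration %||% if (sub == "twitch") 200 else 300
    res <- if (sub == "twitch") simulateTwitch(cfg, dur, seed = opt$seed)
           else simulateTetanus(cfg, dur, seed = opt$seed)
    print(res)
    writeSeriesCsv(res, paste0(opt$out, ".csv"))
    message(sprintf("wrote %s.csv", opt$out))
  } else if (sub == "workloop") {
    res <- simulateWorkLoop(prot, cfg, seed = opt$seed)
    message(sprintf("per-cycle work (J/kg): %s",
                    paste(sprintf("%.3f", res$work_per_cycle),
                          collapse = " ")))
    print(res)
    writeSeriesCsv(res, paste0(opt$out, ".csv"))
    writeWorkLoopJson(res, paste0(opt$out, ".json"))
    message(sprintf("wrote %s.csv and %s.json", opt$out, opt$out))
  } else {
    tab <- sweepNetWork(kind, config = cfg, protocol = prot,
                        seed = opt$seed)
    write.csv(tab, paste0(opt$out, ".csv"), row.names = FALSE)
    print(tab)
    message(sprintf("wrote %s.csv", opt$out))
  }
  invisible(0L)
}
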