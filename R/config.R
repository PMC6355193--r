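#' @include engine.R
NULL

# Full default configuration. Every published protocol constant appears
# explicitly so a saved config is self-documenting.
.defaultConfig <- function() {
  list(
    network = list(
      source = "default",
      vn_drive = 2.15,
      synapse = defaultSynapseParams(),
      nap = defaultNapParams()
    ),
    protocol = list(
      target = "CnF-Glu",
      side = "l",
      m = 1.35,
      b = 3.95,
      alpha = 0,
      fixed_drives = list(),
      lesions = list(),
      sigma_noise = 0.005,
      duration_s = 10,
      dt = 0.1,
      seed = 1
    ),
    analysis = list(
      sweep_steps = 1000,
      chunk_s = 10,
      cap_s = 200,
      tol = 0.001,
      alpha_step = 0.01,
      noisy_duration_s = 100,
      noisy_sigma = 1,
      phase_bins = 65,
      freq_bin = 0.25,
      freq_max = 14,
      gait_windows = gaitWindows()
    ),
    grid = list(
      ex_from = 2.78, ex_to = 3.06, ex_by = 0.02,
      in_target = "CnF-GABA/Gly",
      in_from = 1.15, in_to = 2.85, in_by = 0.07
    ),
    robustness = list(
      sigma_p = seq(0.02, 0.2, by = 0.02),
      n_models = 100,
      sweep_steps = 40
    ),
    output = list(dir = "locomotor-out")
  )
}

.mergeConfig <- function(def, usr, path = "") {
  if (!is.list(usr)) return(usr)
  extra <- setdiff(names(usr), names(def))
  if (length(extra) && !is.null(names(def)) && length(names(def)))
    stop("unknown config key(s): ",
         paste(paste0(path, extra), collapse = ", "))
  for (k in names(usr)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]])) &&
        length(names(def[[k]])))
      def[[k]] <- .mergeConfig(def[[k]], usr[[k]], paste0(path, k, "."))
    else def[[k]] <- usr[[k]]
  }
  def
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills in every default (so the returned
#' object states all protocol constants explicitly: 1000 sweep steps, 65
#' phase bins, 0.25-Hz frequency bins, baseline noise 0.005 pA, vestibular
#' drive 2.15, ...), and rejects unknown keys and unknown population names.
#'
#' @param path YAML file path, or \code{NULL} for the pure defaults.
#' @return validated configuration list.
#' @export
loadConfig <- function(path = NULL) {
  usr <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- .mergeConfig(.defaultConfig(), if (is.null(usr)) list() else usr)
  net <- buildDefaultNetwork()
  known <- c(unique(net@populations$name), "LPGi-Glu",
             names(.POP_ALIASES))
  tgt <- cfg$protocol$target
  if (!is.null(tgt) && !tgt %in% known)
    stop("unknown stimulation target in config: ", tgt)
  if (!cfg$grid$in_target %in% known)
    stop("unknown grid in_target: ", cfg$grid$in_target)
  for (fd in cfg$protocol$fixed_drives)
    if (!fd$target %in% known)
      stop("unknown fixed-drive target: ", fd$target)
  if (cfg$protocol$alpha < 0 || cfg$protocol$alpha > 1.05)
    stop("protocol alpha outside [0, 1.05]")
  cfg
}

#' Save a configuration to YAML
#'
#' @param config configuration list.
#' @param path output file.
#' @return the path, invisibly.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.cfgNetwork <- function(cfg) {
  syn <- modifyList(defaultSynapseParams(), cfg$network$synapse)
  net <- buildDefaultNetwork(synapse = syn)
  nap <- modifyList(defaultNapParams(), cfg$network$nap)
  pops <- net@populations
  sel <- pops$dynamics == "nap"
  for (f in names(nap)) pops[[f]][sel] <- nap[[f]]
  net@populations <- pops
  if (!identical(cfg$network$vn_drive, 2.15))
    net@drives$value <- rep(cfg$network$vn_drive, nrow(net@drives))
  net
}

.writeTSV <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writeManifest <- function(outDir, cmd, cfg, t0, files) {
  man <- list(command = cmd,
              config = cfg,
              seed = cfg$protocol$seed,
              version = as.character(utils::packageVersion("locomotoR")),
              wall_time_s = round(as.numeric(Sys.time()) - t0, 2),
              files = files)
  path <- file.path(outDir, paste0(cmd, "-manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run one analysis command from a configuration
#'
#' Thin dispatcher behind the command-line interface. Each subcommand runs
#' the corresponding package function and writes tab-separated result
#' tables plus a JSON manifest (configuration echo, seed, package version,
#' wall time) into the configured output directory.
#'
#' Subcommands: \code{"simulate"} (single run, time-series TSV),
#' \code{"sweep"} (bifurcation diagram, one TSV per branch),
#' \code{"noisy-sweep"} (cycle-record TSV, phase-frequency histogram and
#' gait-probability map), \code{"grid"} (drive-grid TSV),
#' \code{"robustness"} (report JSON) and \code{"calibrate"} (calibrated
#' persistent-sodium parameters, YAML).
#'
#' @param subcommand one of the names above.
#' @param config configuration list (\code{\link{loadConfig}}).
#' @return invisibly, the list of files written.
#' @export
runCommand <- function(subcommand = c("simulate", "sweep", "noisy-sweep",
                                      "grid", "robustness", "calibrate"),
                       config = loadConfig()) {
  subcommand <- match.arg(subcommand)
  cfg <- config
  t0 <- as.numeric(Sys.time())
  outDir <- cfg$output$dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  net <- .cfgNetwork(cfg)
  p <- cfg$protocol
  a <- cfg$analysis
  lesions <- unlist(p$lesions)
  if (is.null(lesions)) lesions <- character()
  fx <- if (length(p$fixed_drives))
    do.call(rbind, lapply(p$fixed_drives, function(d)
      data.frame(target = d$target,
                 side = if (is.null(d$side)) "both" else d$side,
                 value = d$value, stringsAsFactors = FALSE)))
  else NULL
  files <- character()
  if (subcommand == "simulate") {
    pr <- Protocol(net, p$target, p$side, p$m, p$b, alpha = p$alpha,
                   fixedDrives = fx, lesions = lesions,
                   sigmaNoise = p$sigma_noise,
                   duration = p$duration_s * 1000, dt = p$dt,
                   seed = p$seed)
    res <- simulateNetwork(net, pr)
    d <- data.frame(time_ms = res@time, res@f, check.names = FALSE)
    files <- .writeTSV(d, file.path(outDir, "timeseries.tsv"))
    rec <- cycleRecords(res@time, res@f[, 1], res@f[, 2], res@f[, 3],
                        res@f[, 4])
    files <- c(files, .writeTSV(rec, file.path(outDir, "cycles.tsv")))
  } else if (subcommand == "sweep") {
    bd <- bifurcationSweep(net, p$target, p$side, m = p$m, b = p$b,
                           nSteps = a$sweep_steps,
                           chunk = a$chunk_s * 1000, cap = a$cap_s * 1000,
                           tol = a$tol, dt = p$dt, lesions = lesions,
                           fixedDrives = fx)
    files <- c(.writeTSV(bd@up, file.path(outDir, "sweep-up.tsv")),
               .writeTSV(bd@down, file.path(outDir, "sweep-down.tsv")))
  } else if (subcommand == "noisy-sweep") {
    rec <- noisySweep(net, p$target, p$side, m = p$m, b = p$b,
                      alphaStep = a$alpha_step,
                      durationPerStep = a$noisy_duration_s * 1000,
                      sigmaNoise = a$noisy_sigma, seed = p$seed,
                      lesions = lesions)
    files <- .writeTSV(rec, file.path(outDir, "cycles.tsv"))
    hist <- phaseFrequencyHistogram(rec, phaseBins = a$phase_bins,
                                    freqMax = a$freq_max,
                                    freqBin = a$freq_bin)
    gm <- gaitProbabilityMap(rec, freqMax = a$freq_max,
                             freqBin = a$freq_bin)
    hp <- file.path(outDir, "phase-frequency-histogram.tsv")
    write.table(hist$density, hp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    gp <- file.path(outDir, "gait-probability.tsv")
    write.table(cbind(gait = rownames(gm$prob), as.data.frame(gm$prob)),
                gp, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(phase_breaks = hist$phaseBreaks,
                              freq_breaks = hist$freqBreaks,
                              total_cycles = hist$total,
                              out_of_range = hist$outOfRange),
                         file.path(outDir, "histogram-axes.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, hp, gp, file.path(outDir, "histogram-axes.json"))
  } else if (subcommand == "grid") {
    g <- cfg$grid
    gd <- driveGrid(net, seq(g$ex_from, g$ex_to, by = g$ex_by),
                    g$in_target, seq(g$in_from, g$in_to, by = g$in_by),
                    chunk = a$chunk_s * 1000, cap = a$cap_s * 1000,
                    tol = a$tol, dt = p$dt)
    files <- .writeTSV(gd, file.path(outDir, "drive-grid.tsv"))
  } else if (subcommand == "robustness") {
    r <- cfg$robustness
    rep_ <- robustnessSuite(net, unlist(r$sigma_p), r$n_models,
                            seed = p$seed, m = p$m, b = p$b,
                            nSteps = r$sweep_steps)
    rp <- file.path(outDir, "robustness.json")
    jsonlite::write_json(list(summary = rep_$summary,
                              nSteps = rep_$nSteps),
                         rp, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(rp, .writeTSV(rep_$models,
                             file.path(outDir, "robustness-models.tsv")))
  } else if (subcommand == "calibrate") {
    cal <- calibrateRGCenter()
    cp <- file.path(outDir, "calibrated-nap.yaml")
    yaml::write_yaml(cal$params, cp)
    files <- c(cp, .writeTSV(cal$curve,
                             file.path(outDir, "calibration-curve.tsv")))
  }
  files <- c(files, .writeManifest(outDir, subcommand, cfg, t0, files))
  invisible(files)
}
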