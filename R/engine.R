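#' @include AllClasses.R dynamics.R connectome.R gait.R
#' @useDynLib locomotoR, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Resolve a stimulation target name (+ side) to population ids.
# "LPGi-Glu" expands to both glutamatergic LPGi subpopulations.
.stimTargets <- function(net, target, side = c("l", "r", "both")) {
  side <- match.arg(side)
  target <- .canonName(target)
  pops <- net@populations
  nms <- if (target == "LPGi-Glu") c("LPGi-Glu-1", "LPGi-Glu-2") else target
  hit <- pops$name %in% nms
  if (side != "both") hit <- hit & pops$side == side
  if (!any(hit))
    stop("unknown stimulation target: ", target,
         "; valid population names: ",
         paste(sort(unique(pops$name)), collapse = ", "))
  pops$id[hit]
}

#' Construct a simulation protocol
#'
#' @param net the \code{\link{Network}} the protocol applies to (used to
#'   resolve target names).
#' @param target stimulated population name (e.g. \code{"CnF-Glu"},
#'   \code{"PPN-Glu"}, \code{"LPGi-Glu"}, \code{"CnF-GABA/Gly"}), or
#'   \code{NULL} for no variable stimulation.
#' @param side \code{"l"}, \code{"r"} or \code{"both"}.
#' @param m,b drive-law slope and intercept (\code{\link{driveStrength}}).
#' @param alpha stimulation strength in \eqn{[0, 1.05]}.
#' @param fixedDrives optional \code{data.frame} with columns \code{target}
#'   (population name or id), \code{side}, \code{value} for drives at fixed
#'   strength.
#' @param lesions character vector of regions to lesion before simulating.
#' @param sigmaNoise noise level (pA) for all populations; \code{NA} keeps
#'   per-population values.
#' @param duration run length (ms); \code{dt} integration step (ms).
#' @param dt integration step (ms).
#' @param seed RNG seed for stochastic runs.
#' @return a \code{\link{Protocol}}.
#' @export
Protocol <- function(net, target = NULL, side = "l", m = 0, b = 0,
                     alpha = 0, fixedDrives = NULL, lesions = character(),
                     sigmaNoise = NA_real_, duration = 10000, dt = 0.1,
                     seed = 1) {
  stim <- if (is.null(target))
    data.frame(target = character(), m = numeric(), b = numeric(),
               stringsAsFactors = FALSE)
  else
    data.frame(target = .stimTargets(net, target, side), m = m, b = b,
               stringsAsFactors = FALSE)
  fx <- data.frame(target = character(), value = numeric(),
                   stringsAsFactors = FALSE)
  if (!is.null(fixedDrives) && nrow(fixedDrives)) {
    ids <- unlist(lapply(seq_len(nrow(fixedDrives)), function(k) {
      .stimTargets(net, fixedDrives$target[k],
                   if (is.null(fixedDrives$side)) "both"
                   else fixedDrives$side[k])
    }))
    reps <- vapply(seq_len(nrow(fixedDrives)), function(k) {
      length(.stimTargets(net, fixedDrives$target[k],
                          if (is.null(fixedDrives$side)) "both"
                          else fixedDrives$side[k]))
    }, integer(1))
    fx <- data.frame(target = ids, value = rep(fixedDrives$value, reps),
                     stringsAsFactors = FALSE)
  }
  new("Protocol", stimulations = stim, alpha = alpha, fixedDrives = fx,
      lesions = lesions, sigmaNoise = sigmaNoise, duration = duration,
      dt = dt, seed = seed)
}

# Total dimensionless drive per population id: network constant drives plus
# protocol fixed drives plus the stimulation drive law at the given alpha.
.driveVector <- function(net, protocol, alpha = protocol@alpha) {
  dr <- setNames(net@drives$value, net@drives$target)
  addTo <- function(dr, ids, vals) {
    for (k in seq_along(ids)) {
      id <- ids[k]
      dr[id] <- (if (id %in% names(dr)) dr[[id]] else 0) + vals[k]
    }
    dr
  }
  fx <- protocol@fixedDrives
  if (nrow(fx)) dr <- addTo(dr, fx$target, fx$value)
  st <- protocol@stimulations
  if (nrow(st))
    dr <- addTo(dr, st$target, driveStrength(alpha, st$m, st$b))
  dr
}

# ids of the four flexor centers used for gait read-out, in the fixed order
# left hind, right hind, left fore, right fore
.rgIds <- function(net) {
  c("RG-F:l:hind", "RG-F:r:hind", "RG-F:l:fore", "RG-F:r:fore")
}

#' Integrate a network under a protocol
#'
#' Applies the protocol's lesions, assembles the tonic drives (network
#' constants, fixed drives and the stimulation law at the protocol's
#' \eqn{\alpha}) and integrates the population dynamics with the compiled
#' fixed-step core: classical RK4 for deterministic runs, RK4 with a
#' per-step Euler-Maruyama update of the Ornstein-Uhlenbeck noise currents
#' for stochastic runs. With \code{sigmaNoise = 0} results are exactly
#' reproducible; with noise they are reproducible given the protocol seed.
#'
#' @param net a \code{\link{Network}}.
#' @param protocol a \code{\link{Protocol}}.
#' @param record population ids to record (default: the four flexor
#'   centers), or \code{"all"}.
#' @param state0 warm-start state vector (default: rest).
#' @param sampleEvery recording interval (ms).
#' @return a \code{\link{SimulationResult}}.
#' @examples
#' \donttest{
#' net <- buildDefaultNetwork()
#' pr <- Protocol(net, "CnF-Glu", "l", m = 1.35, b = 3.95, alpha = 0.6,
#'                duration = 3000)
#' res <- simulateNetwork(net, pr)
#' }
#' @export
simulateNetwork <- function(net, protocol, record = NULL, state0 = NULL,
                            sampleEvery = 1) {
  if (length(protocol@lesions))
    net <- applyLesion(net, protocol@lesions)
  drv <- .driveVector(net, protocol)
  cn <- .compileNetwork(net, drv, protocol@sigmaNoise)
  noisy <- any(cn$sigma > 0)
  if (is.null(state0)) state0 <- .initialState(net)
  ids <- net@populations$id
  if (is.null(record)) record <- intersect(.rgIds(net), ids)
  if (identical(record, "all")) record <- ids
  ri <- match(record, ids)
  if (anyNA(ri)) stop("unknown population id in record")
  if (noisy) set.seed(protocol@seed)
  out <- cpp_simulate(cn, state0, protocol@duration, protocol@dt,
                      sampleEvery, ri - 1L, noisy)
  colnames(out$V) <- record
  colnames(out$f) <- record
  new("SimulationResult", time = out$time, V = out$V, f = out$f,
      finalState = out$final, protocol = protocol,
      blewUp = out$blewUp, blewAt = as.numeric(out$blewAt))
}

# Core settling procedure: integrate in chunks until the four phase
# differences are stationary (centered SD over the last five cycles below
# tol), quiescence is detected, or the time cap is reached.
#
# Returns list(status, freq, phase (named, 4), state, maxSD, blewUp).
.settle <- function(net, driveVec, state = NULL, chunk = 10000,
                    cap = 200000, tol = 0.001, dt = 0.1,
                    quiescentAmp = 0.05) {
  cn <- .compileNetwork(net, driveVec)
  if (is.null(state)) state <- .initialState(net)
  ids <- net@populations$id
  ri <- match(.rgIds(net), ids)
  elapsed <- 0
  last <- NULL
  while (elapsed < cap) {
    out <- cpp_simulate(cn, state, chunk, dt, 1, ri - 1L, FALSE)
    state <- out$final
    elapsed <- elapsed + chunk
    if (out$blewUp)
      return(list(status = "blowup", freq = NA_real_,
                  phase = rep(NA_real_, 4), state = state,
                  maxSD = NA_real_, blewUp = TRUE))
    f <- out$f
    tm <- out$time
    # quiescence: flat reference trace or no onsets late in the chunk
    refF <- f[, 1]
    tail5 <- tm >= max(tm) - 5000
    on <- detectOnsets(refF, tm)
    flat <- diff(range(refF[tail5])) < quiescentAmp
    noLateOnset <- !any(on > max(tm) - 3000)
    rec <- cycleRecords(tm, f[, 1], f[, 2], f[, 3], f[, 4],
                        classify = FALSE)
    if ((flat || noLateOnset) && nrow(rec) < 5)
      return(list(status = "quiescent", freq = NA_real_,
                  phase = rep(NA_real_, 4), state = state,
                  maxSD = NA_real_, blewUp = FALSE))
    if (nrow(rec) >= 5) {
      lastRec <- tail(rec, 5)
      phi <- as.matrix(lastRec[, c("hindLR", "foreLR", "homolateral",
                                   "diagonal")])
      if (!anyNA(phi)) {
        centred <- apply(phi, 2, function(x) ((x - x[1] + 0.5) %% 1) - 0.5)
        sds <- apply(centred, 2, sd)
        mean_ <- apply(phi, 2, .circMean)
        freq <- 1000 / mean(lastRec$period)
        last <- list(phase = mean_, freq = freq, maxSD = max(sds))
        if (max(sds) < tol)
          return(list(status = "converged", freq = freq, phase = mean_,
                      state = state, maxSD = max(sds), blewUp = FALSE))
      }
    }
  }
  if (is.null(last))
    list(status = "timeout", freq = NA_real_, phase = rep(NA_real_, 4),
         state = state, maxSD = NA_real_, blewUp = FALSE)
  else
    list(status = "timeout", freq = last$freq, phase = last$phase,
         state = state, maxSD = last$maxSD, blewUp = FALSE)
}

.circMean <- function(x) {
  (atan2(mean(sin(2 * pi * x)), mean(cos(2 * pi * x))) / (2 * pi)) %% 1
}

#' Settle the network at one stimulation strength
#'
#' Integrates in fixed-length chunks until, over the last five locomotor
#' cycles, the standard deviation of each of the four inter-limb phase
#' differences falls below the tolerance, or quiescence is detected, or the
#' time cap passes. The oscillation frequency is the reciprocal of the mean
#' cycle period over those five cycles.
#'
#' @param net a \code{\link{Network}}.
#' @param target,side,m,b stimulation drive law (see \code{\link{Protocol}}).
#' @param alpha stimulation strength.
#' @param state warm-start state (continuation); default rest.
#' @param chunk chunk length (ms); \code{cap} total time budget (ms);
#'   \code{tol} phase-difference SD tolerance; \code{dt} step (ms).
#' @param cap maximum total integration time (ms).
#' @param tol convergence tolerance on the phase-difference SD.
#' @param dt integration step (ms).
#' @param fixedDrives optional fixed drives (as in \code{\link{Protocol}}).
#' @param lesions regions to lesion.
#' @return list with \code{status} (\code{"converged"}, \code{"timeout"},
#'   \code{"quiescent"} or \code{"blowup"}), \code{freq} (Hz), \code{phase}
#'   (named vector: hindLR, foreLR, homolateral, diagonal), \code{state}
#'   (final state for continuation) and \code{maxSD}.
#' @export
settleAtAlpha <- function(net, target, side = "l", m = 0, b = 0, alpha = 0,
                          state = NULL, chunk = 10000, cap = 200000,
                          tol = 0.001, dt = 0.1, fixedDrives = NULL,
                          lesions = character()) {
  if (length(lesions)) net <- applyLesion(net, lesions)
  pr <- Protocol(net, target, side, m, b, alpha = alpha,
                 fixedDrives = fixedDrives, lesions = character())
  .settle(net, .driveVector(net, pr), state, chunk, cap, tol, dt)
}

.branch <- function(net, pr, alphas, state, chunk, cap, tol, dt) {
  rows <- vector("list", length(alphas))
  for (k in seq_along(alphas)) {
    res <- .settle(net, .driveVector(net, pr, alphas[k]), state, chunk,
                   cap, tol, dt)
    state <- res$state
    gait <- if (res$status %in% c("converged", "timeout") &&
                !anyNA(res$phase))
      classifyGait(res$phase) else res$status
    rows[[k]] <- data.frame(alpha = alphas[k], freq = res$freq,
                            hindLR = res$phase[1], foreLR = res$phase[2],
                            homolateral = res$phase[3],
                            diagonal = res$phase[4],
                            status = res$status, gait = gait,
                            maxSD = res$maxSD, stringsAsFactors = FALSE)
  }
  list(tab = do.call(rbind, rows), state = state)
}

#' Continuation sweep of the stimulation strength
#'
#' Increases \eqn{\alpha} from 0 to 1.05 and then decreases it back in
#' equally spaced steps. Each step warm-starts from the final state of the
#' previous one (separately along the up and the down branch, the down
#' branch continuing from the up branch's final state), so regions where
#' the two branches disagree expose bistability between adjacent gaits.
#' A short burn-in at \eqn{\alpha = 0} precedes the first recorded step.
#'
#' @param net a \code{\link{Network}}.
#' @param target,side,m,b the swept stimulation drive law.
#' @param nSteps number of \eqn{\alpha} steps per branch (published
#'   protocol: 1000; reduced sweeps are standard for desk-scale work).
#' @param alphaMax top of the sweep (default 1.05).
#' @param chunk,cap,tol,dt settling controls (\code{\link{settleAtAlpha}}).
#' @param lesions regions lesioned for the whole sweep.
#' @param fixedDrives optional fixed drives.
#' @param burnIn settling time at \eqn{\alpha = 0} before the sweep (ms).
#' @return a \code{\link{BifurcationDiagram}}.
#' @export
bifurcationSweep <- function(net, target, side = "l", m, b, nSteps = 1000,
                             alphaMax = 1.05, chunk = 10000, cap = 200000,
                             tol = 0.001, dt = 0.1, lesions = character(),
                             fixedDrives = NULL, burnIn = 2000) {
  if (length(lesions)) net <- applyLesion(net, lesions)
  pr <- Protocol(net, target, side, m, b, alpha = 0,
                 fixedDrives = fixedDrives)
  alphas <- seq(0, alphaMax, length.out = nSteps)
  cn <- .compileNetwork(net, .driveVector(net, pr, 0))
  ids <- net@populations$id
  ri <- match(.rgIds(net), ids)
  st <- cpp_simulate(cn, .initialState(net), burnIn, dt, burnIn, ri - 1L,
                     FALSE)$final
  up <- .branch(net, pr, alphas, st, chunk, cap, tol, dt)
  down <- .branch(net, pr, rev(alphas), up$state, chunk, cap, tol, dt)
  new("BifurcationDiagram", up = up$tab, down = down$tab,
      stimulation = data.frame(target = target, side = side, m = m, b = b,
                               stringsAsFactors = FALSE))
}

#' Stochastic sweep producing per-cycle records
#'
#' Increases \eqn{\alpha} in small steps, integrating the network with
#' Ornstein-Uhlenbeck noise currents for a fixed duration at each step and
#' pooling one record per detected locomotor cycle (frequency, the four
#' phase differences and the gait label) across all steps. The state is
#' carried from step to step, emulating ongoing locomotion under slowly
#' rising stimulation.
#'
#' @param net a \code{\link{Network}}.
#' @param target,side,m,b the stimulation drive law.
#' @param alphaStep increment of \eqn{\alpha} (published protocol 0.01).
#' @param durationPerStep time simulated at each step (ms; published
#'   protocol 100 s).
#' @param sigmaNoise noise level (pA); must be > 0.
#' @param seed RNG seed.
#' @param alphaMax top of the sweep.
#' @param dt integration step (ms; stochastic runs use a coarser step than
#'   deterministic ones).
#' @param lesions regions lesioned for the whole sweep.
#' @param discard initial time (ms) of each step excluded from the cycle
#'   pool while the network re-equilibrates.
#' @return \code{data.frame} of cycle records with an \code{alpha} column.
#' @export
noisySweep <- function(net, target, side = "l", m, b, alphaStep = 0.01,
                       durationPerStep = 100000, sigmaNoise = 1, seed = 1,
                       alphaMax = 1.05, dt = 0.2, lesions = character(),
                       discard = 1000) {
  if (sigmaNoise <= 0) stop("noisySweep requires sigmaNoise > 0")
  if (length(lesions)) net <- applyLesion(net, lesions)
  pr <- Protocol(net, target, side, m, b, alpha = 0,
                 sigmaNoise = sigmaNoise)
  alphas <- seq(0, alphaMax, by = alphaStep)
  ids <- net@populations$id
  ri <- match(.rgIds(net), ids)
  state <- .initialState(net)
  set.seed(seed)
  recs <- vector("list", length(alphas))
  for (k in seq_along(alphas)) {
    cn <- .compileNetwork(net, .driveVector(net, pr, alphas[k]),
                          sigmaNoise)
    out <- cpp_simulate(cn, state, durationPerStep, dt, 1, ri - 1L, TRUE)
    state <- out$final
    if (out$blewUp) stop("integration failure at alpha = ", alphas[k])
    keep <- out$time >= discard
    rec <- cycleRecords(out$time[keep], out$f[keep, 1], out$f[keep, 2],
                        out$f[keep, 3], out$f[keep, 4])
    if (nrow(rec)) rec$alpha <- alphas[k]
    recs[[k]] <- rec
  }
  do.call(rbind, recs[vapply(recs, nrow, integer(1)) > 0])
}

#' Two-dimensional drive grid: excitation versus inhibition
#'
#' Locomotion is evoked by bilateral excitatory drive to the glutamatergic
#' CnF populations; at each excitatory level, an excitatory drive to one
#' inhibitory brainstem population (CnF, PPN or LPGi GABA/Gly, unilateral
#' left) is stepped up, warm-starting each cell from its left neighbour.
#' Each cell records the settled frequency and gait, or quiescence.
#'
#' @param net a \code{\link{Network}}.
#' @param exRange bilateral CnF-Glu drive values (published range 2.78 to
#'   3.06 in 0.02 steps).
#' @param inTarget inhibitory population name (\code{"CnF-GABA/Gly"},
#'   \code{"PPN-GABA/Gly"} or \code{"LPGi-GABA/Gly"}).
#' @param inRange inhibitory-stimulation drive values (published range 1.15
#'   to 2.85 in 0.07 steps).
#' @param chunk,cap,tol,dt settling controls.
#' @return \code{data.frame} with one row per (ex, in) cell: \code{ex},
#'   \code{inh}, \code{freq}, \code{status}, \code{gait}.
#' @export
driveGrid <- function(net, exRange = seq(2.78, 3.06, by = 0.02),
                      inTarget = "CnF-GABA/Gly",
                      inRange = seq(1.15, 2.85, by = 0.07),
                      chunk = 10000, cap = 200000, tol = 0.001, dt = 0.1) {
  tgt <- .canonName(inTarget)
  if (!tgt %in% .INH_POPS)
    stop("inTarget must name an inhibitory population, got: ", inTarget)
  rows <- list()
  for (ex in exRange) {
    fx0 <- data.frame(target = "CnF-Glu", side = "both", value = ex,
                      stringsAsFactors = FALSE)
    state <- NULL
    for (inh in c(0, inRange)) {
      fx <- if (inh > 0)
        rbind(fx0, data.frame(target = inTarget, side = "l", value = inh,
                              stringsAsFactors = FALSE))
      else fx0
      pr <- Protocol(net, fixedDrives = fx)
      res <- .settle(net, .driveVector(net, pr), state, chunk, cap, tol,
                     dt)
      state <- res$state
      if (inh > 0) {
        gait <- if (res$status %in% c("converged", "timeout") &&
                    !anyNA(res$phase))
          classifyGait(res$phase) else res$status
        rows[[length(rows) + 1]] <-
          data.frame(ex = ex, inh = inh, freq = res$freq,
                     status = res$status, gait = gait,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Connection-weight robustness study
#'
#' For each perturbation level \code{sigmaP}, builds randomized copies of
#' the network (\code{\link{perturbWeights}}), runs the CnF-Glu continuation
#' sweep on each, and classifies every model: \emph{retains-all-gaits} if
#' all four gaits appear among converged steps of the up branch,
#' \emph{loses-gaits} if stable but missing some gait, \emph{unstable} if
#' integration fails or more than 5\% of steps neither converge nor
#' classify as quiescent while showing non-periodic phase differences.
#'
#' @param net the baseline \code{\link{Network}}.
#' @param sigmaP vector of perturbation SDs.
#' @param nModels randomized models per level.
#' @param seed root seed; model seeds are derived deterministically.
#' @param m,b CnF stimulation drive law.
#' @param nSteps sweep resolution per model (reduced resolution is
#'   recorded in the output).
#' @param chunk,cap,tol,dt settling controls (defaults reduced for
#'   many-model studies).
#' @param upOnly if \code{TRUE} (default) classify from the up branch only.
#' @return list with \code{summary} (per-sigmaP fractions) and
#'   \code{models} (per-model classification), plus the resolution used.
#' @export
robustnessSuite <- function(net, sigmaP = seq(0.02, 0.2, by = 0.02),
                            nModels = 100, seed = 1, m = 1.35, b = 3.95,
                            nSteps = 40, chunk = 5000, cap = 40000,
                            tol = 0.001, dt = 0.1, upOnly = TRUE) {
  classify <- function(bd) {
    tabs <- if (upOnly) list(bd@up) else list(bd@up, bd@down)
    tab <- do.call(rbind, tabs)
    bad <- tab$status == "timeout" &
      (!is.finite(tab$maxSD) | tab$maxSD > 0.1)
    if (any(tab$status == "blowup") || mean(bad) > 0.05)
      return("unstable")
    g <- unique(tab$gait[tab$status == "converged"])
    if (all(c("walk", "trot", "gallop", "bound") %in% g))
      "retains-all-gaits" else "loses-gaits"
  }
  models <- list()
  for (sp in sigmaP) {
    for (i in seq_len(nModels)) {
      mseed <- (seed * 1009L + round(sp * 1000) * 101L + i) %% .Machine$integer.max
      pnet <- perturbWeights(net, sp, seed = mseed)
      bd <- try(bifurcationSweep(pnet, "CnF-Glu", "l", m = m, b = b,
                                 nSteps = nSteps, chunk = chunk, cap = cap,
                                 tol = tol, dt = dt), silent = TRUE)
      cls <- if (inherits(bd, "try-error")) "unstable" else classify(bd)
      models[[length(models) + 1]] <-
        data.frame(sigmaP = sp, model = i, seed = mseed, class = cls,
                   stringsAsFactors = FALSE)
    }
  }
  models <- do.call(rbind, models)
  summ <- do.call(rbind, lapply(split(models, models$sigmaP), function(d) {
    data.frame(sigmaP = d$sigmaP[1],
               retainsAll = mean(d$class == "retains-all-gaits"),
               losesGaits = mean(d$class == "loses-gaits"),
               unstable = mean(d$class == "unstable"),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(summary = summ, models = models, nSteps = nSteps, cap = cap)
}

# Single isolated flexor center under direct conductance drive.
.isolatedRG <- function(napOverride = list()) {
  d <- .cellDefaults("RG-F", "spinal-hind")
  p <- modifyList(defaultNapParams(), napOverride)
  pops <- data.frame(
    id = "RG:l", name = "RG-F", side = "l", girdle = NA_character_,
    compartment = "fixture", dynamics = "nap", transmitter = "exc",
    C = d$C, gL = d$gL, EL = d$EL, Vthr = d$Vthr, Vmax = d$Vmax,
    gNaP = p$gNaP, ENa = p$ENa, Vm = p$Vm, km = p$km, Vh = p$Vh,
    kh = p$kh, tauMax = p$tauMax, driveGain = 1, sigmaNoise = 0,
    tauNoise = 10, stringsAsFactors = FALSE)
  new("Network", populations = pops,
      connections = data.frame(source = character(), target = character(),
                               weight = numeric(), printed = numeric(),
                               stringsAsFactors = FALSE),
      drives = data.frame(target = character(), value = numeric(),
                          stringsAsFactors = FALSE),
      synapse = list(EsynE = -10, EsynI = -75, gE = 1, gI = 1, gD = 1))
}

# Frequency of the isolated center at one drive (NA if quiescent/tonic).
.rgFrequency <- function(net, drive, duration = 5000, dt = 0.1) {
  cn <- .compileNetwork(net, c("RG:l" = drive))
  out <- cpp_simulate(cn, .initialState(net), duration, dt, 1, 0L, FALSE)
  sel <- out$time > duration * 0.3
  f <- out$f[sel, 1]
  on <- detectOnsets(f, out$time[sel])
  if (length(on) < 4 || diff(range(f)) < 0.3) return(NA_real_)
  1000 / mean(diff(on))
}

#' Calibrate the isolated rhythm-generator center
#'
#' Grid search over the persistent-sodium conductance and the inactivation
#' time-constant scale so that the frequency-drive curve of an isolated
#' flexor center is monotonically increasing and spans the target frequency
#' range over the operational drive range. The best parameter set (smallest
#' deviation of the curve's endpoints from the target) is returned together
#' with the realized curve.
#'
#' @param targetRange frequency interval (Hz) the curve should span; must
#'   lie within (0, 20].
#' @param driveRange operational drive (conductance, nS) interval.
#' @param gNaPGrid,tauGrid candidate values searched.
#' @param nDrive number of drive points per candidate curve.
#' @param endTol acceptance tolerance (Hz) at the interval ends.
#' @return list with \code{success}, \code{params} (full persistent-sodium
#'   parameter list), \code{curve} (drive, freq), \code{span} and
#'   \code{message}.
#' @export
calibrateRGCenter <- function(targetRange = c(3, 10.5),
                              driveRange = c(0.2, 1.5),
                              gNaPGrid = c(12, 14, 16),
                              tauGrid = c(180, 250, 320, 420),
                              nDrive = 9, endTol = 0.5) {
  if (targetRange[1] <= 0 || targetRange[2] > 20 ||
      targetRange[1] >= targetRange[2])
    stop("target range must be an increasing interval within (0, 20] Hz")
  dr <- seq(driveRange[1], driveRange[2], length.out = nDrive)
  best <- NULL
  for (g in gNaPGrid) for (tm in tauGrid) {
    net <- .isolatedRG(list(gNaP = g, tauMax = tm))
    fr <- vapply(dr, function(d) .rgFrequency(net, d), numeric(1))
    if (anyNA(fr)) next
    if (any(diff(fr) < -0.1)) next   # monotone up to numerical ripple
    dev <- abs(fr[1] - targetRange[1]) + abs(fr[nDrive] - targetRange[2])
    if (is.null(best) || dev < best$dev)
      best <- list(gNaP = g, tauMax = tm, curve = data.frame(drive = dr,
                   freq = fr), dev = dev)
  }
  if (is.null(best) ||
      abs(best$curve$freq[1] - targetRange[1]) > endTol ||
      abs(best$curve$freq[nDrive] - targetRange[2]) > endTol)
    return(list(success = FALSE, params = NULL,
                curve = if (is.null(best)) NULL else best$curve,
                span = if (is.null(best)) NULL else range(best$curve$freq),
                message = paste("calibration failure: no parameter set",
                                "spans the target range")))
  params <- modifyList(defaultNapParams(),
                       list(gNaP = best$gNaP, tauMax = best$tauMax))
  list(success = TRUE, params = params, curve = best$curve,
       span = range(best$curve$freq), message = "ok")
}
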