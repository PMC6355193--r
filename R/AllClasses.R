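#' @import methods
#' @importFrom stats rnorm sd setNames approx
#' @importFrom utils write.table read.delim head tail modifyList
NULL

#' Network of neural populations
#'
#' An S4 container for a bilateral brainstem-spinal locomotor network: a
#' roster of neural populations (each a rate-model unit, optionally with
#' persistent-sodium slow kinetics), a list of signed weighted connections,
#' constant tonic drives, and the global synaptic parameters shared by all
#' populations.
#'
#' @slot populations \code{data.frame} with one row per population: columns
#'   \code{id}, \code{name}, \code{side} (\code{"l"}/\code{"r"}),
#'   \code{girdle} (\code{"fore"}, \code{"hind"} or \code{NA} for brainstem),
#'   \code{compartment}, \code{dynamics} (\code{"nap"} or \code{"plain"}),
#'   \code{transmitter} (\code{"exc"}/\code{"inh"}), membrane parameters
#'   \code{C} (pF), \code{gL} (nS), \code{EL} (mV), output-function corners
#'   \code{Vthr}, \code{Vmax} (mV), persistent-sodium parameters
#'   (\code{gNaP}, \code{ENa}, \code{Vm}, \code{km}, \code{Vh}, \code{kh},
#'   \code{tauMax}; \code{NA} for plain populations), a per-population
#'   drive gain \code{driveGain} (multiplies the global drive conductance
#'   scale), and noise parameters \code{sigmaNoise} (pA), \code{tauNoise}
#'   (ms).
#' @slot connections \code{data.frame} with columns \code{source},
#'   \code{target} (population ids), \code{weight} (signed effective weight)
#'   and \code{printed} (the magnitude as printed in the source connection
#'   table, kept for round-trip checks).
#' @slot drives \code{data.frame} of constant tonic drives: columns
#'   \code{target} (population id) and \code{value} (dimensionless).
#' @slot synapse named list of global synaptic parameters: reversal
#'   potentials \code{EsynE}, \code{EsynI} (mV) and conductance scale
#'   factors \code{gE}, \code{gI} (nS per unit weighted activity) and
#'   \code{gD} (nS per unit drive).
#'
#' @seealso \code{\link{buildDefaultNetwork}}, \code{\link{validateNetwork}},
#'   \code{\link{applyLesion}}, \code{\link{perturbWeights}}
#' @export
setClass("Network", representation(
  populations = "data.frame",
  connections = "data.frame",
  drives = "data.frame",
  synapse = "list"
))

setValidity("Network", function(object) {
  msg <- character()
  pops <- object@populations
  need <- c("id", "name", "side", "girdle", "compartment", "dynamics",
            "transmitter", "C", "gL", "EL", "Vthr", "Vmax",
            "gNaP", "ENa", "Vm", "km", "Vh", "kh", "tauMax",
            "driveGain", "sigmaNoise", "tauNoise")
  miss <- setdiff(need, names(pops))
  if (length(miss))
    msg <- c(msg, paste("populations lacks columns:", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(pops$id)) msg <- c(msg, "duplicate population ids")
    if (any(pops$C <= 0) || any(pops$gL <= 0))
      msg <- c(msg, "C and gL must be positive")
    if (any(pops$Vmax <= pops$Vthr))
      msg <- c(msg, "Vmax must exceed Vthr")
    if (any(pops$sigmaNoise < 0) || any(pops$tauNoise <= 0))
      msg <- c(msg, "sigmaNoise must be >= 0 and tauNoise > 0")
    nap <- pops$dynamics == "nap"
    if (any(nap & !is.finite(pops$gNaP)))
      msg <- c(msg, "nap populations need persistent-sodium parameters")
    if (any(!nap & is.finite(pops$gNaP)))
      msg <- c(msg, "plain populations must not carry persistent-sodium parameters")
    conn <- object@connections
    bad <- setdiff(c(conn$source, conn$target, object@drives$target), pops$id)
    if (length(bad))
      msg <- c(msg, paste("dangling population ids:", paste(unique(bad), collapse = ", ")))
    syn <- object@synapse
    if (!all(c("EsynE", "EsynI", "gE", "gI", "gD") %in% names(syn)))
      msg <- c(msg, "synapse must contain EsynE, EsynI, gE, gI, gD")
    else {
      if (syn$EsynE <= syn$EsynI) msg <- c(msg, "EsynE must exceed EsynI")
      if (any(unlist(syn[c("gE", "gI", "gD")]) < 0))
        msg <- c(msg, "conductance scale factors must be >= 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Stimulation and simulation protocol
#'
#' Describes one simulation run: which populations receive the variable
#' stimulation drive (linear law \eqn{D(\alpha) = m\alpha + b}), any extra
#' fixed drives, lesioned regions, the noise level, duration, integration
#' step and random seed.
#'
#' @slot stimulations \code{data.frame} with columns \code{target}
#'   (population id), \code{m}, \code{b} (drive-law slope and intercept).
#' @slot alpha normalized stimulation strength in \eqn{[0, 1.05]} applied to
#'   all rows of \code{stimulations}.
#' @slot fixedDrives \code{data.frame} with columns \code{target} and
#'   \code{value}: drives applied at a fixed strength.
#' @slot lesions character vector of region names passed to
#'   \code{\link{applyLesion}} before simulation.
#' @slot sigmaNoise noise-current stationary standard deviation (pA) applied
#'   to every population, or \code{NA} to keep each population's own value.
#' @slot duration run length (ms).
#' @slot dt integration step (ms).
#' @slot seed integer random seed (used when \code{sigmaNoise > 0}).
#' @seealso \code{\link{simulateNetwork}}
#' @export
setClass("Protocol", representation(
  stimulations = "data.frame",
  alpha = "numeric",
  fixedDrives = "data.frame",
  lesions = "character",
  sigmaNoise = "numeric",
  duration = "numeric",
  dt = "numeric",
  seed = "numeric"
))

setValidity("Protocol", function(object) {
  msg <- character()
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (length(object@alpha) != 1 || !is.finite(object@alpha))
    msg <- c(msg, "alpha must be a single finite number")
  else if (object@alpha < 0 || object@alpha > 1.05)
    msg <- c(msg, "alpha outside the operational range [0, 1.05]")
  if (length(msg)) msg else TRUE
})

#' Simulation result
#'
#' Time grid plus per-population membrane potential and output activity
#' traces for the recorded populations, the final full network state (for
#' warm-starting continuation runs) and an echo of the protocol.
#'
#' @slot time sampled time points (ms).
#' @slot V matrix (time x recorded populations) of membrane potentials (mV).
#' @slot f matrix of output activities \eqn{f(V) \in [0, 1]}.
#' @slot finalState full state vector (all V, h, noise) at the end of the run.
#' @slot protocol the \code{\link{Protocol}} that produced the run.
#' @slot blewUp logical; \code{TRUE} if integration failed (|V| > 200 mV or
#'   non-finite state), with \code{blewAt} the failure time (ms).
#' @slot blewAt failure time stamp (ms) or \code{NA}.
#' @export
setClass("SimulationResult", representation(
  time = "numeric",
  V = "matrix",
  f = "matrix",
  finalState = "numeric",
  protocol = "Protocol",
  blewUp = "logical",
  blewAt = "numeric"
))

#' Bifurcation diagram from a continuation sweep
#'
#' Converged oscillation frequency and the four normalized inter-limb phase
#' differences at each stimulation strength \eqn{\alpha}, separately for the
#' increasing (up) and decreasing (down) continuation branches, so that
#' bistability (hysteresis) regions are exposed where the branches differ.
#'
#' @slot up,down \code{data.frame}s with columns \code{alpha},
#'   \code{freq} (Hz), \code{hindLR}, \code{foreLR}, \code{homolateral},
#'   \code{diagonal} (phase differences in \eqn{[0, 1)}), \code{status}
#'   (\code{"converged"}, \code{"timeout"} or \code{"quiescent"}) and
#'   \code{gait}.
#' @slot stimulation \code{data.frame} echo of the swept drive law.
#' @export
setClass("BifurcationDiagram", representation(
  up = "data.frame",
  down = "data.frame",
  stimulation = "data.frame"
))
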