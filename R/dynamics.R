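#' Piecewise-linear population output function
#'
#' Translates the average membrane potential of a population into its
#' integrated output activity: zero below the threshold \code{Vthr}, one at
#' or above saturation \code{Vmax}, and linear in between.
#'
#' @param V membrane potential (mV); vectorized.
#' @param Vthr output threshold (mV).
#' @param Vmax output saturation (mV); must exceed \code{Vthr}.
#' @return activity in \eqn{[0, 1]}.
#' @examples
#' outputActivity(c(-60, -25, 0), Vthr = -50, Vmax = 0)
#' @export
outputActivity <- function(V, Vthr = -50, Vmax = 0) {
  if (any(Vmax <= Vthr))
    stop("invalid output function: Vmax must exceed Vthr")
  pmin(1, pmax(0, (V - Vthr) / (Vmax - Vthr)))
}

#' Linear stimulation drive law
#'
#' The tonic drive applied to a stimulated population as a function of the
#' normalized stimulation strength \eqn{\alpha}: \eqn{D(\alpha) = m\alpha + b}.
#'
#' @param alpha stimulation strength; the operational range is
#'   \eqn{[0, 1.05]} but the law itself is evaluable everywhere.
#' @param m slope (drive units per unit \eqn{\alpha}).
#' @param b intercept (drive units).
#' @return dimensionless drive strength.
#' @examples
#' driveStrength(0, m = 1.35, b = 3.95)
#' @export
driveStrength <- function(alpha, m, b) m * alpha + b

#' Default persistent-sodium kinetics for rhythm-generator centers
#'
#' The intrinsic oscillatory mechanism of the flexor and extensor
#' rhythm-generating centers is a persistent sodium current
#' \eqn{I_{NaP} = g_{NaP} m_\infty(V) h (V - E_{Na})} with instantaneous
#' sigmoidal activation and slow sigmoidal inactivation \eqn{h}. The
#' constants here are calibrated so that an isolated flexor center sweeps
#' roughly 2-12 Hz over its operational excitatory-conductance range (see
#' the methods vignette); they are package calibration choices, not
#' measurements.
#'
#' @return named list: \code{gNaP} (nS), \code{ENa} (mV), activation
#'   half-voltage \code{Vm} and slope \code{km} (mV, negative), inactivation
#'   half-voltage \code{Vh} and slope \code{kh} (mV, positive), inactivation
#'   time-constant scale \code{tauMax} (ms).
#' @export
defaultNapParams <- function() {
  list(gNaP = 14, ENa = 50, Vm = -32, km = -6, Vh = -44, kh = 5,
       tauMax = 250)
}

#' Default global synaptic parameters
#'
#' Conductance-based synapses: excitatory reversal \code{EsynE}, inhibitory
#' reversal \code{EsynI}, and the scale factors translating weighted
#' presynaptic activity (\code{gE}, \code{gI}) and tonic drive (\code{gD})
#' into conductances.
#'
#' @return named list with elements \code{EsynE}, \code{EsynI} (mV) and
#'   \code{gE}, \code{gI}, \code{gD} (nS per unit).
#' @export
defaultSynapseParams <- function() {
  list(EsynE = -10, EsynI = -75, gE = 10, gI = 30, gD = 0.18)
}

#' Persistent-sodium current and inactivation kinetics
#'
#' @param V membrane potential (mV).
#' @param h inactivation gate in \eqn{[0, 1]}.
#' @param params list as returned by \code{\link{defaultNapParams}}.
#' @return list with \code{INaP} (pA), \code{dh} (1/ms), and the underlying
#'   \code{minf}, \code{hinf}, \code{tauh}.
#' @export
napKinetics <- function(V, h, params = defaultNapParams()) {
  if (any(h < 0 | h > 1)) stop("state corruption: h outside [0, 1]")
  minf <- 1 / (1 + exp((V - params$Vm) / params$km))
  hinf <- 1 / (1 + exp((V - params$Vh) / params$kh))
  tauh <- params$tauMax / cosh((V - params$Vh) / (2 * params$kh))
  list(INaP = params$gNaP * minf * h * (V - params$ENa),
       dh = (hinf - h) / tauh, minf = minf, hinf = hinf, tauh = tauh)
}

#' Leak and synaptic currents of one population
#'
#' Conductance-based currents: the leak \eqn{I_L = g_L (V - E_L)}, the
#' excitatory synaptic current driven by summed weighted presynaptic
#' activity plus tonic drive, and the inhibitory synaptic current driven by
#' the summed magnitudes of inhibitory inputs.
#'
#' @param V membrane potential (mV).
#' @param gL leak conductance (nS); \code{EL} leak reversal (mV).
#' @param EL leak reversal potential (mV).
#' @param syn global synaptic parameters (\code{\link{defaultSynapseParams}}).
#' @param excInput summed weight x activity over excitatory afferents (>= 0).
#' @param inhInput summed |weight| x activity over inhibitory afferents (>= 0).
#' @param drive summed tonic drive (dimensionless, >= 0 after clamping).
#' @return named numeric vector \code{c(IL, ISynE, ISynI)} in pA.
#' @export
evaluateCurrents <- function(V, gL, EL, syn = defaultSynapseParams(),
                             excInput = 0, inhInput = 0, drive = 0) {
  if (excInput < 0 || inhInput < 0)
    stop("contract violation: weighted synaptic inputs must be non-negative")
  gExc <- syn$gE * excInput + syn$gD * max(drive, 0)
  gInh <- syn$gI * inhInput
  c(IL = gL * (V - EL),
    ISynE = gExc * (V - syn$EsynE),
    ISynI = gInh * (V - syn$EsynI))
}

#' One Euler-Maruyama step of the Ornstein-Uhlenbeck noise current
#'
#' The noisy current of each population follows an Ornstein-Uhlenbeck
#' process with relaxation time \code{tau} and stationary standard deviation
#' \code{sigma}. Draws come from R's RNG, so \code{set.seed} makes the
#' sequence reproducible.
#'
#' @param noise current value (pA); vectorized.
#' @param dt step (ms); \code{tau} relaxation time (ms).
#' @param sigma stationary standard deviation (pA); 0 gives deterministic
#'   decay toward 0.
#' @param tau relaxation time constant (ms).
#' @return updated noise current (pA).
#' @export
noiseStep <- function(noise, dt, sigma, tau = 10) {
  if (dt <= 0 || tau <= 0) stop("dt and tau must be positive")
  out <- noise - noise * dt / tau
  if (any(sigma > 0))
    out <- out + sigma * sqrt(2 * dt / tau) * rnorm(length(out))
  out
}

# Flatten a Network plus per-population drives into the list consumed by the
# compiled stepper. `drives` is a named vector of total dimensionless drive
# per population id (missing -> 0); conductance scales are folded in here so
# the C++ core only sees effective conductances.
.compileNetwork <- function(net, drives = numeric(), sigmaNoise = NA_real_) {
  pops <- net@populations
  syn <- net@synapse
  idx <- setNames(seq_len(nrow(pops)), pops$id)
  dr <- numeric(nrow(pops))
  if (length(drives)) {
    bad <- setdiff(names(drives), pops$id)
    if (length(bad)) stop("unknown drive targets: ", paste(bad, collapse = ", "))
    dr[idx[names(drives)]] <- pmax(unlist(drives), 0)
  }
  conn <- net@connections
  w <- ifelse(conn$weight >= 0, syn$gE * conn$weight, syn$gI * conn$weight)
  sig <- if (is.finite(sigmaNoise)) rep(sigmaNoise, nrow(pops)) else pops$sigmaNoise
  isnap <- pops$dynamics == "nap"
  num0 <- function(x) ifelse(is.finite(x), x, 0)
  list(n = nrow(pops),
       C = pops$C, gL = pops$gL, EL = pops$EL,
       Vthr = pops$Vthr, Vmax = pops$Vmax,
       isnap = isnap,
       gNaP = num0(pops$gNaP), ENa = num0(pops$ENa),
       Vm = num0(pops$Vm), km = ifelse(is.finite(pops$km), pops$km, -1),
       Vh = num0(pops$Vh), kh = ifelse(is.finite(pops$kh), pops$kh, 1),
       tauMax = ifelse(is.finite(pops$tauMax), pops$tauMax, 1),
       csrc = idx[conn$source] - 1L, ctgt = idx[conn$target] - 1L,
       cw = w,
       gdrive = syn$gD * dr * pops$driveGain,
       EsynE = syn$EsynE, EsynI = syn$EsynI,
       sigma = sig, tauNoise = pops$tauNoise)
}

#' Network state derivative (reference implementation)
#'
#' Computes the time derivatives of all membrane potentials and
#' persistent-sodium inactivation gates from the current network state, with
#' noise currents held at their instantaneous values. This is a plain-R
#' reference of the same dynamical laws used by the compiled integrator and
#' is intended for testing and for integration with external ODE solvers.
#'
#' @param net a \code{\link{Network}}.
#' @param state numeric vector \code{c(V, h, noise)} of length 3n in the
#'   population order of \code{populations(net)} (\code{h} entries are
#'   ignored for plain populations).
#' @param drives named numeric vector of total tonic drive per population id.
#' @return numeric vector \code{c(dV, dh)} of length 2n (units mV/ms, 1/ms).
#' @export
stateDerivative <- function(net, state, drives = numeric()) {
  pops <- net@populations
  n <- nrow(pops)
  if (length(state) != 3 * n)
    stop("state length must be 3 x number of populations")
  V <- state[seq_len(n)]
  if (any(!is.finite(V))) {
    bad <- pops$id[!is.finite(V)]
    stop("integration failure: non-finite V in ", paste(bad, collapse = ", "))
  }
  h <- state[n + seq_len(n)]
  nz <- state[2 * n + seq_len(n)]
  syn <- net@synapse
  f <- outputActivity(V, pops$Vthr, pops$Vmax)
  # sloppy-but-clear: accumulate conductances connection by connection
  idx <- setNames(seq_len(n), pops$id)
  gE <- numeric(n); gI <- numeric(n)
  conn <- net@connections
  for (k in seq_len(nrow(conn))) {
    s <- idx[[conn$source[k]]]; t <- idx[[conn$target[k]]]
    if (conn$weight[k] >= 0) gE[t] <- gE[t] + syn$gE * conn$weight[k] * f[s]
    else gI[t] <- gI[t] - syn$gI * conn$weight[k] * f[s]
  }
  if (length(drives)) {
    j <- idx[names(drives)]
    gE[j] <- gE[j] + syn$gD * pmax(unlist(drives), 0) * pops$driveGain[j]
  }
  dV <- numeric(n); dh <- numeric(n)
  for (i in seq_len(n)) {
    I <- pops$gL[i] * (V[i] - pops$EL[i]) +
      gE[i] * (V[i] - syn$EsynE) + gI[i] * (V[i] - syn$EsynI) + nz[i]
    if (pops$dynamics[i] == "nap") {
      kin <- napKinetics(V[i], h[i], list(
        gNaP = pops$gNaP[i], ENa = pops$ENa[i], Vm = pops$Vm[i],
        km = pops$km[i], Vh = pops$Vh[i], kh = pops$kh[i],
        tauMax = pops$tauMax[i]))
      I <- I + kin$INaP
      dh[i] <- kin$dh
    }
    dV[i] <- -I / pops$C[i]
  }
  c(dV, dh)
}

# Resting initial state: V = EL plus a small graded offset that breaks the
# exact left-right (and fore-hind) permutation symmetry of the network --
# from perfectly symmetric initial conditions the dynamics would stay on
# the symmetric manifold forever, even where it is unstable. h = hinf(V),
# noise = 0.
.initialState <- function(net) {
  pops <- net@populations
  n <- nrow(pops)
  V <- pops$EL + 0.01 * seq_len(n)
  h <- numeric(n)
  nap <- pops$dynamics == "nap"
  h[nap] <- 1 / (1 + exp((V[nap] - pops$Vh[nap]) / pops$kh[nap]))
  c(V, h, numeric(n))
}
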