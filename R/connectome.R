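#' @include AllClasses.R dynamics.R
NULL

# Population name sets. Transmitter type decides the sign every outgoing
# connection must carry; the inhibitory relay dIni and the brainstem
# GABA/glycine populations are inhibitory, everything else glutamatergic /
# excitatory. "Inh" is the package's short name for the GABA/Gly populations.
.EXC_POPS <- c("CnF-Glu", "PPN-Glu", "LPGi-Glu-1", "LPGi-Glu-2", "VN",
               "Ine", "CINe", "RG-F", "RG-E", "V0V", "V3", "V2a-lr",
               "V2a-diag", "Sh2-LPN", "V0V-LPN")
.INH_POPS <- c("CnF-Inh", "PPN-Inh", "LPGi-Inh", "dIni", "InF", "InE",
               "Ini", "V0D", "CINi", "LPNi", "V0D-LPN")

# Aliases accepted wherever a population name is taken from user input.
.POP_ALIASES <- c(
  "CnF-GABA/Gly" = "CnF-Inh", "PPN-GABA/Gly" = "PPN-Inh",
  "LPGi-GABA/Gly" = "LPGi-Inh",
  "CnF-GABA" = "CnF-Inh", "PPN-GABA" = "PPN-Inh", "LPGi-GABA" = "LPGi-Inh",
  "V0_D" = "V0D", "V0_V" = "V0V", "V0_D-LPN" = "V0D-LPN",
  "V0_V-LPN" = "V0V-LPN")

.canonName <- function(x) {
  i <- match(x, names(.POP_ALIASES))
  ifelse(is.na(i), x, .POP_ALIASES[i])
}

.popId <- function(name, side, girdle = NA_character_) {
  ifelse(is.na(girdle), paste(name, side, sep = ":"),
         paste(name, side, girdle, sep = ":"))
}

# Membrane parameter defaults by tier. The rhythm-generator centers carry
# the persistent-sodium current; brainstem and relay populations have
# gL = 5 nS; remaining spinal interneurons use the lineage convention of a
# smaller leak. All outputs use the same piecewise-linear corners.
#
# Resting potentials are tiered (a package calibration choice; see the
# methods vignette): brainstem and relay populations rest just below the
# output threshold so the descending command cascade operates in its
# sensitive near-threshold range; the vestibular population rests above
# threshold (tonically active); the gait relay dIni rests lower so that it
# is recruited only at higher stimulation strengths, which is what staggers
# the suppression of the V0 commissural pathways and hence the gait
# transitions; spinal interneurons use the standard -60 mV.
.cellDefaults <- function(name, compartment) {
  nap <- name %in% c("RG-F", "RG-E")
  p <- defaultNapParams()
  brainstem <- compartment %in% c("CnF", "PPN", "LPGi", "VN", "relay")
  EL <- if (nap) -62.5
  else if (name == "VN") -42
  else if (name == "dIni") -54
  else if (brainstem) -52
  else -60
  list(dynamics = if (nap) "nap" else "plain",
       C = 10,
       gL = if (nap) 4.5 else if (brainstem) 5 else 2.8,
       EL = EL,
       Vthr = -50, Vmax = 0,
       gNaP = if (nap) p$gNaP else NA_real_,
       ENa = if (nap) p$ENa else NA_real_,
       Vm = if (nap) p$Vm else NA_real_,
       km = if (nap) p$km else NA_real_,
       Vh = if (nap) p$Vh else NA_real_,
       kh = if (nap) p$kh else NA_real_,
       tauMax = if (nap) p$tauMax else NA_real_,
       driveGain = if (name == "LPGi-Glu-2") 1.2
       else if (name == "LPGi-Inh") 1.3
       else if (compartment == "LPGi") 2.4 else 1,
       sigmaNoise = 0.005, tauNoise = 10)
}

.makePopulations <- function() {
  rows <- list()
  add <- function(name, side, girdle, compartment) {
    d <- .cellDefaults(name, compartment)
    rows[[length(rows) + 1]] <<- data.frame(
      id = .popId(name, side, girdle), name = name, side = side,
      girdle = girdle, compartment = compartment,
      dynamics = d$dynamics,
      transmitter = if (name %in% .INH_POPS) "inh" else "exc",
      C = d$C, gL = d$gL, EL = d$EL, Vthr = d$Vthr, Vmax = d$Vmax,
      gNaP = d$gNaP, ENa = d$ENa, Vm = d$Vm, km = d$km, Vh = d$Vh,
      kh = d$kh, tauMax = d$tauMax, driveGain = d$driveGain,
      sigmaNoise = d$sigmaNoise, tauNoise = d$tauNoise,
      stringsAsFactors = FALSE)
  }
  for (s in c("l", "r")) {
    add("CnF-Glu", s, NA, "CnF"); add("CnF-Inh", s, NA, "CnF")
    add("PPN-Glu", s, NA, "PPN"); add("PPN-Inh", s, NA, "PPN")
    add("LPGi-Glu-1", s, NA, "LPGi"); add("LPGi-Glu-2", s, NA, "LPGi")
    add("LPGi-Inh", s, NA, "LPGi")
    add("VN", s, NA, "VN")
    for (g in c("fore", "hind")) {
      add("Ine", s, g, "relay"); add("CINe", s, g, "relay")
      add("dIni", s, g, "relay")
      comp <- paste0("spinal-", g)
      for (nm in c("RG-F", "RG-E", "InF", "InE", "V0D", "V0V", "V3",
                   "CINi", "Ini", "V2a-lr", "V2a-diag"))
        add(nm, s, g, comp)
      add("Sh2-LPN", s, g, comp)
      add("V0V-LPN", s, g, comp)
      if (g == "fore") { add("LPNi", s, g, comp); add("V0D-LPN", s, g, comp) }
    }
  }
  do.call(rbind, rows)
}

.makeConnections <- function() {
  src <- character(); tgt <- character(); w <- numeric(); pr <- numeric()
  add <- function(s, t, weight, printed = abs(weight)) {
    src <<- c(src, s); tgt <<- c(tgt, t); w <<- c(w, weight)
    pr <<- c(pr, printed)
  }
  for (s in c("l", "r")) {
    o <- if (s == "l") "r" else "l"
    bs <- function(nm, side) .popId(nm, side)
    sp <- function(nm, side, g) .popId(nm, side, g)
    # within brainstem
    add(bs("CnF-Glu", s), bs("PPN-Glu", s), 0.56)
    add(bs("CnF-Glu", s), bs("LPGi-Glu-1", s), 0.95)
    add(bs("CnF-Glu", s), bs("LPGi-Glu-2", s), 1.02)
    add(bs("CnF-Glu", s), bs("CnF-Glu", o), 0.1)
    add(bs("CnF-Glu", s), bs("PPN-Glu", o), 0.15)
    add(bs("CnF-Glu", s), bs("LPGi-Glu-1", o), 0.45)
    add(bs("CnF-Glu", s), bs("LPGi-Glu-2", o), 0.08)
    add(bs("CnF-Inh", s), bs("CnF-Glu", s), -0.5)
    add(bs("CnF-Inh", s), bs("PPN-Glu", s), -0.5)
    add(bs("PPN-Glu", s), bs("LPGi-Glu-1", s), 1)
    add(bs("PPN-Glu", s), bs("LPGi-Glu-1", o), 0.4)
    add(bs("PPN-Inh", s), bs("PPN-Glu", s), -0.5)
    add(bs("LPGi-Inh", s), bs("LPGi-Glu-1", s), -0.5)
    add(bs("LPGi-Inh", s), bs("LPGi-Glu-2", s), -0.5)
    # vestibular input to the extensor centers
    for (g in c("fore", "hind")) add(bs("VN", s), sp("RG-E", s, g), 1)
    # brainstem to relay populations (cervical and lumbar copies)
    for (g in c("fore", "hind")) {
      add(bs("LPGi-Glu-1", s), sp("Ine", s, g), 1)
      add(bs("LPGi-Glu-1", s), sp("CINe", s, g), 1)
      add(bs("LPGi-Glu-2", s), sp("dIni", s, g), 1)
      add(bs("LPGi-Glu-2", s), sp("dIni", o, g), 1)
      add(bs("LPGi-Inh", s), sp("Ine", o, g), -0.5)
      add(bs("LPGi-Inh", s), sp("CINe", o, g), -0.5)
    }
    # relay to spinal circuits; the inhibitory relay weights are printed as
    # magnitudes in the source table and realized here with their
    # inhibitory sign
    for (g in c("fore", "hind")) {
      add(sp("Ine", s, g), sp("RG-F", s, g), 1)
      add(sp("CINe", s, g), sp("RG-F", o, g), 1)
      add(sp("dIni", s, g), sp("V0D", s, g), -4, printed = 4)
      add(sp("dIni", s, g), sp("V0V", s, g), -1.7, printed = 1.7)
    }
    add(sp("dIni", s, "fore"), sp("V0D-LPN", s, "fore"), -7.5, printed = 7.5)
    # within girdle and side
    for (g in c("fore", "hind")) {
      add(sp("RG-F", s, g), sp("InF", s, g), 0.4)
      add(sp("RG-F", s, g), sp("V0D", s, g), 0.7)
      add(sp("RG-F", s, g), sp("V2a-lr", s, g), 1)
      add(sp("RG-F", s, g), sp("V3", s, g), 0.35)
      add(sp("RG-F", s, g), sp("V2a-diag", s, g), 0.5)
      add(sp("RG-E", s, g), sp("InE", s, g), 0.4)
      add(sp("RG-E", s, g), sp("CINi", s, g), 0.4)
      add(sp("RG-E", s, g), sp("Sh2-LPN", s, g), 0.5)
      add(sp("InF", s, g), sp("RG-E", s, g), -1)
      add(sp("InE", s, g), sp("RG-F", s, g), -0.08)
      add(sp("V2a-lr", s, g), sp("V0V", s, g), 1)
      add(sp("V2a-diag", s, g), sp("V0V-LPN", s, g), 0.9)
      add(sp("Ini", s, g), sp("RG-F", s, g), -0.075)
      # commissural connections within the girdle
      add(sp("V0D", s, g), sp("RG-F", o, g), -0.07)
      add(sp("V0V", s, g), sp("Ini", o, g), 0.6)
      add(sp("V3", s, g), sp("RG-F", o, g), 0.03)
      add(sp("CINi", s, g), sp("RG-F", o, g), -0.03)
    }
    add(sp("RG-F", s, "fore"), sp("LPNi", s, "fore"), 0.7)
    add(sp("RG-F", s, "fore"), sp("V0D-LPN", s, "fore"), 0.5)
    # long propriospinal pathways between girdles
    add(sp("LPNi", s, "fore"), sp("RG-F", s, "hind"), -0.01)
    add(sp("Sh2-LPN", s, "fore"), sp("RG-F", s, "hind"), 0.01)
    add(sp("Sh2-LPN", s, "hind"), sp("RG-F", s, "fore"), 0.075)
    add(sp("V0D-LPN", s, "fore"), sp("RG-F", o, "hind"), -0.1)
    add(sp("V0V-LPN", s, "fore"), sp("RG-F", o, "hind"), 0.02)
    add(sp("V0V-LPN", s, "hind"), sp("RG-F", o, "fore"), 0.065)
  }
  data.frame(source = src, target = tgt, weight = w, printed = pr,
             stringsAsFactors = FALSE)
}

#' Build the default brainstem-spinal locomotor network
#'
#' Constructs the complete bilateral network: cuneiform (CnF) and
#' pedunculopontine (PPN) nuclei and the lateral paragigantocellular nucleus
#' (LPGi) with excitatory and inhibitory populations on each side, the
#' vestibular drive population (VN), the descending relay populations (Ine,
#' CINe, dIni, duplicated for the cervical and lumbar girdles), and per
#' girdle and side the spinal rhythm-generator centers (RG-F, RG-E), their
#' inhibitory partners (InF, InE), commissural interneurons (V0D, V0V, V3,
#' CINi, Ini, V2a relays) and long propriospinal neurons. Every connection
#' carries its published weight on both sides (exact mirror symmetry) and a
#' constant tonic drive of 2.15 is attached to both VN populations to keep
#' the extensor centers tonic.
#'
#' @param synapse global synaptic parameters; see
#'   \code{\link{defaultSynapseParams}}.
#' @return a validated \code{\link{Network}}.
#' @examples
#' net <- buildDefaultNetwork()
#' connectionWeight(net, "CnF-Glu:l", "PPN-Glu:l")
#' @export
buildDefaultNetwork <- function(synapse = defaultSynapseParams()) {
  net <- new("Network",
             populations = .makePopulations(),
             connections = .makeConnections(),
             drives = data.frame(target = c("VN:l", "VN:r"),
                                 value = c(2.15, 2.15),
                                 stringsAsFactors = FALSE),
             synapse = synapse)
  validObject(net)
  net
}

#' Lesion a region by silencing its outgoing connections
#'
#' Returns a copy of the network in which every connection originating from
#' a population of the lesioned region (on the selected sides) has weight 0.
#' All other weights, drives and parameters are untouched; the input network
#' is not modified.
#'
#' @param net a \code{\link{Network}}.
#' @param region character vector of compartment names (e.g. \code{"PPN"})
#'   or population names (e.g. \code{"PPN-Glu"}).
#' @param sides \code{"both"}, \code{"l"} or \code{"r"}.
#' @return the lesioned \code{\link{Network}}.
#' @examples
#' net <- applyLesion(buildDefaultNetwork(), "PPN")
#' @export
applyLesion <- function(net, region, sides = c("both", "l", "r")) {
  sides <- match.arg(sides)
  if (length(region) == 0) return(net)
  region <- .canonName(region)
  pops <- net@populations
  hit <- pops$compartment %in% region | pops$name %in% region
  if (sides != "both") hit <- hit & pops$side == sides
  known <- unique(c(pops$compartment, pops$name))
  bad <- setdiff(region, known)
  if (length(bad))
    stop("unknown region(s): ", paste(bad, collapse = ", "),
         "; valid names include: ", paste(sort(known), collapse = ", "))
  lesioned <- pops$id[hit]
  conn <- net@connections
  conn$weight[conn$source %in% lesioned] <- 0
  net@connections <- conn
  net
}

#' Multiplicative random perturbation of all connection weights
#'
#' Each connection weight is independently multiplied by a normally
#' distributed random number with mean 1 and standard deviation
#' \code{sigmaP}. Multipliers are drawn per connection, so the exact mirror
#' symmetry of the default network is (intentionally) not preserved. Draws
#' that flip a weight's sign are kept as drawn.
#'
#' @param net a \code{\link{Network}}.
#' @param sigmaP standard deviation of the multiplier (>= 0).
#' @param seed integer seed making the perturbation reproducible.
#' @return the perturbed \code{\link{Network}} (input unchanged).
#' @export
perturbWeights <- function(net, sigmaP, seed = 1) {
  if (sigmaP < 0) stop("sigmaP must be >= 0")
  conn <- net@connections
  set.seed(seed)
  conn$weight <- conn$weight * rnorm(nrow(conn), mean = 1, sd = sigmaP)
  net@connections <- conn
  net
}

#' Structural validation of a network
#'
#' Checks the structural rules the default connectome is built to satisfy
#' and returns violations as data rather than raising errors: left/right
#' mirror symmetry of every connection, agreement of each weight's sign with
#' its source population's transmitter type, and absence of dangling
#' population references.
#'
#' @param net a \code{\link{Network}}.
#' @return character vector of violation descriptions; empty if none.
#' @examples
#' validateNetwork(buildDefaultNetwork())
#' @export
validateNetwork <- function(net) {
  out <- character()
  pops <- net@populations
  conn <- net@connections
  bad <- setdiff(c(conn$source, conn$target), pops$id)
  if (length(bad))
    out <- c(out, paste("dangling population reference:", unique(bad)))
  trans <- setNames(pops$transmitter, pops$id)
  sgn <- trans[conn$source]
  viol <- (sgn == "exc" & conn$weight < 0) | (sgn == "inh" & conn$weight > 0)
  viol[is.na(viol)] <- FALSE
  if (any(viol))
    out <- c(out, sprintf("sign violation: %s -> %s (%g)",
                          conn$source[viol], conn$target[viol],
                          conn$weight[viol]))
  # mirror symmetry: swap l <-> r in both endpoints
  swap <- function(id) {
    parts <- strsplit(id, ":", fixed = TRUE)
    vapply(parts, function(p) {
      p[2] <- if (p[2] == "l") "r" else "l"
      paste(p, collapse = ":")
    }, character(1))
  }
  key <- paste(conn$source, conn$target)
  mkey <- paste(swap(conn$source), swap(conn$target))
  m <- match(mkey, key)
  missing <- is.na(m)
  if (any(missing))
    out <- c(out, sprintf("mirror violation: no homolog for %s -> %s",
                          conn$source[missing], conn$target[missing]))
  ok <- !missing
  diffw <- ok & abs(conn$weight - conn$weight[m]) > 1e-12
  if (any(diffw))
    out <- c(out, sprintf("mirror violation: %s -> %s weight differs from homolog",
                          conn$source[diffw], conn$target[diffw]))
  out
}

#' Two-population half-center fixture
#'
#' A minimal test network: two identical persistent-sodium oscillator
#' populations with reciprocal inhibition (weight -0.5 each way) and a
#' shared excitatory drive. With zero drive both populations rest; with
#' mid-range drive (default 0.8, the middle of the center's oscillatory
#' input range) the pair locks into anti-phase oscillation, the canonical
#' half-center rhythm. Excitatory/drive scale factors are 1 so drive is in
#' nS-equivalent units; the inhibitory scale is 2 nS per unit, strong
#' enough for hard alternation across the mid-range.
#'
#' @param drive shared tonic drive (>= 0).
#' @return list with the \code{\link{Network}} (\code{$net}) and the drive
#'   vector (\code{$drives}) to pass to the engine.
#' @export
buildHalfcenterFixture <- function(drive = 0.8) {
  if (drive < 0) stop("drive must be >= 0")
  d <- .cellDefaults("RG-F", "spinal-hind")
  mk <- function(id) data.frame(
    id = id, name = "HC", side = if (id == "HC:l") "l" else "r",
    girdle = NA_character_, compartment = "fixture",
    dynamics = "nap", transmitter = "exc",
    C = d$C, gL = d$gL, EL = d$EL, Vthr = d$Vthr, Vmax = d$Vmax,
    gNaP = d$gNaP, ENa = d$ENa, Vm = d$Vm, km = d$km, Vh = d$Vh,
    kh = d$kh, tauMax = d$tauMax, driveGain = 1, sigmaNoise = 0,
    tauNoise = 10, stringsAsFactors = FALSE)
  pops <- rbind(mk("HC:l"), mk("HC:r"))
  # fixture breaks the transmitter sign rule on purpose (mutual inhibition
  # between two excitatory-output centers stands in for the InF pathway)
  conn <- data.frame(source = c("HC:l", "HC:r"), target = c("HC:r", "HC:l"),
                     weight = c(-0.5, -0.5), printed = c(0.5, 0.5),
                     stringsAsFactors = FALSE)
  net <- new("Network", populations = pops, connections = conn,
             drives = data.frame(target = character(), value = numeric(),
                                 stringsAsFactors = FALSE),
             synapse = list(EsynE = -10, EsynI = -75, gE = 1, gI = 2, gD = 1))
  list(net = net, drives = c("HC:l" = drive, "HC:r" = drive))
}

#' Machine-readable copy of the published connection-weight table
#'
#' Reads the package's transcription of the printed connection table
#' (\code{inst/extdata/table1.tsv}): one row per printed entry with the
#' source population, the target specification in the printed shorthand
#' (\code{i-} ipsilateral, \code{c-} contralateral, \code{f-}/\code{h-}
#' fore/hind girdle restriction) and the printed weight.
#'
#' @return \code{data.frame} with columns \code{section}, \code{source},
#'   \code{target} and \code{weight}.
#' @export
table1Weights <- function() {
  path <- system.file("extdata", "table1.tsv", package = "locomotoR")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Export the connectome as a tab-separated table
#'
#' Writes one row per realized connection (source id, target id, signed
#' effective weight) for diffing against the published table or external
#' editing.
#'
#' @param net a \code{\link{Network}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeConnectomeTSV <- function(net, path) {
  write.table(net@connections[, c("source", "target", "weight")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply connection weights from a tab-separated table
#'
#' Reads a table in the format written by \code{\link{writeConnectomeTSV}}
#' (columns \code{source}, \code{target}, \code{weight}) and returns a
#' copy of the network with those weights applied, so users can edit the
#' connectome outside R and load it back.
#'
#' @param net the \code{\link{Network}} to modify (typically the default).
#' @param path TSV file path.
#' @return the updated \code{\link{Network}} (input unchanged).
#' @export
readConnectomeTSV <- function(net, path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(d)))
    stop("connectome table needs columns source, target, weight")
  conn <- net@connections
  key <- paste(conn$source, conn$target)
  j <- match(paste(d$source, d$target), key)
  if (anyNA(j))
    stop("unknown connection(s): ",
         paste(d$source[is.na(j)], "->", d$target[is.na(j)],
               collapse = ", "))
  conn$weight[j] <- d$weight
  net@connections <- conn
  net
}
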