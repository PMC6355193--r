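# Shared fixtures: small networks and a slow-but-transparent RK4 stepper
# used as an independent oracle against the compiled core.

# the acceptance suite reports every failed expectation
options(testthat.progress.max_fails = 1000)

# left-right mirror permutation of a full state vector (V, h, noise)
mirrorState <- function(net, st) {
  ids <- populations(net)$id
  swap <- vapply(strsplit(ids, ":", fixed = TRUE), function(p) {
    p[2] <- if (p[2] == "l") "r" else "l"
    paste(p, collapse = ":")
  }, character(1))
  j <- match(swap, ids)
  n <- length(ids)
  c(st[j], st[n + j], st[2 * n + j])
}

# one plain population with optional drive, all scale factors 1
plainPopNet <- function(gL = 5, EL = -60) {
  pops <- data.frame(
    id = "P:l", name = "P", side = "l", girdle = NA_character_,
    compartment = "fixture", dynamics = "plain", transmitter = "exc",
    C = 10, gL = gL, EL = EL, Vthr = -50, Vmax = 0,
    gNaP = NA_real_, ENa = NA_real_, Vm = NA_real_, km = NA_real_,
    Vh = NA_real_, kh = NA_real_, tauMax = NA_real_, driveGain = 1,
    sigmaNoise = 0, tauNoise = 10, stringsAsFactors = FALSE)
  new("Network", populations = pops,
      connections = data.frame(source = character(), target = character(),
                               weight = numeric(), printed = numeric(),
                               stringsAsFactors = FALSE),
      drives = data.frame(target = character(), value = numeric(),
                          stringsAsFactors = FALSE),
      synapse = list(EsynE = -10, EsynI = -75, gE = 1, gI = 1, gD = 1))
}

# reference RK4 integration of stateDerivative (pure R, independent of the
# compiled stepper's internals)
rk4Reference <- function(net, state, drives, duration, dt) {
  nsteps <- round(duration / dt)
  n <- nrow(populations(net))
  for (s in seq_len(nsteps)) {
    k1 <- stateDerivative(net, state, drives)
    st2 <- state; st2[1:(2 * n)] <- st2[1:(2 * n)] + dt / 2 * k1
    k2 <- stateDerivative(net, st2, drives)
    st3 <- state; st3[1:(2 * n)] <- st3[1:(2 * n)] + dt / 2 * k2
    k3 <- stateDerivative(net, st3, drives)
    st4 <- state; st4[1:(2 * n)] <- st4[1:(2 * n)] + dt * k3
    k4 <- stateDerivative(net, st4, drives)
    state[1:(2 * n)] <- state[1:(2 * n)] +
      dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  state
}

# expand one printed connection-table row into the realized connection ids
# (independent re-implementation of the wiring rules, used by the
# completeness test)
expandTableRow <- function(row) {
  nm <- function(x) {
    al <- c("CnF-GABA/Gly" = "CnF-Inh", "PPN-GABA/Gly" = "PPN-Inh",
            "LPGi-GABA/Gly" = "LPGi-Inh", "V0_D" = "V0D", "V0_V" = "V0V",
            "V0_D-LPN" = "V0D-LPN", "V0_V-LPN" = "V0V-LPN",
            "Ini" = if (row$section == "relay-spinal") "dIni" else "Ini")
    if (x %in% names(al)) al[[x]] else x
  }
  brainstem <- c("CnF-Glu", "CnF-Inh", "PPN-Glu", "PPN-Inh", "LPGi-Glu-1",
                 "LPGi-Glu-2", "LPGi-Inh", "VN")
  girdles <- c("fore", "hind")
  # parse prefixes
  parse <- function(x) {
    g <- NA_character_; rel <- "i"
    while (grepl("^(i|c|f|h|ih|ch|if|cf)-", x)) {
      p <- sub("-.*", "", x)
      x <- sub("^[a-z]+-", "", x)
      if (p %in% c("i", "c")) rel <- p
      if (p %in% c("f", "h")) g <- ifelse(p == "f", "fore", "hind")
      if (p %in% c("ih", "ch")) { rel <- substr(p, 1, 1); g <- "hind" }
      if (p %in% c("if", "cf")) { rel <- substr(p, 1, 1); g <- "fore" }
    }
    list(name = nm(x), rel = rel, girdle = g)
  }
  srcSpec <- parse(row$source)
  tgtSpec <- parse(row$target)
  sBrain <- srcSpec$name %in% brainstem
  tBrain <- tgtSpec$name %in% brainstem
  # girdle pairing: explicit prefixes win; an unspecified spinal source
  # follows the target's girdle (and vice versa); fully unspecified
  # spinal-spinal rows are girdle-local in both girdles; brainstem-to-spinal
  # rows hit both girdle copies
  pairs <- if (sBrain && tBrain) list(c(NA, NA))
  else if (sBrain) {
    tg <- if (!is.na(tgtSpec$girdle)) tgtSpec$girdle else girdles
    lapply(tg, function(g) c(NA, g))
  } else if (!is.na(srcSpec$girdle) && !is.na(tgtSpec$girdle))
    list(c(srcSpec$girdle, tgtSpec$girdle))
  else if (!is.na(srcSpec$girdle))
    list(c(srcSpec$girdle, srcSpec$girdle))
  else if (!is.na(tgtSpec$girdle))
    list(c(tgtSpec$girdle, tgtSpec$girdle))
  else lapply(girdles, function(g) c(g, g))
  out <- list()
  mk <- function(n, sd, g)
    if (is.na(g)) paste(n, sd, sep = ":") else paste(n, sd, g, sep = ":")
  for (s in c("l", "r")) {
    o <- if (s == "l") "r" else "l"
    ts <- if (tgtSpec$rel == "c") o else s
    for (p in pairs)
      out[[length(out) + 1]] <- c(mk(srcSpec$name, s, p[1]),
                                  mk(tgtSpec$name, ts, p[2]))
  }
  do.call(rbind, out)
}
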