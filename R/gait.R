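#' @include AllClasses.R
NULL

#' Detect burst onsets in an activity trace
#'
#' Onsets are upward crossings of a threshold, linearly interpolated between
#' samples. Crossings closer than the refractory gap to the previous onset
#' are suppressed.
#'
#' @param f activity trace sampled on the time grid \code{time}.
#' @param time sample times (ms); must be increasing.
#' @param threshold crossing level (default 0.1).
#' @param refractory minimum gap between onsets (ms).
#' @return numeric vector of onset times (ms); empty for constant traces.
#' @examples
#' t <- seq(0, 400, by = 1)
#' detectOnsets(as.numeric(t %% 100 >= 50), t)
#' @export
detectOnsets <- function(f, time, threshold = 0.1, refractory = 20) {
  stopifnot(length(f) == length(time))
  if (length(f) < 2) return(numeric())
  below <- f < threshold
  i <- which(below[-length(f)] & !below[-1])
  if (!length(i)) return(numeric())
  # linear interpolation of the crossing time inside [i, i+1]
  t0 <- time[i]; t1 <- time[i + 1]; f0 <- f[i]; f1 <- f[i + 1]
  on <- t0 + (threshold - f0) / (f1 - f0) * (t1 - t0)
  keep <- c(TRUE, diff(on) >= refractory)
  while (!all(keep)) {            # re-apply after deletions
    on <- on[keep]
    keep <- c(TRUE, diff(on) >= refractory)
  }
  on
}

#' Normalized phase difference between two onsets
#'
#' \eqn{\phi = ((t_{other} - t_{ref}) / T) \bmod 1}. A value of 0.5 means
#' alternation, 0 (equivalently 1) means synchronization.
#'
#' @param reference onset time of the reference limb (ms).
#' @param other onset time of the other limb (ms).
#' @param period cycle period (ms), > 0.
#' @return phase difference in \eqn{[0, 1)}.
#' @export
phaseDifference <- function(reference, other, period) {
  if (any(period <= 0)) stop("period must be > 0")
  ((other - reference) / period) %% 1
}

#' Per-cycle oscillation frequency from consecutive onsets
#'
#' @param onsets reference-limb onset times (ms), increasing.
#' @return frequencies (Hz), one per cycle; \code{NA} (with a warning
#'   attribute) if fewer than two onsets were supplied.
#' @export
cycleFrequency <- function(onsets) {
  if (length(onsets) < 2) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  1000 / diff(onsets)
}

.circDist <- function(phi, centre) {
  d <- abs(phi - centre) %% 1
  pmin(d, 1 - d)
}

#' Default gait classification windows
#'
#' Circular tolerance windows, in normalized phase units, used by
#' \code{\link{classifyGait}}: \code{sync} is the half-width around 0 within
#' which a left-right pair counts as synchronous, \code{alt} the half-width
#' around 0.5 for alternation, and \code{diagSync} the half-width around 0
#' within which the diagonal pair counts as synchronous (separating trot
#' from walk).
#'
#' @return named list \code{sync}, \code{alt}, \code{diagSync}.
#' @export
gaitWindows <- function() list(sync = 0.15, alt = 0.1, diagSync = 0.15)

#' Classify a gait from the four inter-limb phase differences
#'
#' Uses circular distances of the hind and fore left-right phase differences
#' from synchrony (0) and alternation (0.5): \emph{bound} when both
#' left-right pairs are synchronous; \emph{trot} when both alternate and the
#' diagonal pair is synchronous; \emph{walk} when both alternate and the
#' diagonal pair is not synchronous; \emph{gallop} when a left-right pair
#' sits in the intermediate band between synchrony and alternation;
#' otherwise \emph{unclassified}.
#'
#' @param hindLR,foreLR,homolateral,diagonal phase differences in
#'   \eqn{[0, 1)}; alternatively pass a length-4 vector as \code{hindLR}.
#' @param windows tolerance windows, see \code{\link{gaitWindows}}.
#' @return one of \code{"walk"}, \code{"trot"}, \code{"gallop"},
#'   \code{"bound"}, \code{"unclassified"}.
#' @examples
#' classifyGait(0.5, 0.5, 0.5, 0.0)   # trot
#' classifyGait(0.02, 0.98, 0.5, 0.5) # bound
#' @export
classifyGait <- function(hindLR, foreLR = NULL, homolateral = NULL,
                         diagonal = NULL, windows = gaitWindows()) {
  if (is.null(foreLR) && length(hindLR) == 4) {
    foreLR <- hindLR[2]; homolateral <- hindLR[3]; diagonal <- hindLR[4]
    hindLR <- hindLR[1]
  }
  phi <- c(hindLR, foreLR, homolateral, diagonal)
  if (any(!is.finite(phi)) || any(phi < 0 | phi >= 1))
    stop("phase differences must lie in [0, 1)")
  hSync <- .circDist(hindLR, 0) <= windows$sync
  fSync <- .circDist(foreLR, 0) <= windows$sync
  hAlt <- .circDist(hindLR, 0.5) <= windows$alt
  fAlt <- .circDist(foreLR, 0.5) <= windows$alt
  if (hSync && fSync) return("bound")
  if (hAlt && fAlt) {
    if (.circDist(diagonal, 0) <= windows$diagSync) return("trot")
    return("walk")
  }
  hMid <- !hSync && !hAlt
  fMid <- !fSync && !fAlt
  if (hMid || fMid) return("gallop")
  "unclassified"
}

#' Cycle records from simulated rhythm-generator traces
#'
#' Segments the left hind flexor-center output into locomotor cycles
#' (threshold onsets) and computes, for every complete cycle, the frequency
#' and the four normalized phase differences: hind left-right, fore
#' left-right, homolateral (left fore vs left hind) and diagonal (right
#' fore vs left hind), each from the onset of the corresponding limb
#' falling inside the cycle.
#'
#' @param time sample times (ms).
#' @param fLH,fRH,fLF,fRF output traces of the left hind, right hind, left
#'   fore and right fore flexor centers.
#' @param threshold,refractory onset-detection settings
#'   (\code{\link{detectOnsets}}).
#' @param classify if \code{TRUE}, add a gait label per cycle.
#' @return \code{data.frame} with columns \code{cycle}, \code{onset},
#'   \code{period}, \code{freq}, \code{hindLR}, \code{foreLR},
#'   \code{homolateral}, \code{diagonal} and (optionally) \code{gait}.
#' @export
cycleRecords <- function(time, fLH, fRH, fLF, fRF, threshold = 0.1,
                         refractory = 20, classify = TRUE) {
  ref <- detectOnsets(fLH, time, threshold, refractory)
  if (length(ref) < 2)
    return(data.frame(cycle = integer(), onset = numeric(),
                      period = numeric(), freq = numeric(),
                      hindLR = numeric(), foreLR = numeric(),
                      homolateral = numeric(), diagonal = numeric(),
                      gait = character(), stringsAsFactors = FALSE))
  others <- list(hindLR = detectOnsets(fRH, time, threshold, refractory),
                 homolateral = detectOnsets(fLF, time, threshold, refractory),
                 diagonal = detectOnsets(fRF, time, threshold, refractory))
  n <- length(ref) - 1
  period <- diff(ref)
  phi <- sapply(others, function(on) {
    vapply(seq_len(n), function(k) {
      inside <- on[on >= ref[k] & on < ref[k + 1]]
      if (!length(inside)) return(NA_real_)
      phaseDifference(ref[k], inside[1], period[k])
    }, numeric(1))
  })
  phi <- matrix(phi, nrow = n,
                dimnames = list(NULL, c("hindLR", "homolateral", "diagonal")))
  # fore left-right from the left fore onset to the right fore onset,
  # normalized by the same cycle period and referenced to the cycle start
  foreLR <- (phi[, "diagonal"] - phi[, "homolateral"]) %% 1
  out <- data.frame(cycle = seq_len(n), onset = ref[-length(ref)],
                    period = period, freq = 1000 / period,
                    hindLR = phi[, "hindLR"], foreLR = foreLR,
                    homolateral = phi[, "homolateral"],
                    diagonal = phi[, "diagonal"],
                    stringsAsFactors = FALSE)
  if (classify) {
    out$gait <- vapply(seq_len(n), function(k) {
      v <- c(out$hindLR[k], out$foreLR[k], out$homolateral[k],
             out$diagonal[k])
      if (any(!is.finite(v))) "unclassified"
      else classifyGait(v)
    }, character(1))
  }
  out
}

#' Bivariate phase-frequency histogram
#'
#' Relative frequency of occurrence of (phase difference, cycle frequency)
#' pairs: the phase axis is partitioned into 65 equal bins on \eqn{[0, 1]}
#' and the frequency axis into 0.25-Hz bins on \eqn{[0, 14]} Hz. Counts are
#' divided by the total number of locomotor cycles; cycles falling outside
#' the axes are counted in the total but not binned, and their fraction is
#' reported.
#'
#' @param records cycle-record \code{data.frame}
#'   (\code{\link{cycleRecords}}).
#' @param phase which phase-difference column to bin (default
#'   \code{"hindLR"}).
#' @param phaseBins number of phase bins; \code{freqMax}, \code{freqBin}
#'   define the frequency axis.
#' @param freqMax upper edge of the frequency axis (Hz).
#' @param freqBin frequency bin width (Hz).
#' @return list with \code{density} (phase x frequency matrix of relative
#'   frequencies), \code{phaseBreaks}, \code{freqBreaks}, \code{total}
#'   (cycle count) and \code{outOfRange} (unbinned fraction).
#' @export
phaseFrequencyHistogram <- function(records, phase = "hindLR",
                                    phaseBins = 65, freqMax = 14,
                                    freqBin = 0.25) {
  if (!nrow(records)) stop("empty input: no locomotor cycles")
  pb <- seq(0, 1, length.out = phaseBins + 1)
  fb <- seq(0, freqMax, by = freqBin)
  phi <- records[[phase]]
  fr <- records$freq
  ok <- is.finite(phi) & is.finite(fr) & phi >= 0 & phi <= 1 &
    fr >= 0 & fr <= freqMax
  pi_ <- pmin(findInterval(phi[ok], pb, rightmost.closed = TRUE), phaseBins)
  fi <- pmin(findInterval(fr[ok], fb, rightmost.closed = TRUE),
             length(fb) - 1)
  dens <- matrix(0, phaseBins, length(fb) - 1)
  for (k in seq_along(pi_)) dens[pi_[k], fi[k]] <- dens[pi_[k], fi[k]] + 1
  total <- nrow(records)
  list(density = dens / total, phaseBreaks = pb, freqBreaks = fb,
       total = total, outOfRange = sum(!ok) / total)
}

#' Frequency-resolved gait probability map
#'
#' Relative frequency of each gait category per frequency bin, with gallop
#' and bound grouped into one category. Normalization matches
#' \code{\link{phaseFrequencyHistogram}}: counts divided by the total
#' number of cycles.
#'
#' @param records cycle-record \code{data.frame} with a \code{gait} column.
#' @param freqMax,freqBin frequency axis (Hz).
#' @return list with \code{prob} (gait x frequency-bin matrix, rows
#'   \code{walk}, \code{trot}, \code{gallop.bound}, \code{other}),
#'   \code{freqBreaks}, \code{total}, \code{outOfRange}.
#' @export
gaitProbabilityMap <- function(records, freqMax = 14, freqBin = 0.25) {
  if (!nrow(records)) stop("empty input: no locomotor cycles")
  fb <- seq(0, freqMax, by = freqBin)
  cats <- c("walk", "trot", "gallop.bound", "other")
  grp <- ifelse(records$gait %in% c("gallop", "bound"), "gallop.bound",
                ifelse(records$gait %in% c("walk", "trot"), records$gait,
                       "other"))
  ok <- is.finite(records$freq) & records$freq >= 0 & records$freq <= freqMax
  fi <- pmin(findInterval(records$freq[ok], fb, rightmost.closed = TRUE),
             length(fb) - 1)
  prob <- matrix(0, length(cats), length(fb) - 1,
                 dimnames = list(cats, NULL))
  gok <- grp[ok]
  for (k in seq_along(fi)) prob[gok[k], fi[k]] <- prob[gok[k], fi[k]] + 1
  total <- nrow(records)
  list(prob = prob / total, freqBreaks = fb, total = total,
       outOfRange = sum(!ok) / total)
}
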