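#' @include AllClasses.R
NULL

#' @describeIn Network-accessors population roster
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @describeIn Network-accessors connection table
#' @export
setGeneric("connections", function(x) standardGeneric("connections"))
#' @describeIn Network-accessors constant tonic drives
#' @export
setGeneric("drives", function(x) standardGeneric("drives"))
#' @describeIn Network-accessors global synaptic parameters
#' @export
setGeneric("synapseParams", function(x) standardGeneric("synapseParams"))

#' Accessors for Network objects
#'
#' @param x a \code{\link{Network}}.
#' @name Network-accessors
NULL

#' @rdname Network-accessors
#' @export
setMethod("populations", "Network", function(x) x@populations)
#' @rdname Network-accessors
#' @export
setMethod("connections", "Network", function(x) x@connections)
#' @rdname Network-accessors
#' @export
setMethod("drives", "Network", function(x) x@drives)
#' @rdname Network-accessors
#' @export
setMethod("synapseParams", "Network", function(x) x@synapse)

#' Look up one connection weight
#'
#' @param net a \code{\link{Network}}.
#' @param source,target population ids (e.g. \code{"CnF-Glu:l"}).
#' @return the signed weight (0 if the connection does not exist).
#' @export
connectionWeight <- function(net, source, target) {
  conn <- net@connections
  hit <- conn$source == source & conn$target == target
  if (!any(hit)) 0 else sum(conn$weight[hit])
}

setMethod("show", "Network", function(object) {
  p <- object@populations
  cat("Network of", nrow(p), "populations (",
      sum(p$dynamics == "nap"), "oscillatory ),",
      nrow(object@connections), "connections,",
      nrow(object@drives), "constant drives\n")
  cat("compartments:", paste(unique(p$compartment), collapse = ", "), "\n")
})

setMethod("show", "Protocol", function(object) {
  cat("Protocol:", nrow(object@stimulations), "stimulation target(s),",
      "alpha =", object@alpha, "\n")
  cat("  duration", object@duration, "ms, dt", object@dt,
      "ms, sigmaNoise", object@sigmaNoise, "pA, seed", object@seed, "\n")
  if (length(object@lesions))
    cat("  lesions:", paste(object@lesions, collapse = ", "), "\n")
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult:", length(object@time), "samples over",
      round(max(object@time) / 1000, 2), "s,", ncol(object@V),
      "recorded populations\n")
  if (object@blewUp) cat("  ** integration failed at", object@blewAt, "ms\n")
})

setMethod("show", "BifurcationDiagram", function(object) {
  cat("BifurcationDiagram:", nrow(object@up), "up-branch and",
      nrow(object@down), "down-branch steps\n")
  up <- object@up
  conv <- up$status == "converged"
  if (any(conv))
    cat("  up-branch frequency range:",
        sprintf("%.2f-%.2f Hz", min(up$freq[conv], na.rm = TRUE),
                max(up$freq[conv], na.rm = TRUE)),
        "; gaits:", paste(unique(up$gait[conv]), collapse = ", "), "\n")
})

#' @describeIn BifurcationDiagram up-branch step table
#' @param x a \code{BifurcationDiagram}.
#' @export
upBranch <- function(x) x@up

#' @describeIn BifurcationDiagram down-branch step table
#' @export
downBranch <- function(x) x@down
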