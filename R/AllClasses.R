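#' @import methods
NULL

#' Result of a tight-binding dissociation-constant fit
#'
#' Holds the dissociation constant estimated from an EMSA titration by
#' least-squares fitting of the Morrison (tight-binding) closed form, together
#' with its uncertainty and fit diagnostics.
#'
#' @slot kd Fitted dissociation constant (nM).
#' @slot standardError Standard error of \code{kd} from the Jacobian-based
#'   covariance of the least-squares fit (nM).
#' @slot betweenReplicateSd Standard deviation of per-replicate Kd estimates
#'   when the titration carries two or more replicates; \code{NA} otherwise.
#' @slot rss Residual sum of squares on the fraction-bound scale.
#' @slot nPoints Number of titration points used.
#' @slot converged Whether the optimiser reported convergence.
#'
#' @seealso [fitKd()], [morrisonFraction()]
#' @export
setClass("KdFit",
  representation(
    kd = "numeric",
    standardError = "numeric",
    betweenReplicateSd = "numeric",
    rss = "numeric",
    nPoints = "integer",
    converged = "logical"
  )
)

setValidity("KdFit", function(object) {
  msg <- character()
  if (length(object@kd) != 1L) msg <- c(msg, "'kd' must be length 1")
  if (isTRUE(object@converged) && !is.na(object@kd) && object@kd <= 0)
    msg <- c(msg, "'kd' must be positive for a converged fit")
  if (!is.na(object@standardError) && object@standardError < 0)
    msg <- c(msg, "'standardError' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Calpha-only structure model
#'
#' A minimal coordinate model keyed by (chain, residue number), holding one
#' Calpha position per residue. This is the container against which
#' crosslink-derived distance restraints are evaluated.
#'
#' @slot residues A \code{data.frame} with columns \code{chain},
#'   \code{resno}, \code{resid} (three-letter residue name), and coordinates
#'   \code{x}, \code{y}, \code{z} in Angstrom.
#'
#' @seealso [readStructure()], [mapCrosslinks()]
#' @export
setClass("StructureModel", representation(residues = "data.frame"))

setValidity("StructureModel", function(object) {
  r <- object@residues
  need <- c("chain", "resno", "resid", "x", "y", "z")
  if (!all(need %in% names(r)))
    return(paste("residues must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) && any(!is.finite(as.matrix(r[, c("x", "y", "z")]))))
    return("coordinates must be finite")
  if (anyDuplicated(paste(r$chain, r$resno)))
    return("at most one Calpha per (chain, residue number)")
  TRUE
})

#' Null distribution of random residue-pair distances
#'
#' Calpha-Calpha distances between randomly drawn residue pairs of the
#' allowed residue classes, used as the reference distribution against which
#' observed crosslink distances are compared.
#'
#' @slot distances Sampled (or exhaustively enumerated) distances in Angstrom.
#' @slot residueClasses One-letter codes of the residue types sampled.
#' @slot nSamples Number of pairs drawn (equals \code{length(distances)}).
#' @slot exhaustive Whether all eligible pairs were enumerated instead of
#'   sampled.
#' @slot seed Seed used for sampling (\code{NA} for exhaustive enumeration).
#'
#' @seealso [sampleNull()], [compareDistributions()]
#' @export
setClass("NullDistribution",
  representation(
    distances = "numeric",
    residueClasses = "character",
    nSamples = "integer",
    exhaustive = "logical",
    seed = "integer"
  )
)

#' Binned FRET efficiency histogram
#'
#' @slot breaks Bin edges, strictly increasing; bins are half-open
#'   \code{[edge, next_edge)} so a sample on an edge falls in the bin to its
#'   right.
#' @slot counts Integer counts per bin; sums to \code{nSamples}.
#' @slot nSamples Total number of samples binned.
#' @slot nBelow,nAbove Number of out-of-range samples folded into the first
#'   and last bin, respectively.
#'
#' @seealso [buildHistogram()], [fitMixture()]
#' @export
setClass("EfficiencyHistogram",
  representation(
    breaks = "numeric",
    counts = "integer",
    nSamples = "integer",
    nBelow = "integer",
    nAbove = "integer"
  )
)

setValidity("EfficiencyHistogram", function(object) {
  if (any(diff(object@breaks) <= 0)) return("breaks must be strictly increasing")
  if (length(object@counts) != length(object@breaks) - 1L)
    return("counts must have one entry per bin")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (sum(object@counts) != object@nSamples)
    return("counts must sum to nSamples")
  TRUE
})

#' Gaussian mixture fit to a FRET efficiency histogram
#'
#' Least-squares fit of a sum of one or two Gaussian curves to binned
#' efficiency counts, the convention used for single-molecule FRET population
#' analysis. Component weights are areas (amplitude times width), normalised
#' to sum to one.
#'
#' @slot components \code{data.frame} with columns \code{mean}, \code{sd},
#'   \code{weight}, ordered by decreasing weight.
#' @slot standardErrors Named standard errors of the fitted parameters.
#' @slot rSquared Coefficient of determination of the fit to bin counts.
#' @slot order Number of components fitted (1 or 2).
#' @slot bic Bayesian information criterion computed from the least-squares
#'   residuals, used for model-order selection.
#' @slot converged Whether the optimiser converged to a valid solution.
#' @slot histogram The fitted [EfficiencyHistogram-class], retained so that
#'   model selection can verify two fits describe the same data.
#'
#' @seealso [fitMixture()], [selectModel()]
#' @export
setClass("MixtureFit",
  representation(
    components = "data.frame",
    standardErrors = "numeric",
    rSquared = "numeric",
    order = "integer",
    bic = "numeric",
    converged = "logical",
    histogram = "EfficiencyHistogram"
  )
)

setValidity("MixtureFit", function(object) {
  k <- nrow(object@components)
  if (!object@order %in% c(1L, 2L)) return("order must be 1 or 2")
  if (k != object@order) return("components must match the model order")
  if (isTRUE(object@converged)) {
    if (any(object@components$sd <= 0)) return("component sds must be positive")
    if (abs(sum(object@components$weight) - 1) > 1e-6)
      return("component weights must sum to 1")
    if (is.unsorted(rev(object@components$weight)))
      return("components must be sorted by decreasing weight")
  }
  TRUE
})

#' A generated dataset bundled with its ground truth
#'
#' Container returned by every synthetic-data generator: the payload (a
#' titration table, a structure plus crosslink list, efficiency samples, or a
#' genome plus annotation), the exact generator parameters needed for a
#' recovery assertion, and the seed, so identical calls are byte-identical.
#'
#' @slot kind One of \code{"titration"}, \code{"fret"}, \code{"xlinks"},
#'   \code{"genome"}.
#' @slot payload Named list of in-memory inputs for the matching pipeline.
#' @slot truth Named list of generator parameters (ground truth).
#' @slot seed Integer seed the payload was generated from.
#'
#' @seealso [genTitration()], [genFretSamples()], [genToyComplex()],
#'   [genGenome()], [writeDataset()]
#' @export
setClass("SyntheticDataset",
  representation(
    kind = "character",
    payload = "list",
    truth = "list",
    seed = "integer"
  )
)

setValidity("SyntheticDataset", function(object) {
  if (!object@kind %in% c("titration", "fret", "xlinks", "genome"))
    return("unknown dataset kind")
  TRUE
})
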