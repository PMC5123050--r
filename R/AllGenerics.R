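#' Accessors for fit and dataset objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{kd()} and \code{standardError()} read a [KdFit-class];
#' \code{components()}, \code{rSquared()} and \code{modelOrder()} read a
#' [MixtureFit-class]; \code{residues()} reads a [StructureModel-class];
#' \code{nullDistances()} reads a [NullDistribution-class];
#' \code{truth()} and \code{payload()} read a [SyntheticDataset-class];
#' \code{converged()} reads either fit class.
#'
#' @param object The object to read from.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))

#' @rdname accessors
#' @export
setGeneric("standardError", function(object) standardGeneric("standardError"))

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("modelOrder", function(object) standardGeneric("modelOrder"))

#' @rdname accessors
#' @export
setGeneric("residues", function(object) standardGeneric("residues"))

#' @rdname accessors
#' @export
setGeneric("nullDistances", function(object) standardGeneric("nullDistances"))

#' @rdname accessors
#' @export
setGeneric("truth", function(object) standardGeneric("truth"))

#' @rdname accessors
#' @export
setGeneric("payload", function(object) standardGeneric("payload"))

#' Write a synthetic dataset to disk
#'
#' @param object A [SyntheticDataset-class].
#' @param dir Output directory (created if absent).
#' @param ... Passed to methods.
#' @return Invisibly, the named character vector of files written.
#' @export
setGeneric("writeDataset", function(object, dir, ...) standardGeneric("writeDataset"))
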