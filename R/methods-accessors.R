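#' @rdname accessors
#' @aliases kd,KdFit-method
setMethod("kd", "KdFit", function(object) object@kd)

#' @rdname accessors
#' @aliases standardError,KdFit-method
setMethod("standardError", "KdFit", function(object) object@standardError)

#' @rdname accessors
#' @aliases converged,KdFit-method
setMethod("converged", "KdFit", function(object) object@converged)

#' @rdname accessors
#' @aliases converged,MixtureFit-method
setMethod("converged", "MixtureFit", function(object) object@converged)

#' @rdname accessors
#' @aliases components,MixtureFit-method
setMethod("components", "MixtureFit", function(object) object@components)

#' @rdname accessors
#' @aliases rSquared,MixtureFit-method
setMethod("rSquared", "MixtureFit", function(object) object@rSquared)

#' @rdname accessors
#' @aliases modelOrder,MixtureFit-method
setMethod("modelOrder", "MixtureFit", function(object) object@order)

#' @rdname accessors
#' @aliases standardError,MixtureFit-method
setMethod("standardError", "MixtureFit", function(object) object@standardErrors)

#' @rdname accessors
#' @aliases residues,StructureModel-method
setMethod("residues", "StructureModel", function(object) object@residues)

#' @rdname accessors
#' @aliases nullDistances,NullDistribution-method
setMethod("nullDistances", "NullDistribution", function(object) object@distances)

#' @rdname accessors
#' @aliases truth,SyntheticDataset-method
setMethod("truth", "SyntheticDataset", function(object) object@truth)

#' @rdname accessors
#' @aliases payload,SyntheticDataset-method
setMethod("payload", "SyntheticDataset", function(object) object@payload)

setMethod("show", "KdFit", function(object) {
  cat("KdFit object\n")
  cat(sprintf("  Kd: %.3g nM  (se %.3g nM)\n", object@kd, object@standardError))
  if (!is.na(object@betweenReplicateSd))
    cat(sprintf("  between-replicate sd: %.3g nM\n", object@betweenReplicateSd))
  cat(sprintf("  rss: %.4g over %d points; converged: %s\n",
              object@rss, object@nPoints, object@converged))
})

setMethod("show", "StructureModel", function(object) {
  r <- object@residues
  cat(sprintf("StructureModel: %d residues (Calpha) in %d chain(s): %s\n",
              nrow(r), length(unique(r$chain)),
              paste(sort(unique(r$chain)), collapse = ", ")))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: %d %s pair distances (classes: %s)\n",
              object@nSamples,
              if (object@exhaustive) "enumerated" else "sampled",
              paste(object@residueClasses, collapse = ",")))
  if (length(object@distances))
    cat(sprintf("  mean %.1f A, range %.1f-%.1f A\n", mean(object@distances),
                min(object@distances), max(object@distances)))
})

setMethod("show", "EfficiencyHistogram", function(object) {
  cat(sprintf("EfficiencyHistogram: %d samples in %d bins over [%.2f, %.2f]\n",
              object@nSamples, length(object@counts),
              min(object@breaks), max(object@breaks)))
  if (object@nBelow || object@nAbove)
    cat(sprintf("  out-of-range: %d below, %d above (folded into edge bins)\n",
                object@nBelow, object@nAbove))
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: %d-Gaussian fit (converged: %s, R^2 = %.4f)\n",
              object@order, object@converged, object@rSquared))
  cmp <- object@components
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  component %d: E = %.3f (sd %.3f), weight %.1f%%\n",
                i, cmp$mean[i], cmp$sd[i], 100 * cmp$weight[i]))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset (kind '%s', seed %d)\n", object@kind, object@seed))
  cat("  payload:", paste(names(object@payload), collapse = ", "), "\n")
  cat("  truth:  ", paste(names(object@truth), collapse = ", "), "\n")
})
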