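#' Fraction bound under the tight-binding (Morrison) equilibrium
#'
#' Closed-form solution of the 1:1 binding equilibrium in terms of total
#' concentrations, valid when the labelled ligand concentration is comparable
#' to the dissociation constant so the free-equals-total approximation fails:
#' \deqn{f = \frac{(K_d + R_T + L_T) - \sqrt{(K_d + R_T + L_T)^2 - 4 R_T L_T}}{2 L_T}}
#' where \eqn{R_T} is the total receptor (polymerase) concentration and
#' \eqn{L_T} the total labelled ligand concentration. The discriminant is
#' non-negative analytically; tiny negative values arising from floating-point
#' cancellation are clamped to zero before the square root.
#'
#' @param kd Dissociation constant, nM (> 0).
#' @param receptorTotal Total receptor concentration(s), nM (>= 0); vectorised.
#' @param ligandTotal Total labelled ligand concentration, nM (> 0).
#' @return Fraction of ligand in complex, in
#'   \code{[0, min(1, receptorTotal/ligandTotal)]}.
#' @examples
#' morrisonFraction(12.6, c(1, 10, 100), 1)
#' @export
morrisonFraction <- function(kd, receptorTotal, ligandTotal) {
  stopifnot_scalar(kd, "kd", positive = TRUE)
  stopifnot_scalar(ligandTotal, "ligandTotal")
  if (ligandTotal < 0 || any(!is.finite(receptorTotal)) || any(receptorTotal < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (ligandTotal == 0)
    stop("ligandTotal is zero: fraction bound is undefined (division by zero)",
         call. = FALSE)
  s <- kd + receptorTotal + ligandTotal
  disc <- pmax(s^2 - 4 * receptorTotal * ligandTotal, 0)
  (s - sqrt(disc)) / (2 * ligandTotal)
}

# Data-driven initial Kd guess: receptor concentration at which the observed
# fraction bound crosses 0.5, or the geometric mean of the receptor range if
# it never crosses.
init_kd_guess <- function(receptor, fraction) {
  o <- order(receptor)
  r <- receptor[o]; f <- fraction[o]
  above <- which(f >= 0.5)
  if (length(above) && above[1] > 1) {
    i <- above[1]
    # linear interpolation between the bracketing points
    r[i - 1] + (0.5 - f[i - 1]) * (r[i] - r[i - 1]) / (f[i] - f[i - 1])
  } else if (length(above)) {
    r[above[1]]
  } else {
    sqrt(max(min(r[r > 0]), 1e-4) * max(r))
  }
}

#' Fit a dissociation constant to an EMSA titration
#'
#' Least-squares fit of [morrisonFraction()] to observed fractions bound.
#' Replicates enter as independent points (unweighted, matching the usual
#' densitometry treatment). The standard error comes from the Jacobian-based
#' covariance of the one-parameter fit; when the table carries two or more
#' replicates with enough points each, the between-replicate standard
#' deviation of per-replicate Kd estimates is reported as well, since a
#' printed "+/-" can mean either.
#'
#' @param points \code{data.frame} with columns \code{receptor_total_nM},
#'   \code{ligand_total_nM}, \code{fraction_bound} and optionally
#'   \code{replicate}. At least 3 points spanning at least a 2-fold receptor
#'   range are required.
#' @param init Optional starting Kd (nM). Default: the receptor concentration
#'   at which the observed fraction crosses 0.5, or the geometric mean of the
#'   receptor range if it never does.
#' @param bounds Length-2 numeric, lower/upper Kd bounds in nM. The defaults
#'   keep the optimiser in the physically meaningful regime.
#' @return A [KdFit-class].
#' @examples
#' tt <- payload(genTitration(trueKd = 12.6, noiseSd = 0, seed = 1))$titration
#' fitKd(tt)
#' @export
fitKd <- function(points, init = NULL, bounds = c(1e-4, 1e6)) {
  need <- c("receptor_total_nM", "ligand_total_nM", "fraction_bound")
  if (!is.data.frame(points) || !all(need %in% names(points)))
    stop("'points' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  r <- points$receptor_total_nM
  l <- points$ligand_total_nM
  f <- points$fraction_bound
  if (any(!is.finite(f)))
    stop("fraction_bound contains non-finite values; fit rejected", call. = FALSE)
  if (any(f < 0 | f > 1))
    stop("fraction_bound must lie in [0, 1]", call. = FALSE)
  if (nrow(points) < 3L)
    stop("need at least 3 titration points", call. = FALSE)
  rp <- r[r > 0]
  if (!length(rp) || max(rp) / min(rp) < 2)
    stop("titration must span at least a 2-fold receptor range", call. = FALSE)
  if (stats::var(f) == 0)
    stop("all fraction_bound values identical; Kd is unidentifiable", call. = FALSE)

  if (is.null(init)) init <- init_kd_guess(r, f)
  init <- min(max(init, bounds[1]), bounds[2])

  dat <- data.frame(r = r, l = l, f = f)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ morrisonFraction(kd, r, l[1]),
      data = dat,
      start = list(kd = init),
      lower = bounds[1], upper = bounds[2],
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new("KdFit", kd = NA_real_, standardError = NA_real_,
               betweenReplicateSd = NA_real_, rss = NA_real_,
               nPoints = nrow(points), converged = FALSE))
  }
  est <- stats::coef(fit)[["kd"]]
  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  rss <- sum(stats::resid(fit)^2)
  conv <- isTRUE(fit$convInfo$isConv) || is.null(fit$convInfo)

  repsd <- NA_real_
  if ("replicate" %in% names(points)) {
    reps <- split(points, points$replicate)
    reps <- Filter(function(p) nrow(p) >= 3L, reps)
    if (length(reps) >= 2L) {
      per <- vapply(reps, function(p) {
        ft <- tryCatch(fitKd(p[, need], init = est, bounds = bounds),
                       error = function(e) NULL)
        if (is.null(ft) || !converged(ft)) NA_real_ else kd(ft)
      }, numeric(1))
      if (sum(!is.na(per)) >= 2L) repsd <- stats::sd(per, na.rm = TRUE)
    }
  }

  new("KdFit", kd = est, standardError = se, betweenReplicateSd = repsd,
      rss = rss, nPoints = nrow(points), converged = conv)
}

#' Normalise a transcription dose-response series
#'
#' Converts raw quantified transcript signals measured at increasing
#' inhibitor:polymerase stoichiometries into activities relative to the
#' uninhibited reference, so that stoichiometry 0 maps to relative activity 1.
#'
#' @param rawSignals \code{data.frame} with columns \code{stoichiometry}
#'   (molar ratio of inhibitor to polymerase) and \code{signal} (arbitrary
#'   phosphorimager units).
#' @param referenceStoichiometry The stoichiometry whose signal defines 100%
#'   activity (default 0).
#' @return \code{data.frame} with columns \code{stoichiometry} and
#'   \code{relative_activity}, in input order.
#' @examples
#' normalizeDoseResponse(data.frame(stoichiometry = c(0, 2, 8),
#'                                  signal = c(1000, 500, 100)))
#' @export
normalizeDoseResponse <- function(rawSignals, referenceStoichiometry = 0) {
  if (!is.data.frame(rawSignals) ||
      !all(c("stoichiometry", "signal") %in% names(rawSignals)))
    stop("'rawSignals' must have columns stoichiometry, signal", call. = FALSE)
  i <- which(rawSignals$stoichiometry == referenceStoichiometry)
  if (!length(i))
    stop("reference stoichiometry ", referenceStoichiometry,
         " not present in input", call. = FALSE)
  ref <- rawSignals$signal[i[1]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference signal must be positive", call. = FALSE)
  data.frame(stoichiometry = rawSignals$stoichiometry,
             relative_activity = rawSignals$signal / ref)
}

#' Read / write a titration table
#'
#' Tab-separated with header columns \code{receptor_total_nM},
#' \code{ligand_total_nM}, \code{fraction_bound}, \code{replicate};
#' missing values are encoded as \code{"."}.
#'
#' @param path File path.
#' @param points Titration \code{data.frame} (see [fitKd()]).
#' @return \code{readTitration}: the validated \code{data.frame};
#'   \code{writeTitration}: the path, invisibly.
#' @export
readTitration <- function(path) {
  df <- read_tsv(path, required = c("receptor_total_nM", "ligand_total_nM",
                                    "fraction_bound"))
  if (any(df$fraction_bound < 0 | df$fraction_bound > 1, na.rm = TRUE))
    stop("fraction_bound outside [0, 1] in ", path, call. = FALSE)
  if (any(df$receptor_total_nM < 0, na.rm = TRUE) ||
      any(df$ligand_total_nM < 0, na.rm = TRUE))
    stop("negative concentration in ", path, call. = FALSE)
  df
}

#' @rdname readTitration
#' @export
writeTitration <- function(points, path) {
  invisible(write_tsv(points, path))
}
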