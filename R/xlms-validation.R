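# Crosslinking-MS distance validation: map claimed residue pairs onto a
# Calpha model, score satisfaction against the crosslinker reach, compare
# with a random-pair null, and localise the binding interface.

# one-letter -> three-letter residue name map for the classes BS3 can react
# with (lysine plus the side reactivities).
RESIDUE_CLASS_MAP <- c(K = "LYS", S = "SER", T = "THR", Y = "TYR")

#' Construct a structure model from a residue table
#'
#' @param residues \code{data.frame} with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{x}, \code{y}, \code{z} (one Calpha per residue,
#'   Angstrom).
#' @return A [StructureModel-class].
#' @export
StructureModel <- function(residues) {
  new("StructureModel", residues = as.data.frame(residues))
}

#' Read a Calpha structure model from PDB or mmCIF
#'
#' Parsing rules: Calpha atoms only; the first model of multi-model files;
#' for alternate locations the highest-occupancy altloc is kept, ties going
#' to altloc \code{"A"}. Residues lacking a Calpha are dropped with a warning.
#'
#' @param path Path to a \code{.pdb} or \code{.cif} file (format chosen by
#'   extension; anything not ending in \code{.cif} is read as PDB).
#' @param chainMap Optional named character vector mapping protein names to
#'   chain IDs, applied to \code{names(chainMap)} found in crosslink tables;
#'   every mapped chain must exist in the file.
#' @return A [StructureModel-class].
#' @export
readStructure <- function(path, chainMap = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, verbose = FALSE))
  } else {
    # rm.alt = FALSE: alternate locations are resolved here by occupancy,
    # not by bio3d's keep-first rule
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  n_res_all <- nrow(unique(at[, c("chain", "resno")]))
  at <- at[at$elety == "CA" & !is.na(at$x), , drop = FALSE]
  if (!nrow(at)) stop("no Calpha atoms in ", path, call. = FALSE)

  # altloc resolution: highest occupancy, ties -> altloc "A" (then first)
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
    if (length(i) == 1L) return(i)
    i <- i[at$o[i] == max(at$o[i])]
    if (length(i) > 1L && any(at$alt[i] %in% c("A", ""))) {
      i <- i[at$alt[i] %in% c("A", "")]
    }
    i[1]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  if (nrow(at) < n_res_all)
    warning(n_res_all - nrow(at), " residue(s) lack a Calpha and were dropped",
            call. = FALSE)

  if (!is.null(chainMap)) {
    missing <- setdiff(unname(chainMap), unique(at$chain))
    if (length(missing))
      stop("chain(s) in chainMap absent from structure: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  StructureModel(data.frame(chain = at$chain, resno = at$resno,
                            resid = at$resid, x = at$x, y = at$y, z = at$z))
}

#' Write a Calpha-only model as PDB or minimal mmCIF
#'
#' @param structure A [StructureModel-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeStructurePDB <- function(structure, path) {
  r <- residues(structure)
  xyz <- as.numeric(t(as.matrix(r[, c("x", "y", "z")])))
  write_atomic(function(p) {
    bio3d::write.pdb(file = p, xyz = xyz, resno = r$resno, chain = r$chain,
                     resid = r$resid, elety = rep("CA", nrow(r)),
                     o = rep(1, nrow(r)), b = rep(0, nrow(r)))
  }, path)
}

#' @rdname writeStructurePDB
#' @export
writeStructureCIF <- function(structure, path) {
  r <- residues(structure)
  write_atomic(function(p) {
    # canonical PDBx atom_site column set and order, as in PDB-distributed
    # mmCIF files (readers commonly rely on it)
    lines <- c(
      "data_model",
      "#",
      "loop_",
      "_atom_site.group_PDB",
      "_atom_site.id",
      "_atom_site.type_symbol",
      "_atom_site.label_atom_id",
      "_atom_site.label_alt_id",
      "_atom_site.label_comp_id",
      "_atom_site.label_asym_id",
      "_atom_site.label_entity_id",
      "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x",
      "_atom_site.Cartn_y",
      "_atom_site.Cartn_z",
      "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv",
      "_atom_site.pdbx_formal_charge",
      "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id",
      "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id",
      "_atom_site.pdbx_PDB_model_num",
      sprintf("ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s CA 1",
              seq_len(nrow(r)), r$resid, r$chain, r$resno,
              r$x, r$y, r$z, r$resno, r$resid, r$chain),
      "#")
    writeLines(lines, p)
  }, path)
}

# canonical ordering of a pair's two ends so a<->b duplicates collapse
canonicalize_pairs <- function(links) {
  flip <- links$Chain1 > links$Chain2 |
    (links$Chain1 == links$Chain2 & links$Residue1 > links$Residue2)
  out <- links
  out[flip, c("Chain1", "Residue1")] <- links[flip, c("Chain2", "Residue2")]
  out[flip, c("Chain2", "Residue2")] <- links[flip, c("Chain1", "Residue1")]
  out[!duplicated(out[, c("Chain1", "Residue1", "Chain2", "Residue2")]), ,
      drop = FALSE]
}

#' Read a crosslink pair table
#'
#' Tab-separated with columns \code{Chain1}, \code{Residue1}, \code{Chain2},
#' \code{Residue2} and optionally \code{Score} (an upstream search score or
#' FDR; the pipeline never recomputes it). Protein names are translated to
#' chain IDs via \code{chainMap}; pair ends are ordered canonically so
#' duplicate a-b / b-a entries collapse.
#'
#' @param path File path.
#' @param chainMap Optional named character vector, protein name -> chain ID.
#' @return \code{data.frame} with canonicalised pairs and an
#'   \code{inter_protein} flag (ends on different chains).
#' @export
readCrosslinks <- function(path, chainMap = NULL) {
  df <- read_tsv(path, required = c("Chain1", "Residue1", "Chain2", "Residue2"))
  if (!"Score" %in% names(df)) df$Score <- NA_real_
  if (!is.null(chainMap)) {
    for (col in c("Chain1", "Chain2")) {
      hit <- df[[col]] %in% names(chainMap)
      df[[col]][hit] <- unname(chainMap[df[[col]][hit]])
    }
  }
  df <- canonicalize_pairs(df)
  df$inter_protein <- df$Chain1 != df$Chain2
  df
}

#' Drop crosslinks whose upstream score exceeds a threshold
#'
#' The upstream search's score/FDR column is an input filter here, never a
#' computed quantity: pairs scoring above \code{maxScore} are removed before
#' any statistic.
#'
#' @param links Crosslink \code{data.frame} (see [readCrosslinks()]).
#' @param maxScore Maximum allowed \code{Score}; pairs with \code{NA} scores
#'   are kept.
#' @return The filtered \code{data.frame}.
#' @export
filterCrosslinks <- function(links, maxScore) {
  keep <- is.na(links$Score) | links$Score <= maxScore
  links[keep, , drop = FALSE]
}

#' Map crosslinks onto a structure and score distance satisfaction
#'
#' Computes the Euclidean Calpha-Calpha distance of every claimed pair.
#' Pairs with either end absent from the model are returned with
#' \code{mappable = FALSE} (their satisfaction is undefined); self-pairs are
#' flagged \code{degenerate}.
#'
#' @param structure A [StructureModel-class].
#' @param links Crosslink \code{data.frame} with columns \code{Chain1},
#'   \code{Residue1}, \code{Chain2}, \code{Residue2} (non-empty).
#' @param limit Satisfaction limit in Angstrom; default 27.4, the maximum
#'   Calpha-Calpha reach of BS3.
#' @return \code{data.frame}: the input pairs plus \code{ca_distance},
#'   \code{mappable}, \code{satisfied} (\code{NA} when unmappable),
#'   \code{degenerate} and \code{inter_protein}.
#' @export
mapCrosslinks <- function(structure, links, limit = 27.4) {
  if (!nrow(links)) stop("no links", call. = FALSE)
  stopifnot_scalar(limit, "limit", positive = TRUE)
  r <- residues(structure)
  key <- paste(r$chain, r$resno)
  i1 <- match(paste(links$Chain1, links$Residue1), key)
  i2 <- match(paste(links$Chain2, links$Residue2), key)
  mappable <- !is.na(i1) & !is.na(i2)
  d <- rep(NA_real_, nrow(links))
  d[mappable] <- sqrt((r$x[i1[mappable]] - r$x[i2[mappable]])^2 +
                      (r$y[i1[mappable]] - r$y[i2[mappable]])^2 +
                      (r$z[i1[mappable]] - r$z[i2[mappable]])^2)
  out <- links
  out$ca_distance <- d
  out$mappable <- mappable
  out$satisfied <- ifelse(mappable, d <= limit, NA)
  out$degenerate <- links$Chain1 == links$Chain2 &
    links$Residue1 == links$Residue2
  out$inter_protein <- links$Chain1 != links$Chain2
  out
}

#' Fraction of mappable crosslinks satisfying the distance limit
#'
#' @param records Output of [mapCrosslinks()].
#' @return Named list: \code{fraction_satisfied} (among mappable pairs),
#'   \code{n_satisfied}, \code{n_mappable}, \code{n_total}. All three counts
#'   are always reported because the denominator convention ("observable
#'   residue pairs") varies between studies.
#' @export
satisfactionRate <- function(records) {
  n_map <- sum(records$mappable)
  if (n_map == 0L)
    stop("no mappable crosslink records; satisfaction undefined", call. = FALSE)
  n_sat <- sum(records$satisfied, na.rm = TRUE)
  list(fraction_satisfied = n_sat / n_map,
       n_satisfied = as.integer(n_sat),
       n_mappable = as.integer(n_map),
       n_total = nrow(records))
}

eligible_residues <- function(structure, residueClasses, withinChains) {
  r <- residues(structure)
  resid3 <- RESIDUE_CLASS_MAP[toupper(residueClasses)]
  if (any(is.na(resid3)))
    stop("unknown residue class(es): ",
         paste(residueClasses[is.na(resid3)], collapse = ", "), call. = FALSE)
  keep <- r$resid %in% resid3
  if (!is.null(withinChains)) keep <- keep & r$chain %in% withinChains
  r[keep, , drop = FALSE]
}

#' Random-pair null distribution of Calpha-Calpha distances
#'
#' Draws unordered residue pairs uniformly from the residues of the allowed
#' classes (default: lysines, the crosslinker's main target) and returns
#' their Calpha distances. This is the reference distribution against which
#' the observed crosslink distances are compared. With
#' \code{exhaustive = TRUE} all eligible pairs are enumerated exactly once,
#' deterministically.
#'
#' @param structure A [StructureModel-class].
#' @param residueClasses One-letter residue codes to sample from
#'   (subset of K, S, T, Y).
#' @param n Number of pairs to draw (ignored when \code{exhaustive}).
#' @param withinChains Optional chain subset (e.g. the polymerase chains,
#'   excluding the ligand) restricting both pair ends.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all pairs instead of sampling.
#' @return A [NullDistribution-class].
#' @export
sampleNull <- function(structure, residueClasses = "K", n = 10000,
                       withinChains = NULL, seed = 1, exhaustive = FALSE) {
  el <- eligible_residues(structure, residueClasses, withinChains)
  if (nrow(el) < 2L)
    stop("fewer than 2 eligible residues of class(es) ",
         paste(residueClasses, collapse = ","), call. = FALSE)
  co <- as.matrix(el[, c("x", "y", "z")])
  if (exhaustive) {
    d <- as.numeric(stats::dist(co))
    return(new("NullDistribution", distances = d,
               residueClasses = toupper(residueClasses),
               nSamples = length(d), exhaustive = TRUE, seed = NA_integer_))
  }
  stopifnot_scalar(n, "n", positive = TRUE)
  seed <- check_seed(seed)
  d <- withr::with_seed(seed, {
    i <- sample.int(nrow(el), n, replace = TRUE)
    j <- sample.int(nrow(el) - 1L, n, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # uniform over unordered pairs, no self
    sqrt(rowSums((co[i, , drop = FALSE] - co[j, , drop = FALSE])^2))
  })
  new("NullDistribution", distances = d,
      residueClasses = toupper(residueClasses),
      nSamples = as.integer(n), exhaustive = FALSE, seed = seed)
}

#' Compare observed crosslink distances with the random-pair null
#'
#' Bins both samples on shared edges from 0 to the joint maximum and runs a
#' two-sample Kolmogorov-Smirnov test.
#'
#' @param observed Numeric vector of observed distances (Angstrom).
#' @param null A [NullDistribution-class] (or numeric vector).
#' @param binWidth Histogram bin width in Angstrom.
#' @return List: \code{histogram} (\code{data.frame} with bin edges and both
#'   counts), \code{ks_statistic}, \code{p_value}.
#' @export
compareDistributions <- function(observed, null, binWidth = 2) {
  if (is(null, "NullDistribution")) null <- nullDistances(null)
  if (!length(observed) || !length(null))
    stop("both samples must be non-empty", call. = FALSE)
  stopifnot_scalar(binWidth, "binWidth", positive = TRUE)
  top <- max(observed, null)
  edges <- seq(0, top + binWidth, by = binWidth)
  bin <- function(x) {
    idx <- pmin(pmax(floor(x / binWidth) + 1L, 1L), length(edges) - 1L)
    tabulate(idx, nbins = length(edges) - 1L)
  }
  ks <- suppressWarnings(stats::ks.test(observed, null))
  list(histogram = data.frame(bin_lo = edges[-length(edges)],
                              bin_hi = edges[-1],
                              observed = bin(observed),
                              null = bin(null)),
       ks_statistic = unname(ks$statistic),
       p_value = ks$p.value)
}

#' Localise the binding interface and flag outlier crosslinks
#'
#' For inter-protein crosslinks between a ligand chain and the rest of the
#' complex, collects the structure-side anchor residues and flags a link as
#' an outlier when its anchor Calpha lies farther than \code{clusterLimit}
#' from the centroid of all other anchors (leave-one-out). The remaining
#' anchors are reported as the inferred binding interface. The default limit
#' is two crosslinker reaches plus ~20 Angstrom of ligand width.
#'
#' @param records Output of [mapCrosslinks()].
#' @param structure The [StructureModel-class] the records were mapped on.
#' @param ligandChain Chain ID of the ligand; anchors are the opposite ends.
#' @param clusterLimit Outlier distance threshold in Angstrom.
#' @return List: \code{anchors} (\code{data.frame} with chain, resno,
#'   centroid distance and \code{outlier} flag), \code{interface}
#'   (non-outlier anchor residues), \code{outliers} (flagged anchor residues).
#' @export
interfaceReport <- function(records, structure, ligandChain,
                            clusterLimit = 2 * 27.4 + 20) {
  stopifnot_scalar(clusterLimit, "clusterLimit", positive = TRUE)
  inter <- records[records$inter_protein & records$mappable &
                     (records$Chain1 == ligandChain |
                        records$Chain2 == ligandChain), , drop = FALSE]
  if (nrow(inter) < 2L)
    stop("need at least 2 mappable inter-protein crosslinks; ",
         "structural consistency is undefined for fewer", call. = FALSE)
  lig_is_1 <- inter$Chain1 == ligandChain
  anchor <- data.frame(
    chain = ifelse(lig_is_1, inter$Chain2, inter$Chain1),
    resno = ifelse(lig_is_1, inter$Residue2, inter$Residue1)
  )
  r <- residues(structure)
  idx <- match(paste(anchor$chain, anchor$resno), paste(r$chain, r$resno))
  co <- as.matrix(r[idx, c("x", "y", "z")])
  n <- nrow(co)
  dist_loo <- vapply(seq_len(n), function(i) {
    cen <- colMeans(co[-i, , drop = FALSE])
    sqrt(sum((co[i, ] - cen)^2))
  }, numeric(1))
  anchor$centroid_distance <- dist_loo
  anchor$outlier <- dist_loo > clusterLimit
  list(anchors = anchor,
       interface = unique(anchor[!anchor$outlier, c("chain", "resno")]),
       outliers = unique(anchor[anchor$outlier, c("chain", "resno")]))
}
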