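# Synthetic-data generators. Each emulates one of the experimental designs
# the pipelines consume, returns a SyntheticDataset with the generating
# parameters recorded as ground truth, and is a pure function of
# (parameters, seed): the RNG state is scoped locally with withr::with_seed.

#' Generate a synthetic EMSA titration
#'
#' Emulates a tight-binding gel-shift titration: a fixed concentration of
#' radiolabelled ligand titrated with increasing receptor (polymerase), with
#' the fraction bound given by the Morrison closed form plus additive
#' Gaussian densitometry noise, clipped to \code{[0, 1]}. The defaults mirror
#' the assay design: 1 nM labelled ligand against 1-100 nM polymerase.
#'
#' @param trueKd Ground-truth dissociation constant, nM (> 0).
#' @param ligandTotal Total labelled ligand, nM.
#' @param receptorTotals Receptor concentration series, nM (non-empty).
#' @param noiseSd Gaussian noise standard deviation, fraction-bound units.
#' @param nReplicates Number of technical replicates of the full series.
#' @param seed Integer seed.
#' @return A [SyntheticDataset-class]; \code{payload(x)$titration} is a
#'   titration \code{data.frame} as accepted by [fitKd()].
#' @examples
#' ds <- genTitration(trueKd = 12.6, noiseSd = 0.05, seed = 1)
#' kd(fitKd(payload(ds)$titration))
#' @export
genTitration <- function(trueKd,
                         ligandTotal = 1,
                         receptorTotals = c(1, 2, 5, 10, 20, 50, 100),
                         noiseSd = 0.05,
                         nReplicates = 1,
                         seed = 1) {
  stopifnot_scalar(trueKd, "trueKd", positive = TRUE)
  stopifnot_scalar(ligandTotal, "ligandTotal", positive = TRUE)
  stopifnot_scalar(noiseSd, "noiseSd", nonneg = TRUE)
  stopifnot_scalar(nReplicates, "nReplicates", positive = TRUE)
  seed <- check_seed(seed)
  if (!length(receptorTotals))
    stop("'receptorTotals' must contain at least one concentration",
         call. = FALSE)
  if (any(receptorTotals < 0))
    stop("concentrations must be non-negative", call. = FALSE)

  model <- morrisonFraction(trueKd, receptorTotals, ligandTotal)
  tab <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nReplicates), function(rep) {
      f <- model + stats::rnorm(length(model), 0, noiseSd)
      data.frame(receptor_total_nM = receptorTotals,
                 ligand_total_nM = ligandTotal,
                 fraction_bound = pmin(pmax(f, 0), 1),
                 replicate = rep)
    }))
  })
  new("SyntheticDataset", kind = "titration",
      payload = list(titration = tab),
      truth = list(true_kd = trueKd, ligand_total = ligandTotal,
                   receptor_totals = receptorTotals, noise_sd = noiseSd,
                   n_replicates = nReplicates),
      seed = seed)
}

#' Generate synthetic smFRET efficiency samples
#'
#' Draws apparent FRET efficiencies from a one- or two-component Gaussian
#' mixture. Samples are deliberately not clipped to \code{[0, 1]}: measured
#' apparent efficiencies routinely fall outside that interval through shot
#' noise and background correction.
#'
#' @param components \code{data.frame} (or coercible list of rows) with
#'   columns \code{mean}, \code{sd}, \code{weight}; weights must sum to 1
#'   within 1e-9 and sds must be positive.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @return A [SyntheticDataset-class]; \code{payload(x)$samples} is the
#'   numeric efficiency vector.
#' @examples
#' ds <- genFretSamples(data.frame(mean = c(0.67, 0.40), sd = 0.08,
#'                                 weight = c(0.82, 0.18)), n = 5000, seed = 7)
#' @export
genFretSamples <- function(components, n, seed = 1) {
  components <- as.data.frame(components)
  if (!all(c("mean", "sd", "weight") %in% names(components)))
    stop("'components' needs columns mean, sd, weight", call. = FALSE)
  if (abs(sum(components$weight) - 1) > 1e-9)
    stop("component weights must sum to 1 (within 1e-9)", call. = FALSE)
  if (any(components$sd <= 0))
    stop("component sds must be positive", call. = FALSE)
  stopifnot_scalar(n, "n", positive = TRUE)
  seed <- check_seed(seed)

  samples <- withr::with_seed(seed, {
    idx <- sample.int(nrow(components), n, replace = TRUE,
                      prob = components$weight)
    stats::rnorm(n, components$mean[idx], components$sd[idx])
  })
  new("SyntheticDataset", kind = "fret",
      payload = list(samples = samples),
      truth = list(components = components, n = n),
      seed = seed)
}

#' Generate a toy multi-chain complex with planted crosslinks
#'
#' Builds a minimal Calpha-only structure (residues on a rigid 3-D lattice:
#' 3.8-Angstrom spacing along each chain, chains offset by 10 Angstrom) and a
#' crosslink table in which exactly \code{nSatisfied} residue pairs lie below
#' the distance limit and \code{nViolated} lie above it. All residues are
#' lysines, so the whole structure is eligible for the lysine-based null.
#'
#' @param nChains Number of chains (>= 1); chain IDs A, B, ...
#' @param residuesPerChain Residues per chain (>= 1).
#' @param nSatisfied,nViolated Numbers of planted links below/above the limit.
#' @param limit Distance limit in Angstrom (default: the BS3 maximum
#'   Calpha-Calpha reach, 27.4).
#' @param seed Integer seed.
#' @return A [SyntheticDataset-class]; payload carries \code{structure}
#'   (a [StructureModel-class]) and \code{links} (a crosslink
#'   \code{data.frame} with columns Chain1, Residue1, Chain2, Residue2,
#'   Score); truth records each planted link's true distance.
#' @examples
#' ds <- genToyComplex(2, 20, nSatisfied = 5, nViolated = 2, seed = 3)
#' @export
genToyComplex <- function(nChains = 2, residuesPerChain = 20,
                          nSatisfied = 5, nViolated = 2,
                          limit = 27.4, seed = 1) {
  stopifnot_scalar(nChains, "nChains", positive = TRUE)
  stopifnot_scalar(residuesPerChain, "residuesPerChain", positive = TRUE)
  stopifnot_scalar(nSatisfied, "nSatisfied", nonneg = TRUE)
  stopifnot_scalar(nViolated, "nViolated", nonneg = TRUE)
  stopifnot_scalar(limit, "limit", positive = TRUE)
  seed <- check_seed(seed)

  chains <- LETTERS[seq_len(nChains)]
  res <- expand.grid(resno = seq_len(residuesPerChain), chain = chains,
                     stringsAsFactors = FALSE)
  res <- data.frame(chain = res$chain, resno = res$resno, resid = "LYS",
                    x = 3.8 * (res$resno - 1),
                    y = 10 * (match(res$chain, chains) - 1),
                    z = 0)
  structure <- new("StructureModel", residues = res)

  pairs <- utils::combn(nrow(res), 2)
  d <- sqrt((res$x[pairs[1, ]] - res$x[pairs[2, ]])^2 +
            (res$y[pairs[1, ]] - res$y[pairs[2, ]])^2 +
            (res$z[pairs[1, ]] - res$z[pairs[2, ]])^2)
  sat_pool <- which(d < limit)
  vio_pool <- which(d > limit)
  if (length(sat_pool) < nSatisfied || length(vio_pool) < nViolated)
    stop("requested links exceed the available residue pairs ",
         sprintf("(%d below / %d above the %.1f A limit available)",
                 length(sat_pool), length(vio_pool), limit), call. = FALSE)

  pick <- withr::with_seed(seed, {
    c(if (nSatisfied) sample(sat_pool, nSatisfied),
      if (nViolated) sample(vio_pool, nViolated))
  })
  links <- if (length(pick)) {
    data.frame(Chain1 = res$chain[pairs[1, pick]],
               Residue1 = res$resno[pairs[1, pick]],
               Chain2 = res$chain[pairs[2, pick]],
               Residue2 = res$resno[pairs[2, pick]],
               Score = 0.01)
  } else {
    data.frame(Chain1 = character(), Residue1 = integer(),
               Chain2 = character(), Residue2 = integer(),
               Score = numeric())
  }
  new("SyntheticDataset", kind = "xlinks",
      payload = list(structure = structure, links = links),
      truth = list(limit = limit, distances = d[pick],
                   satisfied = d[pick] < limit,
                   n_satisfied = as.integer(nSatisfied),
                   n_violated = as.integer(nViolated)),
      seed = seed)
}

# Expand one IUPAC symbol to its concrete bases.
iupac_bases <- function(ch) {
  code <- unname(Biostrings::IUPAC_CODE_MAP[toupper(ch)])
  if (is.na(code)) stop("invalid IUPAC symbol: ", ch, call. = FALSE)
  strsplit(code, "")[[1]]
}

validate_iupac <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  if (!length(chars)) stop("empty motif", call. = FALSE)
  for (ch in chars) iupac_bases(ch)
  chars
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

count_motif <- function(pattern, subject) {
  length(Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                  fixed = FALSE))
}

#' Generate a genome with TATA motifs planted upstream of start codons
#'
#' Builds a single-contig genome (FASTA-ready \code{DNAStringSet}) and a gene
#' annotation (\code{GRanges}) with genes alternating between both strands,
#' spaced so that every gene leads its own transcription unit under the
#' default gap threshold. For a chosen fraction of genes, a concrete
#' instantiation of the degenerate motif is planted upstream of the start
#' codon at a spacing drawn from \code{N(spacingMean, spacingSd)} (rounded to
#' integer bp; spacing measured from the motif 3' end to the base immediately
#' preceding the start codon). The rest of each \code{-upstream..+downstream}
#' window is kept motif-free by rejection sampling, so exact recovery by the
#' scanner is a construction guarantee.
#'
#' @param nGenes Number of genes.
#' @param fractionWithMotif Fraction of genes receiving a planted motif; the
#'   planted count is \code{round(fractionWithMotif * nGenes)}.
#' @param spacingMean,spacingSd Spacing distribution in bp.
#' @param motif IUPAC motif string (default the archaeal TATA consensus
#'   \code{"TTTWWAA"}).
#' @param seed Integer seed.
#' @param cdsLength Length of each coding sequence, bp.
#' @param upstream,downstream Extent of the promoter window the generator
#'   keeps motif-free around each start codon.
#' @param intergenic Spacer length between gene blocks, bp (> default TU gap
#'   threshold so each gene is its own unit).
#' @return A [SyntheticDataset-class]; payload carries \code{sequences}
#'   (\code{DNAStringSet}) and \code{genes} (\code{GRanges} with
#'   \code{gene_id}); truth records, per gene, whether a motif was planted,
#'   its spacing and its concrete sequence.
#' @examples
#' ds <- genGenome(nGenes = 10, fractionWithMotif = 0.5, seed = 2)
#' @export
genGenome <- function(nGenes = 46, fractionWithMotif = 26 / 46,
                      spacingMean = 25, spacingSd = 5,
                      motif = "TTTWWAA", seed = 1,
                      cdsLength = 120, upstream = 100, downstream = 50,
                      intergenic = 150) {
  stopifnot_scalar(nGenes, "nGenes", positive = TRUE)
  stopifnot_scalar(fractionWithMotif, "fractionWithMotif", nonneg = TRUE)
  if (fractionWithMotif > 1)
    stop("'fractionWithMotif' must be in [0, 1]", call. = FALSE)
  motif_chars <- validate_iupac(motif)
  m <- length(motif_chars)
  if (m > upstream)
    stop("motif (", m, " bp) is longer than the upstream window (",
         upstream, " bp)", call. = FALSE)
  if (cdsLength < downstream)
    stop("'cdsLength' must be at least 'downstream'", call. = FALSE)
  seed <- check_seed(seed)

  n_plant <- round(fractionWithMotif * nGenes)

  gen <- withr::with_seed(seed, {
    strands <- sample(rep(c("+", "-"), length.out = nGenes))
    planted <- seq_len(nGenes) %in% sample(seq_len(nGenes), n_plant)

    blocks <- vector("list", nGenes)
    info <- vector("list", nGenes)
    for (i in seq_len(nGenes)) {
      d <- NA_integer_
      inst <- NA_character_
      if (planted[i]) {
        repeat {
          d <- as.integer(round(stats::rnorm(1, spacingMean, spacingSd)))
          if (d >= 1 && d + m <= upstream) break
        }
        inst <- paste(vapply(motif_chars,
                             function(ch) sample(iupac_bases(ch), 1), ""),
                      collapse = "")
      }
      # build the -upstream..+downstream window by rejection
      repeat {
        up <- random_dna(upstream)
        if (!is.na(d)) {
          # motif occupies upstream positions (upstream-d-m+1)..(upstream-d)
          substr(up, upstream - d - m + 1L, upstream - d) <- inst
        }
        cds_head <- paste0("ATG", random_dna(downstream - 3L))
        win <- paste0(up, cds_head)
        hits <- count_motif(motif, win)
        want <- if (is.na(d)) 0L else 1L
        if (hits == want) break
      }
      cds_tail <- random_dna(cdsLength - downstream)
      block <- paste0(up, cds_head, cds_tail)  # gene-oriented
      if (strands[i] == "-")
        block <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(block)))
      blocks[[i]] <- block
      info[[i]] <- list(strand = strands[i], distance = d, instance = inst)
    }
    list(blocks = blocks, info = info, strands = strands, planted = planted)
  })

  # assemble contig: [intergenic][block1][intergenic][block2]...[intergenic]
  spacer <- withr::with_seed(seed + 1L, {
    replicate(nGenes + 1L, random_dna(intergenic))
  })
  pieces <- character(2 * nGenes + 1)
  pieces[seq(1, 2 * nGenes + 1, by = 2)] <- spacer
  pieces[seq(2, 2 * nGenes, by = 2)] <- unlist(gen$blocks)
  contig <- paste(pieces, collapse = "")

  block_len <- upstream + cdsLength
  starts <- ends <- integer(nGenes)
  offset <- intergenic
  for (i in seq_len(nGenes)) {
    a <- offset + 1L                      # contig coord of block start
    b <- offset + block_len               # contig coord of block end
    if (gen$strands[i] == "+") {
      starts[i] <- a + upstream
      ends[i] <- b
    } else {
      # block was reverse-complemented: gene-oriented position p maps to
      # contig coordinate b - p + 1
      starts[i] <- a                       # = b - block_len + 1
      ends[i] <- b - upstream
    }
    offset <- offset + block_len + intergenic
  }

  ids <- sprintf("gene%03d", seq_len(nGenes))
  genes <- GenomicRanges::GRanges(
    "contig1", IRanges::IRanges(starts, ends),
    strand = gen$strands, type = "gene", ID = ids, gene_id = ids
  )
  seqs <- Biostrings::DNAStringSet(stats::setNames(contig, "contig1"))

  truth_tab <- data.frame(
    gene_id = ids,
    strand = gen$strands,
    planted = gen$planted,
    distance = vapply(gen$info, function(x) as.integer(x$distance %||% NA), 1L),
    instance = vapply(gen$info, function(x) x$instance %||% NA_character_, "")
  )
  new("SyntheticDataset", kind = "genome",
      payload = list(sequences = seqs, genes = genes),
      truth = list(genes = truth_tab, motif = motif, n_planted = sum(gen$planted),
                   spacing_mean = spacingMean, spacing_sd = spacingSd,
                   upstream = upstream, downstream = downstream),
      seed = seed)
}

#' @describeIn writeDataset Write the payload as plain-text files (TSV /
#'   FASTA / GFF3 / PDB / mmCIF) plus a \code{truth.json} sidecar.
#' @export
setMethod("writeDataset", "SyntheticDataset", function(object, dir, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c()
  p <- object@payload
  switch(object@kind,
    titration = {
      files["titration"] <- file.path(dir, "titration.tsv")
      write_tsv(p$titration, files["titration"])
    },
    fret = {
      files["samples"] <- file.path(dir, "fret_samples.tsv")
      write_tsv(data.frame(efficiency = p$samples), files["samples"])
    },
    xlinks = {
      files["structure"] <- file.path(dir, "complex.pdb")
      writeStructurePDB(p$structure, files["structure"])
      files["structure_cif"] <- file.path(dir, "complex.cif")
      writeStructureCIF(p$structure, files["structure_cif"])
      files["links"] <- file.path(dir, "links.tsv")
      write_tsv(p$links, files["links"])
    },
    genome = {
      files["fasta"] <- file.path(dir, "genome.fasta")
      Biostrings::writeXStringSet(p$sequences, files["fasta"])
      files["gff"] <- file.path(dir, "genes.gff3")
      rtracklayer::export(p$genes, files["gff"], format = "gff3")
    }
  )
  files["truth"] <- file.path(dir, "truth.json")
  tr <- object@truth
  tr$seed <- object@seed
  write_json(tr, files["truth"])
  invisible(files)
})
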