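# Leaderless-promoter analysis: transcription-unit prediction from gene
# annotations, start-codon-anchored window extraction, degenerate TATA motif
# scanning, and spacing summaries.
#
# Coordinate conventions, stated once and used everywhere: GFF3 input is
# 1-based inclusive; window positions are reported relative to the start
# codon with the start codon's first base at +1 and no position 0; spacing
# (distance_to_start) runs from the motif's 3' end to the base immediately
# preceding the start codon, the TATA-to-TSS convention for leaderless
# transcripts whose TSS coincides with the start codon.

#' Read a genome and its gene models
#'
#' Loads a FASTA genome and a GFF3 annotation, keeping \code{gene} features
#' (or \code{CDS} where no \code{gene} features exist) and validating that
#' every feature lies within its contig. The start codon position in gene
#' orientation is the annotated \code{start} for plus-strand genes and the
#' annotated \code{end} for minus-strand genes.
#'
#' @param fasta Path to the genome FASTA.
#' @param gff Path to the GFF3 annotation.
#' @return List with \code{sequences} (\code{DNAStringSet}) and \code{genes}
#'   (\code{GRanges} with a \code{gene_id} metadata column, sorted by contig
#'   and start).
#' @export
readGenomeAndGenes <- function(fasta, gff) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  lines <- readLines(gff)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  if (any(nfield != 9L))
    stop("malformed GFF3 record at line ",
         body[which(nfield != 9L)[1]], ": expected 9 tab-separated fields",
         call. = FALSE)

  gr <- rtracklayer::import(gff, format = "gff3")
  keep_type <- if (any(gr$type == "gene")) "gene" else "CDS"
  gr <- gr[gr$type == keep_type]
  if (!length(gr)) stop("no gene or CDS features in ", gff, call. = FALSE)
  if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
    stop("every gene feature must carry a + or - strand", call. = FALSE)

  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("%s_%d", keep_type, seq_along(gr))
  gr$gene_id <- ids

  bad <- !as.character(GenomicRanges::seqnames(gr)) %in% names(seqs)
  if (any(bad))
    stop("feature ", ids[which(bad)[1]], " refers to contig '",
         as.character(GenomicRanges::seqnames(gr))[which(bad)[1]],
         "' absent from the FASTA", call. = FALSE)
  widths <- stats::setNames(Biostrings::width(seqs),
                            names(seqs))[as.character(GenomicRanges::seqnames(gr))]
  beyond <- GenomicRanges::end(gr) > widths | GenomicRanges::start(gr) < 1L
  if (any(beyond))
    stop("feature ", ids[which(beyond)[1]],
         " extends beyond its contig", call. = FALSE)

  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  list(sequences = seqs, genes = gr[o])
}

#' Group genes into predicted transcription units
#'
#' Consecutive genes on the same contig and strand whose intergenic gap does
#' not exceed \code{maxGap} are merged into one unit; a strand flip always
#' starts a new unit (when \code{requireSameStrand}). The lead gene of a unit
#' is its 5'-most gene in gene orientation: the first (leftmost) gene for
#' plus-strand units, the last (rightmost) for minus-strand units. Every gene
#' belongs to exactly one unit. Same-strand genes that overlap are merged
#' with a warning.
#'
#' @param genes \code{GRanges} of gene models with \code{gene_id}, sorted per
#'   contig (as returned by [readGenomeAndGenes()]).
#' @param maxGap Maximum intergenic gap in bp for co-transcription.
#' @param requireSameStrand Whether a strand flip forces a new unit
#'   (default TRUE; promoters are directional).
#' @return \code{data.frame} with one row per gene: \code{gene_id},
#'   \code{tu}, \code{lead} (is this the unit's lead gene), plus contig,
#'   strand and coordinates.
#' @export
callTranscriptionUnits <- function(genes, maxGap = 50,
                                   requireSameStrand = TRUE) {
  stopifnot_scalar(maxGap, "maxGap", nonneg = TRUE)
  df <- data.frame(
    gene_id = genes$gene_id,
    contig = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes)
  )
  o <- order(df$contig, df$start)
  df <- df[o, , drop = FALSE]

  tu <- integer(nrow(df))
  cur <- 0L
  for (i in seq_len(nrow(df))) {
    new_unit <- i == 1L ||
      df$contig[i] != df$contig[i - 1L] ||
      (requireSameStrand && df$strand[i] != df$strand[i - 1L]) ||
      (df$start[i] - df$end[i - 1L] - 1L) > maxGap
    if (!new_unit && df$start[i] <= df$end[i - 1L])
      warning("overlapping same-strand genes ", df$gene_id[i - 1L], " and ",
              df$gene_id[i], " merged into one unit", call. = FALSE)
    if (new_unit) cur <- cur + 1L
    tu[i] <- cur
  }
  df$tu <- sprintf("tu%03d", tu)
  df$lead <- FALSE
  for (u in split(seq_len(nrow(df)), tu)) {
    lead <- if (df$strand[u[1]] == "-") u[which.max(df$end[u])]
            else u[which.min(df$start[u])]
    df$lead[lead] <- TRUE
  }
  rownames(df) <- NULL
  df
}

#' Extract start-codon-anchored promoter windows
#'
#' For the lead gene of every transcription unit, extracts the gene-oriented
#' sequence from \code{-upstream} to \code{+downstream} relative to the start
#' codon (first codon base at +1, no position 0). Minus-strand windows are
#' the reverse complement of the contig slice. Windows truncated by a contig
#' end are clipped and flagged, never padded.
#'
#' @param tus Output of [callTranscriptionUnits()].
#' @param sequences \code{DNAStringSet} of contigs.
#' @param upstream,downstream Window extent in bp.
#' @return \code{DNAStringSet} named by unit ID, with metadata columns
#'   \code{tu}, \code{gene_id}, \code{strand}, \code{clipped},
#'   \code{up_len} and \code{down_len} (the bases actually present on each
#'   side of the start codon, after any clipping).
#' @export
extractWindows <- function(tus, sequences, upstream = 100, downstream = 50) {
  stopifnot_scalar(upstream, "upstream", positive = TRUE)
  stopifnot_scalar(downstream, "downstream", positive = TRUE)
  leads <- tus[tus$lead, , drop = FALSE]
  out_seq <- character(nrow(leads))
  up_len <- down_len <- integer(nrow(leads))
  clipped <- logical(nrow(leads))
  for (i in seq_len(nrow(leads))) {
    contig <- sequences[[leads$contig[i]]]
    len <- length(contig)
    if (leads$strand[i] == "+") {
      s <- leads$start[i]                       # first base of start codon
      lo <- s - upstream; hi <- s - 1L + downstream
    } else {
      s <- leads$end[i]
      lo <- s - downstream + 1L; hi <- s + upstream
    }
    lo_c <- max(lo, 1L); hi_c <- min(hi, len)
    if (lo_c > len || hi_c < 1L)
      stop("promoter window of unit ", leads$tu[i],
           " lies entirely off contig ", leads$contig[i], call. = FALSE)
    clipped[i] <- lo_c != lo || hi_c != hi
    seq <- Biostrings::subseq(contig, lo_c, hi_c)
    if (leads$strand[i] == "-") seq <- Biostrings::reverseComplement(seq)
    out_seq[i] <- as.character(seq)
    if (leads$strand[i] == "+") {
      up_len[i] <- s - lo_c; down_len[i] <- hi_c - s + 1L
    } else {
      up_len[i] <- hi_c - s; down_len[i] <- s - lo_c + 1L
    }
  }
  res <- Biostrings::DNAStringSet(stats::setNames(out_seq, leads$tu))
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(
    tu = leads$tu, gene_id = leads$gene_id, strand = leads$strand,
    clipped = clipped, up_len = up_len, down_len = down_len)
  res
}

#' Scan promoter windows for a degenerate IUPAC motif
#'
#' Reports every exact degenerate match on the window (coding) strand at
#' every offset, overlapping matches included. The spacing
#' \code{distance_to_start} runs from the motif's 3' end to the base
#' immediately preceding the start codon (positive when the motif is fully
#' upstream).
#'
#' @param windows \code{DNAStringSet} from [extractWindows()].
#' @param pattern IUPAC motif string (default the archaeal TATA consensus
#'   \code{"TTTWWAA"}).
#' @return \code{data.frame} with one row per hit: \code{tu}, \code{offset}
#'   (1-based in the window), \code{match}, \code{distance_to_start}.
#' @export
iupacScan <- function(windows, pattern = "TTTWWAA") {
  validate_iupac(pattern)
  m <- nchar(pattern)
  mc <- S4Vectors::mcols(windows)
  hits <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    mt <- Biostrings::matchPattern(pattern, windows[[i]], fixed = FALSE)
    if (!length(mt)) next
    st <- Biostrings::start(mt)
    hits[[i]] <- data.frame(
      tu = mc$tu[i],
      offset = st,
      match = as.character(mt),
      distance_to_start = as.integer(mc$up_len[i]) - (st + m - 1L)
    )
  }
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits))
    return(data.frame(tu = character(), offset = integer(),
                      match = character(), distance_to_start = integer()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Summarise motif hits across transcription units
#'
#' Reduces hits to one per unit (the hit nearest the start codon, by absolute
#' spacing, ties to the smaller spacing) and reports how many units carry a
#' hit at all, how many carry one inside the expected spacing window, and the
#' spacing mean and standard deviation over the per-unit nearest hits. An
#' empty hit table yields a defined all-zero summary, not an error.
#'
#' @param hits Output of [iupacScan()].
#' @param spacingWindow Length-2 numeric, inclusive spacing window in bp.
#' @param nUnits Optional total number of units scanned (reported back for
#'   "k of n" statements).
#' @return Named list: \code{n_units_with_hit}, \code{n_units_in_window},
#'   \code{spacing_mean}, \code{spacing_sd}, \code{n_units_total},
#'   \code{per_unit} (the reduced one-row-per-unit table).
#' @export
summarizeHits <- function(hits, spacingWindow = c(20, 30), nUnits = NA) {
  if (!nrow(hits))
    return(list(n_units_with_hit = 0L, n_units_in_window = 0L,
                spacing_mean = NA_real_, spacing_sd = NA_real_,
                n_units_total = nUnits,
                per_unit = data.frame(tu = character(),
                                      distance_to_start = integer())))
  nearest <- do.call(rbind, lapply(split(hits, hits$tu), function(h) {
    h <- h[order(abs(h$distance_to_start), h$distance_to_start), , drop = FALSE]
    h[1, , drop = FALSE]
  }))
  rownames(nearest) <- NULL
  in_win <- vapply(split(hits, hits$tu), function(h) {
    any(h$distance_to_start >= spacingWindow[1] &
        h$distance_to_start <= spacingWindow[2])
  }, TRUE)
  list(n_units_with_hit = length(unique(hits$tu)),
       n_units_in_window = sum(in_win),
       spacing_mean = mean(nearest$distance_to_start),
       spacing_sd = stats::sd(nearest$distance_to_start),
       n_units_total = nUnits,
       per_unit = nearest)
}

#' Position frequency matrix of a window set
#'
#' Per-position base frequencies over equal-length windows (clipped windows
#' are excluded), a WebLogo-compatible summary for visualising the promoter
#' alignment.
#'
#' @param windows \code{DNAStringSet} from [extractWindows()].
#' @return Matrix with rows A, C, G, T and one column per window position.
#' @export
positionFrequencyMatrix <- function(windows) {
  mc <- S4Vectors::mcols(windows)
  full <- windows[!mc$clipped]
  if (!length(full)) stop("no unclipped windows", call. = FALSE)
  cm <- Biostrings::consensusMatrix(full, baseOnly = TRUE)
  cm[c("A", "C", "G", "T"), , drop = FALSE]
}
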