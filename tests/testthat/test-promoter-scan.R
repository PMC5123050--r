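# The generator's genomes carry full ground truth, so most checks here are
# exact-recovery assertions; coordinate arithmetic is additionally verified
# against direct string slicing.

local_genome <- function(nGenes = 10, fraction = 0.5, seed = 21, ...) {
  ds <- genGenome(nGenes = nGenes, fractionWithMotif = fraction, seed = seed, ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  files <- writeDataset(ds, dir)
  list(ds = ds, files = files,
       gg = readGenomeAndGenes(files[["fasta"]], files[["gff"]]))
}

test_that("genome reading validates annotation against the FASTA", {
  g <- local_genome()
  expect_equal(length(g$gg$genes), 10)
  # minus-strand start codon position is the annotated end coordinate
  minus <- g$gg$genes[as.character(GenomicRanges::strand(g$gg$genes)) == "-"]
  expect_gt(length(minus), 0)

  dir <- withr::local_tempdir()
  # malformed GFF line -> error with line number
  bad_gff <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3", "contig1\tx\tgene\t1\t50"), bad_gff)
  expect_error(readGenomeAndGenes(g$files[["fasta"]], bad_gff), "line 2")
  # coordinate beyond contig -> error naming the feature
  over_gff <- file.path(dir, "over.gff3")
  writeLines(c("##gff-version 3",
               paste("contig1", ".", "gene", "10", "99999999", ".", "+", ".",
                     "ID=geneX", sep = "\t")), over_gff)
  expect_error(readGenomeAndGenes(g$files[["fasta"]], over_gff),
               "geneX.*beyond")
  # unknown contig -> error naming the feature
  wrong_gff <- file.path(dir, "wrong.gff3")
  writeLines(c("##gff-version 3",
               paste("nope", ".", "gene", "10", "50", ".", "+", ".",
                     "ID=geneY", sep = "\t")), wrong_gff)
  expect_error(readGenomeAndGenes(g$files[["fasta"]], wrong_gff),
               "geneY.*absent")
})

test_that("transcription-unit calling merges by gap and splits on strand flips", {
  gr <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(1, 121, 300, 400), c(100, 220, 380, 480)),
    strand = c("+", "+", "+", "-"), gene_id = paste0("g", 1:4))
  tus <- callTranscriptionUnits(gr, maxGap = 50)
  # g1-g2 gap 20 -> merged; g2-g3 gap 79 -> split; g4 strand flip -> split
  expect_equal(length(unique(tus$tu)), 3)
  expect_equal(tus$tu[1], tus$tu[2])
  expect_true(tus$lead[1])                       # + unit leads with leftmost
  expect_false(tus$lead[2])
  expect_true(tus$lead[4])
  # partition: every gene in exactly one unit
  expect_equal(sum(table(tus$gene_id)), 4)
  # minus-strand unit leads with its rightmost gene
  grm <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(1, 121), c(100, 220)),
    strand = "-", gene_id = c("m1", "m2"))
  tum <- callTranscriptionUnits(grm, maxGap = 50)
  expect_equal(tum$gene_id[tum$lead], "m2")
  # overlapping same-strand genes merge with a warning
  gro <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(1, 50), c(100, 150)), strand = "+",
    gene_id = c("o1", "o2"))
  expect_warning(tuo <- callTranscriptionUnits(gro, maxGap = 10), "overlapping")
  expect_equal(length(unique(tuo$tu)), 1)
})

test_that("promoter windows agree with an independent slicing oracle", {
  g <- local_genome(nGenes = 8, fraction = 0.5, seed = 31)
  tus <- callTranscriptionUnits(g$gg$genes)
  win <- extractWindows(tus, g$gg$sequences)
  contig <- as.character(g$gg$sequences[[1]])
  leads <- tus[tus$lead, ]
  for (i in seq_len(nrow(leads))) {
    if (leads$strand[i] == "+") {
      s <- leads$start[i]
      oracle <- substr(contig, s - 100, s + 49)
    } else {
      e <- leads$end[i]
      slice <- substr(contig, e - 49, e + 100)
      oracle <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(slice)))
    }
    expect_equal(as.character(win[[which(names(win) == leads$tu[i])]]), oracle,
                 label = leads$tu[i])
    # start codon sits at +1..+3 in window orientation
    expect_equal(substr(oracle, 101, 103), "ATG")
  }
})

test_that("windows clipped by a contig end are truncated and flagged", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  writeLines(c(">c1", strrep("ACGT", 100)), fa)  # 400 bp
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3",
               paste("c1", ".", "gene", "31", "150", ".", "+", ".",
                     "ID=gA", sep = "\t"),
               paste("c1", ".", "gene", "240", "390", ".", "-", ".",
                     "ID=gB", sep = "\t")), gff)
  gg <- readGenomeAndGenes(fa, gff)
  tus <- callTranscriptionUnits(gg$genes)
  win <- extractWindows(tus, gg$sequences)
  mc <- S4Vectors::mcols(win)
  expect_true(all(mc$clipped))
  expect_equal(mc$up_len[mc$gene_id == "gA"], 30)    # only 30 bp upstream exist
  expect_equal(Biostrings::width(win)[mc$gene_id == "gA"], 80)
  expect_equal(mc$up_len[mc$gene_id == "gB"], 10)    # 400 - 390
})

test_that("degenerate motif scanning equals a brute-force position oracle", {
  # definition of W
  w1 <- Biostrings::DNAStringSet(c(tuX = "GGTTTATAAGG"))
  S4Vectors::mcols(w1) <- S4Vectors::DataFrame(tu = "tuX", up_len = 11L)
  hits <- iupacScan(w1, "TTTWWAA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 3)
  w0 <- Biostrings::DNAStringSet(c(tuY = "GGTTTGGAAGG"))
  S4Vectors::mcols(w0) <- S4Vectors::DataFrame(tu = "tuY", up_len = 11L)
  expect_equal(nrow(iupacScan(w0, "TTTWWAA")), 0)
  expect_error(iupacScan(w1, "TTTXZAA"), "invalid IUPAC")

  # overlapping matches, random sequences: exact agreement with brute force
  withr::with_seed(5, {
    for (i in 1:25) {
      seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                          prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
      ws <- Biostrings::DNAStringSet(stats::setNames(seq, "t"))
      S4Vectors::mcols(ws) <- S4Vectors::DataFrame(tu = "t", up_len = 200L)
      expect_equal(iupacScan(ws, "TTTWWAA")$offset,
                   brute_force_iupac_hits(seq, "TTTWWAA"))
    }
  })
})

test_that("planted motifs are recovered exactly, including on the minus strand", {
  g <- local_genome(nGenes = 46, fraction = 26 / 46, seed = 2)
  tus <- callTranscriptionUnits(g$gg$genes)
  expect_equal(length(unique(tus$tu)), 46)
  win <- extractWindows(tus, g$gg$sequences)
  hits <- iupacScan(win)
  summ <- summarizeHits(hits, nUnits = length(win))
  tr <- truth(g$ds)$genes
  expect_equal(summ$n_units_with_hit, 26)
  # per-gene offsets equal the generator truth exactly, both strands
  merged <- merge(merge(summ$per_unit, tus[tus$lead, c("tu", "gene_id")],
                        by = "tu"),
                  tr, by = "gene_id")
  expect_equal(nrow(merged), 26)
  expect_identical(merged$distance_to_start, merged$distance)
  expect_true(any(merged$strand == "-") && any(merged$strand == "+"))
  expect_equal(summ$spacing_mean, mean(tr$distance, na.rm = TRUE))
})

test_that("a motif-free genome yields zero hits and a defined empty summary", {
  g <- local_genome(nGenes = 6, fraction = 0, seed = 13)
  tus <- callTranscriptionUnits(g$gg$genes)
  hits <- iupacScan(extractWindows(tus, g$gg$sequences))
  expect_equal(nrow(hits), 0)
  summ <- summarizeHits(hits, nUnits = 6)
  expect_equal(summ$n_units_with_hit, 0L)
  expect_equal(summ$n_units_in_window, 0L)
  expect_true(is.na(summ$spacing_mean))
})

test_that("spacing statistics use the hit nearest the start codon", {
  hits <- data.frame(tu = c("t1", "t1", "t2"), offset = c(10, 70, 20),
                     match = "TTTATAA", distance_to_start = c(80L, 22L, 25L))
  summ <- summarizeHits(hits, spacingWindow = c(20, 30), nUnits = 2)
  expect_equal(summ$n_units_with_hit, 2L)
  expect_equal(summ$n_units_in_window, 2L)
  expect_equal(summ$per_unit$distance_to_start[summ$per_unit$tu == "t1"], 22L)
  expect_equal(summ$spacing_mean, mean(c(22, 25)))
})

test_that("reverse-complementing the genome leaves windows and hits unchanged", {
  g <- local_genome(nGenes = 10, fraction = 0.6, seed = 17)
  seqs <- g$gg$sequences
  genes <- g$gg$genes
  # flip the world: revcomp contig, mirror coordinates, flip strands
  L <- Biostrings::width(seqs)[1]
  rc <- Biostrings::reverseComplement(seqs)
  names(rc) <- names(seqs)
  flipped <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(genes)),
    IRanges::IRanges(L - GenomicRanges::end(genes) + 1,
                     L - GenomicRanges::start(genes) + 1),
    strand = ifelse(as.character(GenomicRanges::strand(genes)) == "+", "-", "+"),
    gene_id = genes$gene_id)
  o <- order(GenomicRanges::start(flipped))
  flipped <- flipped[o]

  t1 <- callTranscriptionUnits(genes)
  t2 <- callTranscriptionUnits(flipped)
  w1 <- extractWindows(t1, seqs)
  w2 <- extractWindows(t2, rc)
  m1 <- S4Vectors::mcols(w1); m2 <- S4Vectors::mcols(w2)
  k1 <- order(m1$gene_id); k2 <- order(m2$gene_id)
  expect_identical(unname(as.character(w1)[k1]), unname(as.character(w2)[k2]))
  h1 <- iupacScan(w1); h2 <- iupacScan(w2)
  s1 <- summarizeHits(h1, nUnits = 10); s2 <- summarizeHits(h2, nUnits = 10)
  expect_equal(s1$n_units_with_hit, s2$n_units_with_hit)
  expect_equal(s1$spacing_mean, s2$spacing_mean)
})

test_that("position frequency matrix summarises unclipped windows", {
  g <- local_genome(nGenes = 8, fraction = 1, seed = 19)
  win <- extractWindows(callTranscriptionUnits(g$gg$genes), g$gg$sequences)
  pfm <- positionFrequencyMatrix(win)
  expect_equal(dim(pfm), c(4, 150))
  expect_true(all(colSums(pfm) == 8))
  # the start codon column is all-A at +1 (ATG)
  expect_equal(unname(pfm["A", 101]), 8)
  expect_equal(unname(pfm["T", 102]), 8)
  expect_equal(unname(pfm["G", 103]), 8)
})
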