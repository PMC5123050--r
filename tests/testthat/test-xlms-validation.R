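# Fixtures: toy complexes come from the generator; hand-written PDB text is
# used where the parsing rules themselves are under test.

write_pdb_lines <- function(lines, path) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom <- function(serial, elety, alt, resid, chain, resno, x, y, z, occ = 1) {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, elety, alt, resid, chain, resno, x, y, z, occ, 0)
}

test_that("structure parsing applies the Calpha / model-1 / altloc rules", {
  dir <- withr::local_tempdir()

  # residue 2 lacks a Calpha -> dropped with a warning
  p1 <- write_pdb_lines(c(
    pdb_atom(1, "CA", " ", "LYS", "A", 1, 0, 0, 0),
    pdb_atom(2, "CB", " ", "LYS", "A", 2, 1, 1, 1),
    pdb_atom(3, "CA", " ", "SER", "A", 3, 2, 0, 0)
  ), file.path(dir, "noca.pdb"))
  expect_warning(st <- readStructure(p1), "lack a Calpha")
  expect_equal(residues(st)$resno, c(1, 3))

  # multi-model: only model 1 retained
  p2 <- file.path(dir, "multi.pdb")
  writeLines(c("MODEL     1",
               pdb_atom(1, "CA", " ", "LYS", "A", 1, 0, 0, 0),
               "ENDMDL",
               "MODEL     2",
               pdb_atom(1, "CA", " ", "LYS", "A", 1, 50, 50, 50),
               "ENDMDL", "END"), p2)
  st2 <- readStructure(p2)
  expect_equal(nrow(residues(st2)), 1)
  expect_equal(residues(st2)$x, 0)

  # altloc: highest occupancy wins; tie goes to altloc A
  p3 <- write_pdb_lines(c(
    pdb_atom(1, "CA", "A", "LYS", "A", 1, 1, 0, 0, occ = 0.4),
    pdb_atom(2, "CA", "B", "LYS", "A", 1, 9, 0, 0, occ = 0.6),
    pdb_atom(3, "CA", "B", "LYS", "A", 2, 7, 0, 0, occ = 0.5),
    pdb_atom(4, "CA", "A", "LYS", "A", 2, 3, 0, 0, occ = 0.5)
  ), file.path(dir, "alt.pdb"))
  st3 <- readStructure(p3)
  expect_equal(residues(st3)$x, c(9, 3))

  # no Calpha at all -> error; unknown chain in map -> error
  p4 <- write_pdb_lines(pdb_atom(1, "CB", " ", "LYS", "A", 1, 0, 0, 0),
                        file.path(dir, "none.pdb"))
  expect_error(suppressWarnings(readStructure(p4)), "no Calpha")
  xds <- genToyComplex(2, 5, 1, 0, seed = 1)
  pf <- writeDataset(xds, file.path(dir, "toy"))
  expect_error(readStructure(pf[["structure"]], chainMap = c(RNAP = "Z")),
               "absent from structure")
})

test_that("crosslink mapping computes exact distances and handles edge pairs", {
  st <- StructureModel(data.frame(
    chain = c("A", "A", "B"), resno = c(1, 2, 1), resid = "LYS",
    x = c(0, 10, 0), y = c(0, 0, 3), z = c(0, 0, 4)))
  links <- data.frame(
    Chain1 = c("A", "A", "A", "A"), Residue1 = c(1, 1, 1, 1),
    Chain2 = c("A", "B", "A", "C"), Residue2 = c(2, 1, 1, 9), Score = NA)
  rec <- mapCrosslinks(st, links, limit = 27.4)
  expect_equal(rec$ca_distance[1], 10)
  expect_equal(rec$ca_distance[2], 5)        # 3-4-5 triangle
  expect_true(rec$satisfied[1])
  expect_true(rec$degenerate[3])
  expect_equal(rec$ca_distance[3], 0)
  expect_false(rec$mappable[4])
  expect_true(is.na(rec$satisfied[4]))
  expect_true(rec$inter_protein[2])
  expect_false(rec$inter_protein[1])
})

test_that("distance computation is symmetric in the pair ends", {
  ds <- genToyComplex(2, 20, 6, 2, seed = 2)
  st <- payload(ds)$structure
  links <- payload(ds)$links
  swapped <- data.frame(Chain1 = links$Chain2, Residue1 = links$Residue2,
                        Chain2 = links$Chain1, Residue2 = links$Residue1,
                        Score = links$Score)
  expect_identical(mapCrosslinks(st, links)$ca_distance,
                   mapCrosslinks(st, swapped)$ca_distance)
})

test_that("satisfaction rate reports construction truth and all three counts", {
  ds <- genToyComplex(2, 20, 5, 2, seed = 3)
  rec <- mapCrosslinks(payload(ds)$structure, payload(ds)$links)
  rate <- satisfactionRate(rec)
  expect_equal(rate$fraction_satisfied, 5 / 7)
  expect_equal(rate$n_mappable, 7)
  expect_equal(rate$n_total, 7)
  # all satisfied
  all_sat <- genToyComplex(2, 20, 4, 0, seed = 4)
  rec2 <- mapCrosslinks(payload(all_sat)$structure, payload(all_sat)$links)
  expect_equal(satisfactionRate(rec2)$fraction_satisfied, 1.0)
  # none mappable -> error
  rec$mappable[] <- FALSE
  expect_error(satisfactionRate(rec), "no mappable")
})

test_that("upstream score filtering precedes every statistic", {
  ds <- genToyComplex(2, 20, 5, 2, seed = 3)
  links <- payload(ds)$links
  links$Score <- c(rep(0.01, 5), 0.2, 0.2)   # the two violated links score badly
  kept <- filterCrosslinks(links, maxScore = 0.05)
  expect_equal(nrow(kept), 5)
  rec <- mapCrosslinks(payload(ds)$structure, kept)
  expect_equal(satisfactionRate(rec)$n_total, 5)
})

test_that("duplicate a-b / b-a pairs collapse on read", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "links.tsv")
  writeLines(c("Chain1\tResidue1\tChain2\tResidue2\tScore",
               "B\t5\tA\t1\t0.01",
               "A\t1\tB\t5\t0.01",
               "A\t2\tA\t9\t0.02"), path)
  lk <- readCrosslinks(path)
  expect_equal(nrow(lk), 2)
  expect_equal(lk$Chain1[1], "A")   # canonical order
  expect_true(lk$inter_protein[1])
  expect_false(lk$inter_protein[2])
})

test_that("sampled null matches exhaustive enumeration on a small structure", {
  ds <- genToyComplex(2, 15, 0, 0, seed = 5)   # 30 lysines
  st <- payload(ds)$structure
  ex <- sampleNull(st, exhaustive = TRUE)
  expect_true(ex@exhaustive)
  expect_equal(ex@nSamples, choose(30, 2))
  # exhaustive mode is deterministic
  expect_identical(nullDistances(ex),
                   nullDistances(sampleNull(st, exhaustive = TRUE)))
  sm <- sampleNull(st, n = 10000, seed = 1)
  ks <- suppressWarnings(stats::ks.test(nullDistances(sm), nullDistances(ex)))
  expect_lt(unname(ks$statistic), 0.05)
  expect_lt(abs(mean(nullDistances(sm)) - mean(nullDistances(ex))),
            3 * sd(nullDistances(ex)) / sqrt(10000) * 5)
})

test_that("null sampling respects residue classes and chain restriction", {
  r <- residues(payload(genToyComplex(2, 10, 0, 0, seed = 1))$structure)
  r$resid[r$chain == "B"] <- "SER"
  st <- StructureModel(r)
  expect_error(sampleNull(st, residueClasses = "Y", n = 10),
               "fewer than 2 eligible")
  expect_error(sampleNull(st, residueClasses = "Q", n = 10), "unknown residue")
  only_a <- sampleNull(st, residueClasses = "K", n = 500, seed = 2,
                       withinChains = "A")
  # chain A residues are collinear at 3.8 A spacing: all distances multiples
  expect_true(all(abs(nullDistances(only_a) / 3.8 -
                        round(nullDistances(only_a) / 3.8)) < 1e-9))
  with_ser <- sampleNull(st, residueClasses = c("K", "S"), n = 500, seed = 2)
  expect_gt(max(nullDistances(with_ser)), max(nullDistances(only_a)))
})

test_that("distribution comparison separates disjoint samples and validates input", {
  obs <- runif(50, 5, 20)
  null <- new("NullDistribution", distances = runif(500, 60, 100),
              residueClasses = "K", nSamples = 500L, exhaustive = FALSE,
              seed = 1L)
  out <- compareDistributions(obs, null, binWidth = 5)
  expect_gt(out$ks_statistic, 0.99)
  expect_lt(out$p_value, 1e-10)
  expect_equal(sum(out$histogram$observed), 50)
  expect_equal(sum(out$histogram$null), 500)
  expect_error(compareDistributions(obs, null, binWidth = 0), "binWidth")
  expect_error(compareDistributions(numeric(), null), "non-empty")
})

test_that("observed samples drawn from the null give calibrated KS p-values", {
  ds <- genToyComplex(3, 12, 0, 0, seed = 6)
  st <- payload(ds)$structure
  ex <- nullDistances(sampleNull(st, exhaustive = TRUE))
  pvals <- vapply(1:10, function(i) {
    obs <- withr::with_seed(i, sample(ex, 40, replace = TRUE))
    compareDistributions(obs, sampleNull(st, n = 4000, seed = 100 + i))$p_value
  }, numeric(1))
  # under the null, p-values should not pile up at zero
  expect_gt(median(pvals), 0.05)
  expect_gt(max(pvals), 0.3)
})

test_that("interface report flags exactly the planted distal anchor", {
  fx <- make_interface_fixture()
  rec <- mapCrosslinks(fx$structure, fx$links, limit = 100)
  rep <- interfaceReport(rec, fx$structure, ligandChain = "L",
                         clusterLimit = 40)
  expect_equal(nrow(rep$outliers), 1)
  expect_equal(rep$outliers$resno, 7)
  expect_equal(sort(rep$interface$resno), 1:6)
  # all anchors coincident -> no outliers
  co <- residues(fx$structure)
  co[co$chain == "P", c("x", "y", "z")] <- 0
  rec2 <- mapCrosslinks(StructureModel(co), fx$links, limit = 100)
  rep2 <- interfaceReport(rec2, StructureModel(co), ligandChain = "L")
  expect_equal(nrow(rep2$outliers), 0)
  # a single inter-protein link is rejected
  expect_error(interfaceReport(rec[1, ], fx$structure, ligandChain = "L"),
               "at least 2")
})

test_that("rigid-body motion leaves distances, rates and outlier calls unchanged", {
  ds <- genToyComplex(2, 20, 5, 2, seed = 7)
  st <- payload(ds)$structure
  links <- payload(ds)$links
  st2 <- rigid_transform(st)
  r1 <- mapCrosslinks(st, links)
  r2 <- mapCrosslinks(st2, links)
  expect_equal(r1$ca_distance, r2$ca_distance, tolerance = 1e-6)
  expect_identical(r1$satisfied, r2$satisfied)
  expect_equal(satisfactionRate(r1)$fraction_satisfied,
               satisfactionRate(r2)$fraction_satisfied)
  fx <- make_interface_fixture()
  fx2 <- rigid_transform(fx$structure)
  rep1 <- interfaceReport(mapCrosslinks(fx$structure, fx$links, limit = 100),
                          fx$structure, "L", clusterLimit = 40)
  rep2 <- interfaceReport(mapCrosslinks(fx2, fx$links, limit = 100),
                          fx2, "L", clusterLimit = 40)
  expect_identical(rep1$outliers$resno, rep2$outliers$resno)
})
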