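# Independent oracles and fixture builders used across the suite.

# Numerical solve of the 1:1 mass-action equilibrium by bisection on the
# complex concentration C in [0, min(R, L)]: (R - C)(L - C) = Kd * C.
# Independent of the closed form it checks.
bisect_fraction_bound <- function(kd, receptor, ligand, tol = 1e-14) {
  if (receptor == 0 || ligand == 0) return(0)
  f <- function(cc) (receptor - cc) * (ligand - cc) - kd * cc
  lo <- 0
  hi <- min(receptor, ligand)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  ((lo + hi) / 2) / ligand
}

# Position-by-position degenerate match count, no regex, no Biostrings.
brute_force_iupac_hits <- function(seq, pattern) {
  expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
              S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
              H = "ACT", V = "ACG", N = "ACGT")
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  m <- length(p)
  hits <- integer()
  if (length(s) < m) return(hits)
  for (off in 1:(length(s) - m + 1)) {
    ok <- TRUE
    for (j in 1:m) {
      if (!grepl(s[off + j - 1], expand[[p[j]]], fixed = TRUE)) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# Apply a rigid-body transform (rotation about an arbitrary axis plus
# translation) to every coordinate of a StructureModel.
rigid_transform <- function(structure, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(11, -4, 30)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  r <- residues(structure)
  xyz <- as.matrix(r[, c("x", "y", "z")]) %*% t(R)
  r$x <- xyz[, 1] + shift[1]
  r$y <- xyz[, 2] + shift[2]
  r$z <- xyz[, 3] + shift[3]
  StructureModel(r)
}

# A cluster of inter-protein crosslink anchors plus one distal anchor,
# mirroring the six consistent interface links + one artefact topology.
make_interface_fixture <- function() {
  # ligand chain L at origin; anchors on chain P
  anchors <- data.frame(
    chain = "P", resno = 1:7, resid = "LYS",
    x = c(0, 5, -5, 3, -3, 6, 80),   # residue 7 is 80 A away
    y = c(0, 3, 2, -4, 5, -2, 5),
    z = c(0, 1, -2, 2, 3, -1, 0))
  ligand <- data.frame(chain = "L", resno = 1:7, resid = "LYS",
                       x = anchors$x + 2, y = anchors$y, z = anchors$z)
  structure <- StructureModel(rbind(anchors, ligand))
  links <- data.frame(Chain1 = "L", Residue1 = 1:7,
                      Chain2 = "P", Residue2 = 1:7, Score = 0.01)
  list(structure = structure, links = links)
}

# Seeds for multi-seed stochastic checks, fixed for the suite.
SUITE_SEEDS <- 1:20
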