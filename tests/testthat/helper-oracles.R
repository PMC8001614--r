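# Independent oracles used to check the package's geometric computations.
# These deliberately use naive algorithms (union-find, all-pairs scans,
# Monte-Carlo integration) distinct from the implementation paths.

# Connected components by union-find over an explicit edge scan.
oracle_components <- function(keys, xyz, cutoff) {
  n <- length(keys)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(keys, roots))
}

# Canonical form of a residue-set partition for comparison.
canonical_partition <- function(patches) {
  sorted <- lapply(patches, sort)
  sorted[order(vapply(sorted, `[`, "", 1L))]
}

# Gap detection by brute-force set membership scan.
oracle_gaps <- function(present_resno, start, end) {
  missing <- c()
  runs <- list()
  run <- NULL
  for (no in start:end) {
    if (!(no %in% present_resno)) {
      if (is.null(run)) run <- c(no, no) else run[2] <- no
    } else if (!is.null(run)) {
      runs[[length(runs) + 1]] <- run; run <- NULL
    }
  }
  if (!is.null(run)) runs[[length(runs) + 1]] <- run
  runs
}

# Monte-Carlo per-atom SASA estimate with uniform random sphere points;
# returns estimate and its standard error.
oracle_sasa_mc <- function(xyz, ext, i, n_mc = 20000) {
  v <- matrix(rnorm(3 * n_mc), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  pts <- sweep(v * ext[i], 2, xyz[i, ], `+`)
  exposed <- rep(TRUE, n_mc)
  for (j in seq_len(nrow(xyz))[-i]) {
    d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
    exposed <- exposed & (d2 > ext[j]^2)
  }
  p <- mean(exposed)
  area <- 4 * pi * ext[i]^2
  list(sasa = p * area, se = sqrt(p * (1 - p) / n_mc) * area)
}

# Exposed area of two intersecting solvent-extended spheres (closed form):
# each sphere loses the cap beyond the radical plane.
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  x2 <- d - x1
  a1 <- 4 * pi * r1^2 - 2 * pi * r1 * (r1 - x1)
  a2 <- 4 * pi * r2^2 - 2 * pi * r2 * (r2 - x2)
  a1 + a2
}

# Brute-force O(n^2) smoothed-hydropathy oracle over surface residues.
oracle_smooth_kd <- function(xyz, raw, radius) {
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- c()
    for (j in seq_len(n)) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= radius) acc <- c(acc, raw[j])
    }
    out[i] <- mean(acc)
  }
  out
}

# Hand-built single-residue structure models for geometric toys.
toy_model <- function(xyz, elesy = "C", resid = "ALA", chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  elesy <- rep_len(elesy, n)
  StructureModel(data.frame(
    chain = rep_len(chain, n), resno = seq_len(n), icode = "",
    resid = rep_len(resid, n), elety = elesy, elesy = elesy,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  ), entry_id = "toy")
}

# Vertices of a regular icosahedron on the unit sphere.
icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  v / sqrt(1 + phi^2)
}

minimal_ala_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.456   7.323  -4.874  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      12.897   8.007  -5.796  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      12.477   4.829  -4.962  1.00  0.00           C",
    "END"), path)
  path
}
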