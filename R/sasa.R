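#' Deterministic quasi-uniform points on the unit sphere
#'
#' Fibonacci (golden-angle) lattice, so surface areas are reproducible
#' without a random seed.
#'
#' @param n number of points.
#' @return `n` x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Reference maximal accessible surface areas
#'
#' Per-residue-type maximal accessible areas (Angstrom^2) used to normalize
#' SASA into relative solvent accessibility. Two published normalization
#' tables are provided: the empirical Rost & Sander (1994) table (default,
#' the lineage behind the RSA >= 20% surface convention) and the theoretical
#' Tien et al. (2013) table.
#'
#' @param table `"RostSander1994"` or `"Tien2013"`.
#' @return named numeric vector over the 20 standard residue types, with the
#'   table identity in attribute `"table"`.
#' @export
max_asa <- function(table = c("RostSander1994", "Tien2013")) {
  table <- match.arg(table)
  vals <- switch(table,
    RostSander1994 = c(
      ALA = 106, ARG = 248, ASN = 157, ASP = 163, CYS = 135,
      GLN = 198, GLU = 194, GLY = 84,  HIS = 184, ILE = 169,
      LEU = 164, LYS = 205, MET = 188, PHE = 197, PRO = 136,
      SER = 130, THR = 142, TRP = 227, TYR = 222, VAL = 142),
    Tien2013 = c(
      ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
      GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
      LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
      SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
  )
  attr(vals, "table") <- table
  vals
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' For every heavy atom, test points are spread quasi-uniformly on its
#' solvent-extended sphere (van der Waals radius + probe radius); the
#' accessible area is the fraction of points not inside any other atom's
#' solvent-extended sphere times the sphere area. Residue SASA is the sum
#' over its atoms.
#'
#' With `occluder_scope = "complex"` every atom of the model occludes
#' (binding partners bury their interface); with `"chain_only"` occluders
#' are restricted to the reported residue's own chain. When `chain` is given
#' only that chain's residues are reported.
#'
#' @param model a [StructureModel()].
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_points test points per atom (>= 32).
#' @param occluder_scope `"complex"` or `"chain_only"`.
#' @param chain optional chain id restricting the reported residues.
#' @return an object of class `SasaTable`: a data.frame with one row per
#'   reported polymer residue (`key`, `chain`, `resno`, `icode`, `resid`,
#'   `std_resid`, `n_atoms`, `sasa`, `rsa` = `NA` until [compute_rsa()]),
#'   with the computation parameters in attributes `probe_radius`,
#'   `n_points` and `occluder_scope`.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                         occluder_scope = c("complex", "chain_only"),
                         chain = NULL) {
  occluder_scope <- match.arg(occluder_scope)
  stopifnot(probe_radius > 0, n_points >= 32)
  a <- model$atoms
  rt <- residue_table(model)
  if (!is.null(chain)) {
    if (!chain %in% rt$chain) stop("unknown chain: ", chain)
    rt <- rt[rt$chain == chain, , drop = FALSE]
  }

  target <- !a$het & (if (is.null(chain)) TRUE else a$chain == chain)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ext <- a$vdw + probe_radius
  sphere <- fibonacci_sphere(n_points)

  occ_pool <- if (occluder_scope == "complex") seq_len(nrow(a)) else NULL
  nb <- neighbor_lists(xyz, ext)

  atom_area <- numeric(nrow(a))
  for (i in which(target)) {
    cand <- nb(i)
    if (occluder_scope == "chain_only")
      cand <- cand[a$chain[cand] == a$chain[i]]
    cand <- cand[cand != i]
    pts <- sphere * ext[i]
    pts <- cbind(pts[, 1] + xyz[i, 1], pts[, 2] + xyz[i, 2],
                 pts[, 3] + xyz[i, 3])
    exposed <- rep(TRUE, n_points)
    for (j in cand) {
      if (!any(exposed)) break
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & (d2 > ext[j]^2)
    }
    atom_area[i] <- sum(exposed) / n_points * 4 * pi * ext[i]^2
  }

  sums <- tapply(atom_area[target], a$key[target], sum)
  out <- rt
  out$sasa <- unname(sums[out$key])
  out$sasa[is.na(out$sasa)] <- 0
  out$rsa <- NA_real_
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_points") <- n_points
  attr(out, "occluder_scope") <- occluder_scope
  class(out) <- c("SasaTable", class(out))
  out
}

# Closure giving, for atom i, the indices of atoms whose solvent-extended
# spheres can intersect atom i's (cell-list spatial hash; cells sized to the
# largest extended diameter so 27 cells suffice).
neighbor_lists <- function(xyz, ext) {
  cs <- 2 * max(ext)
  mins <- apply(xyz, 2, min)
  cell <- floor(sweep(xyz, 2, mins) / cs)
  keyfun <- function(cx, cy, cz) paste(cx, cy, cz, sep = ",")
  buckets <- split(seq_len(nrow(xyz)), keyfun(cell[, 1], cell[, 2], cell[, 3]))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  function(i) {
    ks <- keyfun(cell[i, 1] + offsets[, 1], cell[i, 2] + offsets[, 2],
                 cell[i, 3] + offsets[, 3])
    cand <- unlist(buckets[ks], use.names = FALSE)
    d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
          (xyz[cand, 3] - xyz[i, 3])^2
    cand[d2 < (ext[cand] + ext[i])^2]
  }
}

#' Fill relative solvent accessibility
#'
#' RSA = residue SASA / the residue type's maximal accessible area. Values
#' above 1 are permitted (extended termini exceed the reference state) and
#' reported via a message. Residues whose type cannot be mapped to a
#' standard code get `NA` with a warning; a standard type missing from the
#' reference table is an error.
#'
#' @param sasa a `SasaTable` from [compute_sasa()].
#' @param ref reference table from [max_asa()].
#' @return the `SasaTable` with the `rsa` column filled; the reference table
#'   identity is recorded in attribute `max_asa_table`.
#' @export
compute_rsa <- function(sasa, ref = max_asa()) {
  nonstd <- is.na(sasa$std_resid)
  if (any(nonstd))
    warning(sum(nonstd), " residue(s) with non-standard type get RSA = NA: ",
            paste(unique(sasa$resid[nonstd]), collapse = ", "))
  need <- unique(sasa$std_resid[!nonstd])
  missing_ref <- setdiff(need, names(ref))
  if (length(missing_ref))
    stop("no reference area for residue type(s): ",
         paste(missing_ref, collapse = ", "))
  sasa$rsa <- ifelse(nonstd, NA_real_, sasa$sasa / unname(ref[sasa$std_resid]))
  over <- !is.na(sasa$rsa) & sasa$rsa > 1
  if (any(over))
    message(sum(over), " residue(s) have RSA > 1 (exceeding the reference state)")
  attr(sasa, "max_asa_table") <- attr(ref, "table")
  sasa
}

#' Define the protein surface by an RSA threshold
#'
#' The surface is the set of residues with RSA at or above the threshold
#' (inclusive: a residue exactly at the threshold is exposed).
#'
#' @param sasa a `SasaTable` with RSA filled (see [compute_rsa()]).
#' @param threshold RSA cutoff in `[0, 1]` (default 0.20).
#' @return an object of class `SurfaceSet`: list with `keys` (residue keys),
#'   `table` (the member rows of the SasaTable), `threshold` and
#'   `total_area` (sum of member SASA, Angstrom^2).
#' @export
select_surface <- function(sasa, threshold = 0.20) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  if (all(is.na(sasa$rsa)))
    stop("RSA not filled; run compute_rsa() first")
  member <- !is.na(sasa$rsa) & sasa$rsa >= threshold
  tab <- sasa[member, , drop = FALSE]
  structure(list(
    keys = tab$key,
    table = as.data.frame(tab),
    threshold = threshold,
    total_area = sum(tab$sasa)
  ), class = "SurfaceSet")
}

#' @export
print.SurfaceSet <- function(x, ...) {
  cat(sprintf("<SurfaceSet> %d residues with RSA >= %.2f, total area %.1f A^2\n",
              length(x$keys), x$threshold, x$total_area))
  invisible(x)
}
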