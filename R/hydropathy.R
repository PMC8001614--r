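#' Kyte-Doolittle hydropathy scale
#'
#' The 1982 per-residue hydropathy index: +4.5 (Ile, most hydrophobic) to
#' -4.5 (Arg, most hydrophilic).
#'
#' @return named numeric vector over the 20 standard residue types.
#' @export
kd_scale <- function() {
  c(ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5,
    MET =  1.9, ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
    TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
    GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5)
}

#' Spatially smoothed hydropathy over the protein surface
#'
#' Each exposed residue gets the unweighted arithmetic mean of the raw
#' Kyte-Doolittle values of all surface residues (itself included) whose
#' C-alpha lies within `radius` Angstrom of its own C-alpha. This is the
#' quantity used to color hydropathy onto a molecular surface.
#'
#' Surface residues lacking a C-alpha atom, or whose type has no standard
#' hydropathy value, are skipped with a warning.
#'
#' @param surface a `SurfaceSet` from [select_surface()].
#' @param model the [StructureModel()] the surface was computed on.
#' @param scale hydropathy scale, named by residue type (default [kd_scale()]).
#' @param radius smoothing radius, Angstrom (default 6.0).
#' @return an object of class `HydropathyMap`: data.frame with one row per
#'   mapped surface residue (`key`, `chain`, `resno`, `icode`, `std_resid`,
#'   `raw_kd`, `smoothed_kd`, `n_neighbors`), radius in attribute `radius`.
#' @export
smooth_kd <- function(surface, model, scale = kd_scale(), radius = 6.0) {
  stopifnot(inherits(surface, "SurfaceSet"), radius >= 0)
  if (!length(surface$keys)) stop("empty surface: nothing to smooth")
  tab <- surface$table
  known <- !is.na(tab$std_resid) & tab$std_resid %in% names(scale)
  if (!all(known))
    warning(sum(!known), " surface residue(s) without a hydropathy value skipped")
  tab <- tab[known, , drop = FALSE]
  xyz <- ca_coords(model, tab$key)          # warns about missing CA
  tab <- tab[match(rownames(xyz), tab$key), , drop = FALSE]
  if (!nrow(tab)) stop("no surface residue has a C-alpha atom")

  raw <- unname(scale[tab$std_resid])
  d <- as.matrix(stats::dist(xyz))
  within <- d <= radius                      # self included (diagonal 0)
  smoothed <- as.numeric((within %*% raw) / rowSums(within))

  out <- data.frame(
    key = tab$key, chain = tab$chain, resno = tab$resno, icode = tab$icode,
    std_resid = tab$std_resid, raw_kd = raw, smoothed_kd = smoothed,
    n_neighbors = as.integer(rowSums(within)),
    stringsAsFactors = FALSE
  )
  attr(out, "radius") <- radius
  class(out) <- c("HydropathyMap", class(out))
  out
}

#' Summary statistics of a hydropathy map
#'
#' Extremes and the unweighted mean of the smoothed values over all surface
#' residues, plus the raw-value extremes (an isolated hydrophilic residue
#' attains the scale minimum either way).
#'
#' @param map a `HydropathyMap` from [smooth_kd()].
#' @return named list: `min`, `mean`, `max` (smoothed), `raw_min`, `raw_max`.
#' @export
hydropathy_summary <- function(map) {
  if (!nrow(map)) stop("empty hydropathy map")
  list(
    min = min(map$smoothed_kd),
    mean = mean(map$smoothed_kd),
    max = max(map$smoothed_kd),
    raw_min = min(map$raw_kd),
    raw_max = max(map$raw_kd)
  )
}
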