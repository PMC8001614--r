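#' @importFrom stats setNames runif
#' @importFrom utils read.delim write.table head
NULL

# Three-letter codes of the 20 standard amino acids, alphabetical.
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# Common non-standard residues mapped to their parent standard code.
NONSTANDARD_AA_MAP <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO", SEP = "SER",
  TPO = "THR", PTR = "TYR", CSO = "CYS", MLY = "LYS", M3L = "LYS",
  KCX = "LYS", CME = "CYS", CSD = "CYS", OCS = "CYS", FME = "MET"
)

# Water residue names excluded on load.
WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

#' Van der Waals radius table
#'
#' Element-to-radius table (Angstrom) used to build solvent-extended spheres.
#' Hydrogens are ignored by default throughout the package since cryo-EM
#' depositions lack them, but a radius is provided for completeness.
#'
#' @param extra optional named numeric vector of additional or overriding
#'   element radii, names are element symbols (upper case).
#' @return named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function(extra = NULL) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
           P = 1.80, SE = 1.90)
  if (!is.null(extra)) {
    stopifnot(is.numeric(extra), !is.null(names(extra)), all(extra > 0))
    tab[toupper(names(extra))] <- extra
  }
  tab
}

#' Map residue names to standard three-letter codes
#'
#' Standard residues pass through; known modified residues (e.g. MSE) map to
#' their parent; anything else maps to `NA` and is excluded from composition
#' and hydropathy statistics downstream.
#'
#' @param resid character vector of residue names.
#' @return character vector of standard codes or `NA`.
#' @export
standardize_resid <- function(resid) {
  resid <- toupper(resid)
  out <- ifelse(resid %in% STANDARD_AA, resid,
                unname(NONSTANDARD_AA_MAP[resid]))
  as.character(out)
}

#' Residue keys
#'
#' A residue is identified across all modules by the string
#' `"<chain>:<auth number>:<insertion code>"` (empty insertion code allowed),
#' mirroring author numbering in the deposited file.
#'
#' @param chain,resno,icode vectors of chain ids, author residue numbers and
#'   insertion codes (`""` or `NA` for none).
#' @return character vector of keys.
#' @export
res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode), "", icode)
  paste(chain, resno, icode, sep = ":")
}

# Split keys back into their components.
split_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    icode = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
    stringsAsFactors = FALSE
  )
}

#' Construct a structure model from an atom table
#'
#' The atomic substrate of every geometric operation in the package. The
#' atom table uses one row per atom with author residue numbering.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`, `resid`,
#'   `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z`, and
#'   optionally `het` (logical, default `FALSE`), `o` (occupancy, default 1)
#'   and `b` (B-factor, default 0).
#' @param entry_id identifier for the model (e.g. a PDB id).
#' @param provenance list describing the source (path, format).
#' @param vdw_extra optional named vector of extra element radii passed to
#'   [vdw_radii()].
#' @return an object of class `StructureModel`: a list with elements
#'   `entry_id`, `atoms` (the validated table with a `vdw` column and a
#'   `std_resid` column of standardized residue codes) and `provenance`.
#' @export
StructureModel <- function(atoms, entry_id = "model", provenance = list(),
                           vdw_extra = NULL) {
  required <- c("chain", "resno", "icode", "resid", "elety", "elesy",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(atoms)) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  atoms$icode <- ifelse(is.na(atoms$icode), "", atoms$icode)
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$resno <- as.integer(atoms$resno)
  atoms$elesy <- toupper(atoms$elesy)

  radii <- vdw_radii(vdw_extra)
  unknown <- setdiff(unique(atoms$elesy), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "),
         "; supply vdw_extra to configure them")
  atoms$vdw <- unname(radii[atoms$elesy])
  atoms$std_resid <- standardize_resid(atoms$resid)
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)

  structure(
    list(entry_id = entry_id, atoms = atoms, provenance = provenance),
    class = "StructureModel"
  )
}

#' @export
print.StructureModel <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<StructureModel %s> %d atoms, %d residues, chains: %s\n",
              x$entry_id, nrow(x$atoms), nrow(rt),
              paste(unique(rt$chain), collapse = ", ")))
  invisible(x)
}

#' Per-residue summary of a structure model
#'
#' @param model a [StructureModel()].
#' @param hetero include hetero (non-polymer) residues? Default drops them.
#' @return data.frame with one row per residue: `key`, `chain`, `resno`,
#'   `icode`, `resid`, `std_resid`, `n_atoms`, ordered by chain then author
#'   number and insertion code.
#' @export
residue_table <- function(model, hetero = FALSE) {
  a <- model$atoms
  if (!hetero) a <- a[!a$het, , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(key = character(), chain = character(),
                      resno = integer(), icode = character(),
                      resid = character(), std_resid = character(),
                      n_atoms = integer(), stringsAsFactors = FALSE))
  }
  first <- !duplicated(a$key)
  rt <- a[first, c("key", "chain", "resno", "icode", "resid", "std_resid")]
  rt$n_atoms <- as.integer(table(a$key)[rt$key])
  rt <- rt[order(rt$chain, rt$resno, rt$icode), , drop = FALSE]
  rownames(rt) <- NULL
  rt
}

#' Chain ids of a model, longest polymer chain first
#'
#' @param model a [StructureModel()].
#' @return character vector of chain ids ordered by decreasing residue count.
#' @export
chains_by_size <- function(model) {
  rt <- residue_table(model)
  counts <- sort(table(rt$chain), decreasing = TRUE)
  names(counts)
}

# C-alpha coordinate matrix for a set of residue keys; rows named by key.
# Residues without a CA atom are dropped (with a warning if warn = TRUE).
ca_coords <- function(model, keys, warn = TRUE) {
  a <- model$atoms
  ca <- a[a$elety == "CA" & !a$het & a$key %in% keys, , drop = FALSE]
  ca <- ca[!duplicated(ca$key), , drop = FALSE]
  missing <- setdiff(keys, ca$key)
  if (length(missing) && warn)
    warning(length(missing), " residue(s) lack a CA atom and are skipped: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) " ...")
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$key
  m[match(intersect(keys, ca$key), rownames(m)), , drop = FALSE]
}
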