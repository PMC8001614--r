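#' Load a protein structure from PDB or mmCIF
#'
#' Reads atomic coordinates into a [StructureModel()]. Only the first model
#' of multi-model files is used. Waters are excluded, hydrogens are dropped
#' (cryo-EM depositions lack them and the surface computation ignores them),
#' and alternate locations are resolved to the highest-occupancy record
#' (ties: first by label).
#'
#' @param path path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` are mmCIF, anything else PDB).
#' @param entry_id identifier recorded in the model; defaults to the file
#'   base name.
#' @param vdw_extra optional named vector of extra element radii (see
#'   [vdw_radii()]).
#' @return a [StructureModel()].
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           entry_id = NULL, vdw_extra = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e))
  )
  at <- raw$atom
  # first model only: bio3d already returns the first model's coordinates

  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$elesy <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             guess_element(at$elety), at$elesy))
  at$o <- ifelse(is.na(at$o), 1, at$o)

  at <- at[!(at$resid %in% WATER_RESID), , drop = FALSE]
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop("empty structure: no polymer atoms in ", path)

  # resolve altlocs: keep the highest-occupancy record per atom site,
  # breaking ties by altloc label order as encountered in the file
  site <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(at)), site), function(idx) {
    idx[which.max(at$o[idx])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, icode = at$insert,
    resid = at$resid, elety = at$elety, elesy = at$elesy,
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM", o = at$o, b = at$b,
    stringsAsFactors = FALSE
  )
  if (is.null(entry_id))
    entry_id <- tools::file_path_sans_ext(basename(path))
  StructureModel(atoms, entry_id = entry_id,
                 provenance = list(path = path, format = format),
                 vdw_extra = vdw_extra)
}

# Element symbol from a PDB atom name when the element column is absent:
# strip digits/primes, take the leading letters; two-letter elements seen in
# protein files (SE of selenomethionine) are recognized explicitly.
guess_element <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  ifelse(nm == "SE", "SE", substr(nm, 1, 1))
}

#' Backbone gap and coverage accounting for a chain
#'
#' A gap is any maximal run of author residue numbers inside the declared
#' region that is absent from the chain, whether interior or terminal.
#' Coverage is the fraction of the declared region that is solved.
#'
#' @param model a [StructureModel()].
#' @param chain_id chain to examine.
#' @param full_region integer vector `c(start, end)` of the declared full
#'   region in author numbering (inclusive).
#' @return an object of class `GapReport`: list with `chain_id`, `region`,
#'   `n_solved`, `gaps` (data.frame `first`, `last`, `length`), `n_gaps`,
#'   `longest_gap` (the gap maximizing its length, `NULL` if none) and
#'   `coverage_fraction`.
#' @export
detect_gaps <- function(model, chain_id, full_region) {
  rt <- residue_table(model)
  if (!chain_id %in% rt$chain)
    stop("unknown chain: ", chain_id)
  stopifnot(length(full_region) == 2, full_region[1] <= full_region[2])
  start <- as.integer(full_region[1]); end <- as.integer(full_region[2])

  present <- unique(rt$resno[rt$chain == chain_id])
  present <- present[present >= start & present <= end]
  missing <- setdiff(seq.int(start, end), present)

  gaps <- data.frame(first = integer(), last = integer(), length = integer())
  if (length(missing)) {
    brk <- c(0L, which(diff(missing) > 1L), length(missing))
    gaps <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
      run <- missing[(brk[i] + 1L):brk[i + 1L]]
      data.frame(first = run[1], last = run[length(run)],
                 length = length(run))
    }))
  }
  longest <- if (nrow(gaps)) gaps[which.max(gaps$length), ] else NULL
  structure(list(
    chain_id = chain_id,
    region = c(start = start, end = end),
    n_solved = length(present),
    gaps = gaps,
    n_gaps = nrow(gaps),
    longest_gap = longest,
    coverage_fraction = length(present) / (end - start + 1L)
  ), class = "GapReport")
}

#' @export
print.GapReport <- function(x, ...) {
  cat(sprintf("<GapReport chain %s region %d-%d> %d solved, %d gaps, coverage %.3f\n",
              x$chain_id, x$region["start"], x$region["end"],
              x$n_solved, x$n_gaps, x$coverage_fraction))
  if (!is.null(x$longest_gap))
    cat(sprintf("  longest gap: %d-%d (%d residues)\n",
                x$longest_gap$first, x$longest_gap$last, x$longest_gap$length))
  invisible(x)
}

#' Write a structure with per-residue values encoded in the B-factor column
#'
#' Emits a standard PDB file in which every atom's B-factor is replaced by
#' its residue's value from `values` (0.0 where undefined), so any molecular
#' viewer can color the structure by the annotation. The file round-trips
#' through [load_structure()].
#'
#' @param model a [StructureModel()].
#' @param values named numeric vector, names are residue keys (see
#'   [res_key()]); may cover any subset of the model's residues.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotated_pdb <- function(model, values = numeric(), path) {
  a <- model$atoms
  b <- rep(0, nrow(a))
  if (length(values)) {
    if (is.null(names(values))) stop("values must be named by residue key")
    unknown <- setdiff(names(values), a$key)
    if (length(unknown))
      stop("values name residues absent from the model: ",
           paste(head(unknown, 5), collapse = ", "))
    hit <- a$key %in% names(values)
    b[hit] <- unname(values[a$key[hit]])
  }
  # B-factor column is %6.2f: representable range check
  if (any(b >= 1000 | b <= -100))
    stop("annotation value outside the PDB B-factor column width (-99.99..999.99)")
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, chain = a$chain,
    insert = ifelse(a$icode == "", NA, a$icode),
    eleno = seq_len(nrow(a)), elety = a$elety, elesy = a$elesy,
    o = a$o, b = b
  )
  invisible(path)
}
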