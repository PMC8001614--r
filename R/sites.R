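#' Load a residue-level interaction-site track
#'
#' Reads a tab-separated file of externally predicted protein-protein
#' interaction-site residues (chain, author residue number, insertion code,
#' residue type, score in `[0, 1]`), as produced by residue-level interface
#' predictors, and validates every record against the model. An empty file
#' yields an empty set.
#'
#' @param path TSV with columns `chain`, `resno`, `icode`, `resid`, `score`
#'   (header required; `icode` may be blank).
#' @param model the [StructureModel()] the track annotates.
#' @param score_threshold keep only residues with score at or above this
#'   value (default 0: keep all listed residues).
#' @param source label recorded on the set.
#' @return an object of class `InteractionSiteSet`: data.frame with one row
#'   per site residue (`key`, `chain`, `resno`, `icode`, `resid`, `score`),
#'   attributes `source` and `score_threshold`.
#' @export
load_site_track <- function(path, model, score_threshold = 0,
                            source = basename(path)) {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(icode = "character"))
  if (!nrow(df)) {
    df <- data.frame(key = character(), chain = character(), resno = integer(),
                     icode = character(), resid = character(),
                     score = numeric(), stringsAsFactors = FALSE)
    return(site_set(df, source, score_threshold))
  }
  need <- c("chain", "resno", "resid", "score")
  if (length(setdiff(need, names(df))))
    stop("site track must have columns chain, resno, [icode,] resid, score")
  if (is.null(df$icode)) df$icode <- ""
  df$icode[is.na(df$icode)] <- ""
  if (any(!is.finite(df$score) | df$score < 0 | df$score > 1))
    stop("site scores must lie in [0, 1]")
  df$key <- res_key(df$chain, df$resno, df$icode)

  rt <- residue_table(model, hetero = TRUE)
  bad <- setdiff(df$key, rt$key)
  if (length(bad))
    stop("site track names residues absent from the model: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...")
  mism <- df$resid != rt$resid[match(df$key, rt$key)]
  if (any(mism))
    warning(sum(mism), " residue type mismatch(es) between track and model: ",
            paste(head(df$key[mism], 5), collapse = ", "))
  df <- df[df$score >= score_threshold,
           c("key", "chain", "resno", "icode", "resid", "score")]
  site_set(df, source, score_threshold)
}

site_set <- function(df, source, score_threshold) {
  rownames(df) <- NULL
  attr(df, "source") <- source
  attr(df, "score_threshold") <- score_threshold
  class(df) <- c("InteractionSiteSet", class(df))
  df
}

#' Load or construct an ion-site track
#'
#' Predicted metal-ion centers as bare 3D points with a per-site label, as
#' produced by structure-based ion-site predictors.
#'
#' @param path TSV with columns `x`, `y`, `z` and optionally `label`.
#' @param points alternatively, an n x 3 numeric matrix of coordinates.
#' @param labels per-site labels (recycled).
#' @param neighborhood_radius default radius used by [ion_neighborhood()].
#' @return an object of class `IonSiteSet`: list with `points` (n x 3
#'   matrix), `labels` and `neighborhood_radius`.
#' @export
ion_site_set <- function(points, labels = NULL, neighborhood_radius = 3.5,
                         path = NULL) {
  if (!is.null(path)) {
    stopifnot(file.exists(path))
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (!nrow(df)) {
      points <- matrix(numeric(), ncol = 3)
      labels <- character()
    } else {
      if (length(setdiff(c("x", "y", "z"), names(df))))
        stop("ion track must have columns x, y, z[, label]")
      points <- as.matrix(df[, c("x", "y", "z")])
      labels <- if (!is.null(df$label)) as.character(df$label) else NULL
    }
  }
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(points) && !all(is.finite(points)))
    stop("ion coordinates must be finite")
  stopifnot(neighborhood_radius > 0)
  if (is.null(labels)) labels <- rep("site", nrow(points))
  labels <- rep_len(as.character(labels), nrow(points))
  structure(list(points = points, labels = labels,
                 neighborhood_radius = neighborhood_radius),
            class = "IonSiteSet")
}

#' Cluster interaction-site residues into spatial patches
#'
#' An interaction patch is a maximal group of predicted interaction-site
#' residues mutually connected by C-alpha--C-alpha distances strictly below
#' the cutoff: patches are the connected components of the contact graph
#' with an edge wherever the distance is `< cutoff`. Singletons are patches.
#' Site residues lacking a C-alpha atom are skipped with a warning.
#'
#' @param sites an `InteractionSiteSet` (or character vector of residue keys).
#' @param model the [StructureModel()].
#' @param cutoff contact cutoff, Angstrom (default 6.0, strict `<`).
#' @return an object of class `PatchSet`: list with `patches` (list of
#'   residue-key vectors, largest first), `n_patches`, `cutoff` and `sizes`.
#' @export
cluster_patches <- function(sites, model, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  keys <- if (is.character(sites)) unique(sites) else unique(sites$key)
  if (!length(keys)) {
    return(structure(list(patches = list(), n_patches = 0L,
                          cutoff = cutoff, sizes = integer()),
                     class = "PatchSet"))
  }
  xyz <- ca_coords(model, keys)              # warns about missing CA
  n <- nrow(xyz)
  if (!n) {
    return(structure(list(patches = list(), n_patches = 0L,
                          cutoff = cutoff, sizes = integer()),
                     class = "PatchSet"))
  }
  d <- as.matrix(stats::dist(xyz))
  adj <- d < cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  patches <- split(rownames(xyz), comp$membership)
  patches <- patches[order(-vapply(patches, length, 0L))]
  names(patches) <- NULL
  structure(list(
    patches = patches,
    n_patches = length(patches),
    cutoff = cutoff,
    sizes = vapply(patches, length, 0L)
  ), class = "PatchSet")
}

#' @export
print.PatchSet <- function(x, ...) {
  cat(sprintf("<PatchSet> %d patches over %d residues (cutoff %.1f A); sizes: %s\n",
              x$n_patches, sum(x$sizes), x$cutoff,
              paste(head(x$sizes, 10), collapse = " ")))
  invisible(x)
}

#' Residues neighboring predicted ion centers
#'
#' A residue belongs to the neighborhood if any of its heavy atoms lies
#' within `radius` Angstrom (inclusive) of any ion point; membership is
#' deduplicated across ions. The all-heavy-atom rule is the default because
#' the coordination-shell distance is unreachable from most C-alpha
#' positions; a C-alpha-only mode is available.
#'
#' @param ions an `IonSiteSet`.
#' @param model the [StructureModel()].
#' @param radius neighborhood radius, Angstrom; defaults to the set's
#'   `neighborhood_radius` (3.5 unless overridden).
#' @param atoms `"heavy"` (default) or `"calpha"`.
#' @return sorted character vector of residue keys.
#' @export
ion_neighborhood <- function(ions, model, radius = NULL,
                             atoms = c("heavy", "calpha")) {
  atoms <- match.arg(atoms)
  if (is.null(radius)) radius <- ions$neighborhood_radius
  stopifnot(radius > 0)
  if (!nrow(ions$points)) return(character())
  a <- model$atoms[!model$atoms$het, , drop = FALSE]
  if (atoms == "calpha") a <- a[a$elety == "CA", , drop = FALSE]
  if (!nrow(a)) return(character())
  hit <- rep(FALSE, nrow(a))
  for (k in seq_len(nrow(ions$points))) {
    p <- ions$points[k, ]
    d2 <- (a$x - p[1])^2 + (a$y - p[2])^2 + (a$z - p[3])^2
    hit <- hit | d2 <= radius^2
  }
  keys <- unique(a$key[hit])
  ord <- split_key(keys)
  keys[order(ord$chain, ord$resno, ord$icode)]
}

#' Overlap between two residue sets
#'
#' @param a,b character vectors of residue keys from the same model.
#' @return an object of class `OverlapReport`: list with `n_a`, `n_b`,
#'   `intersection` (keys), `n_intersection`, `n_union` and `jaccard`
#'   (0 when both sets are empty).
#' @export
overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- intersect(a, b)
  n_union <- length(union(a, b))
  structure(list(
    n_a = length(a), n_b = length(b),
    intersection = inter,
    n_intersection = length(inter),
    n_union = n_union,
    jaccard = if (n_union > 0) length(inter) / n_union else 0
  ), class = "OverlapReport")
}

#' Assign residues to named sequence domains
#'
#' Each residue is assigned to the first interval (in the order given) whose
#' author-number range contains it; residues matched by no interval count as
#' unassigned. Overlapping intervals trigger a configuration warning and the
#' first-match rule applies.
#'
#' @param residues character vector of residue keys.
#' @param domains data.frame with columns `name`, `start`, `end` (author
#'   numbering, inclusive), e.g. N-HEAT / BRIDGE / C-HEAT intervals.
#' @return named integer vector of counts per domain plus `"unassigned"`.
#' @export
assign_domains <- function(residues, domains) {
  stopifnot(all(c("name", "start", "end") %in% names(domains)),
            all(domains$start <= domains$end))
  if (nrow(domains) > 1) {
    for (i in seq_len(nrow(domains) - 1)) {
      for (j in (i + 1):nrow(domains)) {
        if (domains$start[i] <= domains$end[j] &&
            domains$start[j] <= domains$end[i]) {
          warning("overlapping domain intervals '", domains$name[i], "' and '",
                  domains$name[j], "'; first match wins")
        }
      }
    }
  }
  counts <- setNames(rep(0L, nrow(domains) + 1L),
                     c(domains$name, "unassigned"))
  if (!length(residues)) return(counts)
  resno <- split_key(unique(residues))$resno
  for (no in resno) {
    hit <- which(domains$start <= no & no <= domains$end)
    slot <- if (length(hit)) domains$name[hit[1]] else "unassigned"
    counts[slot] <- counts[slot] + 1L
  }
  counts
}
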