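#' Polarity classification schemes
#'
#' Partition of the 20 standard residue types into charged, polar-uncharged
#' and non-polar classes. `"textbook"` (default) counts histidine as
#' charged; `"his_neutral"` moves it to polar-uncharged, since published
#' polarity percentages do not always state the convention.
#'
#' @param name `"textbook"` or `"his_neutral"`.
#' @return an object of class `PolarityScheme`: list with character vectors
#'   `charged`, `polar_uncharged`, `nonpolar` and the scheme `name`.
#' @export
polarity_scheme <- function(name = c("textbook", "his_neutral")) {
  name <- match.arg(name)
  charged <- c("ASP", "GLU", "LYS", "ARG", "HIS")
  polar <- c("SER", "THR", "ASN", "GLN", "TYR", "CYS")
  if (name == "his_neutral") {
    charged <- setdiff(charged, "HIS")
    polar <- c(polar, "HIS")
  }
  scheme <- list(
    charged = charged,
    polar_uncharged = polar,
    nonpolar = c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP"),
    name = name
  )
  stopifnot(setequal(c(scheme$charged, scheme$polar_uncharged, scheme$nonpolar),
                     STANDARD_AA))
  class(scheme) <- "PolarityScheme"
  scheme
}

#' Residue-type composition and polarity fractions of a residue set
#'
#' Tabulates residue-type occurrences over any residue-key set (e.g. the
#' surface set, an interaction-site set, an ion neighborhood) and aggregates
#' polar / charged / non-polar fractions. Polar includes charged. Residues
#' whose type cannot be standardized are excluded with a warning. An empty
#' input yields a zero-count summary, not an error.
#'
#' @param residues character vector of residue keys.
#' @param model the [StructureModel()] resolving the keys.
#' @param scheme a [polarity_scheme()].
#' @return an object of class `CompositionSummary`: list with `n` (residues
#'   counted), `counts` (named integer vector over the 20 types), `fractions`,
#'   `polar_fraction`, `charged_fraction`, `nonpolar_fraction` and `ranking`
#'   (types present, by decreasing count, ties alphabetical).
#' @export
composition <- function(residues, model, scheme = polarity_scheme()) {
  rt <- residue_table(model, hetero = TRUE)
  residues <- unique(residues)
  unknown <- setdiff(residues, rt$key)
  if (length(unknown))
    stop("residue key(s) not in model: ", paste(head(unknown, 5), collapse = ", "))
  types <- rt$std_resid[match(residues, rt$key)]
  if (any(is.na(types))) {
    warning(sum(is.na(types)), " non-standard residue(s) excluded from composition")
    types <- types[!is.na(types)]
  }
  counts <- table(factor(types, levels = STANDARD_AA))
  counts <- setNames(as.integer(counts), STANDARD_AA)
  n <- sum(counts)
  fractions <- if (n > 0) counts / n else setNames(rep(0, 20), STANDARD_AA)

  frac_of <- function(set) if (n > 0) sum(counts[set]) / n else 0
  present <- names(counts)[counts > 0]
  ranking <- present[order(-counts[present], present)]

  structure(list(
    n = n,
    counts = counts,
    fractions = fractions,
    polar_fraction = frac_of(c(scheme$charged, scheme$polar_uncharged)),
    charged_fraction = frac_of(scheme$charged),
    nonpolar_fraction = frac_of(scheme$nonpolar),
    ranking = ranking,
    scheme = scheme$name
  ), class = "CompositionSummary")
}

#' @export
print.CompositionSummary <- function(x, ...) {
  cat(sprintf("<CompositionSummary> %d residues: %.0f%% polar (%.0f%% charged), %.0f%% non-polar [%s]\n",
              x$n, 100 * x$polar_fraction, 100 * x$charged_fraction,
              100 * x$nonpolar_fraction, x$scheme))
  if (length(x$ranking))
    cat("  most frequent:", paste(head(x$ranking, 6), collapse = ", "), "\n")
  invisible(x)
}
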