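PIPELINE_DEFAULTS <- list(
  format = "auto",
  chain = NULL,
  full_region = NULL,
  probe_radius = 1.4,
  n_points = 960,
  rsa_threshold = 0.20,
  kd_radius = 6.0,
  patch_cutoff = 6.0,
  ion_radius = 3.5,
  occluder_scope = "complex",
  polarity_scheme = "textbook",
  max_asa_table = "RostSander1994",
  site_track = NULL,
  ion_track = NULL,
  domain_map = NULL,
  output_dir = "protsurf-out"
)

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list), fills
#' defaults (probe 1.4 A, 960 sphere points, RSA threshold 0.20, smoothing
#' radius 6 A, patch cutoff 6 A, ion radius 3.5 A) and checks every
#' constraint before any computation; all problems are reported together.
#'
#' @param config path to a YAML file or a named list.
#' @return the validated config list (class `PipelineConfig`), or an error
#'   aggregating every violated constraint.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), c("structure", names(PIPELINE_DEFAULTS)))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config, keep.null = TRUE)

  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  if (length(unknown)) add(paste("unknown config key(s):",
                                 paste(unknown, collapse = ", ")))
  if (is.null(cfg$structure)) add("missing required key: structure")
  else if (!file.exists(cfg$structure))
    add(paste("structure file not found:", cfg$structure))
  for (key in c("probe_radius", "kd_radius", "patch_cutoff", "ion_radius")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      add(paste(key, "must be a positive number"))
  }
  if (!is.numeric(cfg$n_points) || cfg$n_points < 32)
    add("n_points must be >= 32")
  if (!is.numeric(cfg$rsa_threshold) || cfg$rsa_threshold < 0 ||
      cfg$rsa_threshold > 1)
    add("rsa_threshold must lie in [0, 1]")
  if (!cfg$occluder_scope %in% c("complex", "chain_only"))
    add("occluder_scope must be 'complex' or 'chain_only'")
  if (!cfg$polarity_scheme %in% c("textbook", "his_neutral"))
    add("polarity_scheme must be 'textbook' or 'his_neutral'")
  if (!cfg$max_asa_table %in% c("RostSander1994", "Tien2013"))
    add("max_asa_table must be 'RostSander1994' or 'Tien2013'")
  if (!is.null(cfg$full_region) &&
      (length(cfg$full_region) != 2 ||
       cfg$full_region[1] > cfg$full_region[2]))
    add("full_region must be c(start, end) with start <= end")
  for (key in c("site_track", "ion_track", "domain_map")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      add(paste(key, "file not found:", cfg[[key]]))
  }
  if (length(errs))
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Run the full surface-annotation pipeline
#'
#' Orchestrates structure loading, gap accounting, SASA/RSA, surface
#' definition, smoothed hydropathy, surface composition, interaction-patch
#' clustering, ion neighborhoods, overlap and domain assignment, writing
#' per-stage TSV/JSON files, annotated PDBs and a machine-readable
#' `report.json` into the output directory. Stages whose optional inputs
#' (site track, ion track, domain map, full region) are absent are skipped
#' and marked as such in the report.
#'
#' @param config a [validate_config()] result, a path to a YAML config, or a
#'   named list.
#' @param quiet suppress stage-boundary messages.
#' @return the report bundle (class `ReportBundle`), invisibly; the same
#'   content is written to `<output_dir>/report.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else validate_config(config)
  say <- function(...) if (!quiet) message("[protsurf] ", sprintf(...))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)

  say("loading structure %s (format %s)", cfg$structure, cfg$format)
  model <- load_structure(cfg$structure, format = cfg$format)
  chain <- if (is.null(cfg$chain)) chains_by_size(model)[1] else cfg$chain
  say("target chain %s (%d chains in model)", chain,
      length(chains_by_size(model)))

  gap_report <- NULL
  if (!is.null(cfg$full_region)) {
    say("gap accounting over region %d-%d", cfg$full_region[1],
        cfg$full_region[2])
    gap_report <- detect_gaps(model, chain, cfg$full_region)
    jsonlite::write_json(unclass_deep(gap_report), out("gap_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  say("SASA: probe %.2f A, %d points, occluders = %s",
      cfg$probe_radius, cfg$n_points, cfg$occluder_scope)
  sasa <- compute_sasa(model, probe_radius = cfg$probe_radius,
                       n_points = cfg$n_points,
                       occluder_scope = cfg$occluder_scope, chain = chain)
  sasa <- compute_rsa(sasa, ref = max_asa(cfg$max_asa_table))
  surface <- select_surface(sasa, threshold = cfg$rsa_threshold)
  say("surface: %d of %d residues at RSA >= %.2f, area %.1f A^2",
      length(surface$keys), nrow(sasa), cfg$rsa_threshold,
      surface$total_area)
  sasa_out <- as.data.frame(sasa)
  sasa_out$on_surface <- sasa_out$key %in% surface$keys
  write_tsv(sasa_out, out("sasa.tsv"))

  say("hydropathy smoothing, radius %.1f A", cfg$kd_radius)
  kd_map <- smooth_kd(surface, model, radius = cfg$kd_radius)
  kd_sum <- hydropathy_summary(kd_map)
  write_tsv(as.data.frame(kd_map), out("hydropathy.tsv"))
  kd_clamped <- pmax(pmin(setNames(kd_map$smoothed_kd, kd_map$key), 4.5), -4.5)
  write_annotated_pdb(model, kd_clamped, out("hydropathy_annotated.pdb"))

  scheme <- polarity_scheme(cfg$polarity_scheme)
  comp <- composition(surface$keys, model, scheme)
  say("surface composition: %.0f%% polar, %.0f%% non-polar",
      100 * comp$polar_fraction, 100 * comp$nonpolar_fraction)
  jsonlite::write_json(unclass_deep(comp), out("surface_composition.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  sites <- patches <- NULL
  if (!is.null(cfg$site_track)) {
    say("interaction sites from %s", cfg$site_track)
    sites <- load_site_track(cfg$site_track, model)
    patches <- cluster_patches(sites, model, cutoff = cfg$patch_cutoff)
    say("%d site residues -> %d patches (cutoff %.1f A)",
        nrow(sites), patches$n_patches, cfg$patch_cutoff)
    jsonlite::write_json(list(cutoff = patches$cutoff,
                              n_patches = patches$n_patches,
                              patches = patches$patches),
                         out("patches.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else say("no site track: patch stage skipped")

  ions <- neigh <- NULL
  if (!is.null(cfg$ion_track)) {
    say("ion sites from %s", cfg$ion_track)
    ions <- ion_site_set(path = cfg$ion_track,
                         neighborhood_radius = cfg$ion_radius)
    neigh <- ion_neighborhood(ions, model)
    say("%d ions -> %d neighbor residues (radius %.1f A)",
        nrow(ions$points), length(neigh), cfg$ion_radius)
  } else say("no ion track: ion stage skipped")

  ov <- NULL
  if (!is.null(sites) && !is.null(neigh)) {
    ov <- overlap(sites$key, neigh)
    say("overlap: %d residues shared (Jaccard %.3f)",
        ov$n_intersection, ov$jaccard)
  }

  domain_counts <- NULL
  if (!is.null(cfg$domain_map)) {
    domains <- read.delim(cfg$domain_map, sep = "\t",
                          stringsAsFactors = FALSE)
    domain_counts <- list(
      interaction_sites = if (!is.null(sites))
        as.list(assign_domains(sites$key, domains)) else NULL,
      ion_neighbors = if (!is.null(neigh))
        as.list(assign_domains(neigh, domains)) else NULL
    )
  }

  # annotated PDB for the two site classes: 1 = interaction, 2 = ion
  # neighbor, 3 = both
  if (!is.null(sites) || !is.null(neigh)) {
    vals <- numeric()
    if (!is.null(sites)) vals[sites$key] <- 1
    if (!is.null(neigh)) vals[neigh] <- ifelse(neigh %in% names(vals)[vals == 1], 3, 2)
    write_annotated_pdb(model, vals, out("sites_annotated.pdb"))
  }

  report <- list(
    entry_id = model$entry_id,
    chain = chain,
    gap_report = if (is.null(gap_report)) "skipped"
                 else unclass_deep(gap_report),
    surface = list(n_residues = nrow(sasa),
                   n_exposed = length(surface$keys),
                   rsa_threshold = cfg$rsa_threshold,
                   total_area = surface$total_area,
                   total_chain_area = sum(sasa$sasa)),
    hydropathy = kd_sum,
    composition = unclass_deep(comp),
    patches = if (is.null(patches)) "skipped"
              else list(n_sites = nrow(sites),
                        n_patches = patches$n_patches,
                        size_histogram = as.list(table(patches$sizes))),
    ions = if (is.null(neigh)) "skipped"
           else list(n_ions = nrow(ions$points),
                     n_neighbor_residues = length(neigh),
                     radius = cfg$ion_radius,
                     neighbors = neigh),
    overlap = if (is.null(ov)) "skipped" else unclass_deep(ov),
    domains = if (is.null(domain_counts)) "skipped" else domain_counts,
    provenance = list(
      package_version = as.character(utils::packageVersion("protsurf")),
      config = unclass_deep(cfg),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )

  # post-stage self-check: the bundle must be internally consistent
  stopifnot(report$surface$n_exposed == length(surface$keys),
            is.null(patches) ||
              sum(patches$sizes) <= report$patches$n_sites,
            is.null(ov) ||
              ov$n_intersection <= min(ov$n_a, ov$n_b))

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  say("report written to %s", out("report.json"))
  class(report) <- c("ReportBundle", "list")
  invisible(report)
}

# Strip S3 classes recursively so jsonlite serializes plainly.
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (!is.null(attributes(x)) && !is.null(names(x))) return(x)
  x
}
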