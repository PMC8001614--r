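#' Generate a synthetic multi-helix bundle with known ground truth
#'
#' Builds ideal alpha-helices (rise 1.5 A per residue, 100 degrees twist per
#' residue, C-alpha at 2.3 A from the helix axis) on parallel axes arranged
#' on a square grid with the given spacing, one chain per helix. Each
#' residue carries an ideal-geometry backbone (N, CA, C, O) and a single
#' C-beta-like pseudo-atom standing in for the side chain (absent for GLY).
#' This emulates the rod-like alpha-helical architecture of HEAT-repeat
#' proteins closely enough to exercise every geometric operation in the
#' package, with fully known coordinates.
#'
#' The sequence of every helix is either fixed (`sequence`) or drawn from a
#' residue-type composition (`composition`, default uniform over the 20
#' standard types) under the given seed; output is deterministic for a
#' fixed seed.
#'
#' @param n_helices number of helices (chains A, B, ...; at most 26).
#' @param residues_per_helix residues in each helix.
#' @param spacing distance between adjacent helix axes, Angstrom.
#' @param sequence optional fixed sequence: a character vector of 3-letter
#'   codes or a single 1-letter-code string, recycled to the helix length.
#' @param composition optional named fractions over 3-letter codes (must sum
#'   to 1) from which residue types are drawn.
#' @param seed integer seed controlling sequence sampling.
#' @param entry_id model identifier.
#' @return list with `model` (a [StructureModel()]) and `truth` (list
#'   recording the generating parameters and seed).
#' @export
build_helix_bundle <- function(n_helices = 1, residues_per_helix = 20,
                               spacing = 12, sequence = NULL,
                               composition = NULL, seed = 1,
                               entry_id = "synthetic-bundle") {
  stopifnot(n_helices >= 1, n_helices <= 26, residues_per_helix >= 2,
            spacing > 0)
  if (!is.null(sequence)) {
    if (length(sequence) == 1 && nchar(sequence) > 1)
      sequence <- bio3d::aa123(strsplit(sequence, "")[[1]])
    sequence <- toupper(sequence)
    if (!all(sequence %in% STANDARD_AA))
      stop("sequence contains non-standard residue codes")
  }
  if (is.null(composition))
    composition <- setNames(rep(1 / 20, 20), STANDARD_AA)
  if (abs(sum(composition) - 1) > 1e-6)
    stop("composition fractions must sum to 1")

  seqs <- with_seed(seed, {
    lapply(seq_len(n_helices), function(h) {
      if (!is.null(sequence)) rep_len(sequence, residues_per_helix)
      else sample(names(composition), residues_per_helix, replace = TRUE,
                  prob = composition)
    })
  })

  ncol_grid <- ceiling(sqrt(n_helices))
  rows <- lapply(seq_len(n_helices), function(h) {
    gx <- ((h - 1) %% ncol_grid) * spacing
    gy <- ((h - 1) %/% ncol_grid) * spacing
    helix_atoms(seqs[[h]], chain = LETTERS[h], origin = c(gx, gy, 0))
  })
  atoms <- do.call(rbind, rows)
  model <- StructureModel(atoms, entry_id = entry_id,
                          provenance = list(path = NA_character_,
                                            format = "synthetic"))

  dmin <- min_nonself_distance(model)
  if (dmin < 1.0)
    stop(sprintf("generation error: helices clash (min inter-atom distance %.2f A < 1.0 A); increase spacing", dmin))

  list(model = model,
       truth = list(n_helices = n_helices,
                    residues_per_helix = residues_per_helix,
                    spacing = spacing, seed = seed,
                    sequences = seqs))
}

# Ideal-helix coordinates for one chain. Peptide N and C atoms are tilted
# from the virtual C-alpha bond toward the helix axis, carbonyl O points
# along the rise, and the pseudo side chain points radially outward, keeping
# all non-bonded atoms beyond the 1 A overlap bound.
helix_atoms <- function(seq3, chain, origin) {
  n <- length(seq3)
  rise <- 1.5; twist <- 100 * pi / 180; r_ca <- 2.3
  tilt <- 25 * pi / 180
  th <- (seq_len(n) - 1) * twist
  ca <- cbind(origin[1] + r_ca * cos(th),
              origin[2] + r_ca * sin(th),
              origin[3] + (seq_len(n) - 1) * rise)
  u <- cbind(cos(th), sin(th), 0)            # outward radial per residue

  # per virtual bond i -> i+1: direction d and inward perpendicular p
  d <- matrix(0, n, 3); p <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    d[i, ] <- unit(ca[i + 1, ] - ca[i, ])
    w <- -(u[i, ] + u[i + 1, ]) / 2
    p[i, ] <- unit(w - sum(w * d[i, ]) * d[i, ])
  }
  d[n, ] <- d[n - 1, ]; p[n, ] <- p[n - 1, ]

  out <- vector("list", n)
  for (i in seq_len(n)) {
    db <- if (i > 1) d[i - 1, ] else d[1, ]   # bond arriving at i
    pb <- if (i > 1) p[i - 1, ] else p[1, ]
    npos <- ca[i, ] + 1.46 * (-cos(tilt) * db + sin(tilt) * pb)
    cpos <- ca[i, ] + 1.52 * (cos(tilt) * d[i, ] + sin(tilt) * p[i, ])
    q <- unit(pracma_cross(d[i, ], p[i, ]))
    if (q[3] < 0) q <- -q
    opos <- cpos + 1.23 * q
    names_ <- c("N", "CA", "C", "O")
    ele_ <- c("N", "C", "C", "O")
    coords <- rbind(npos, ca[i, ], cpos, opos)
    if (seq3[i] != "GLY") {
      cb <- ca[i, ] + 1.53 * unit(u[i, ] - c(0, 0, 0.35))
      names_ <- c(names_, "CB"); ele_ <- c(ele_, "C")
      coords <- rbind(coords, cb)
    }
    out[[i]] <- data.frame(
      chain = chain, resno = i, icode = "", resid = seq3[i],
      elety = names_, elesy = ele_,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      het = FALSE, o = 1, b = 0, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# plain cross product (avoid a dependency for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Smallest pairwise inter-atom distance in a model (Inf for a single atom).
min_nonself_distance <- function(model) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  if (nrow(xyz) < 2) return(Inf)
  min(stats::dist(xyz))
}

#' Plant spatially clustered interaction sites with known patch count
#'
#' Marks `k_patches` disjoint runs of consecutive residues as interaction
#' sites. Within a run, consecutive C-alpha atoms sit about 3.8 A apart
#' (below any reasonable patch cutoff), while distinct runs are separated in
#' sequence (and across chains) so that every inter-run C-alpha distance
#' exceeds the cutoff: the true patch count is exactly `k_patches`. The
#' construction is verified geometrically before returning.
#'
#' @param model a [StructureModel()] (typically from [build_helix_bundle()]).
#' @param k_patches number of patches to plant (0 allowed).
#' @param patch_size residues per patch.
#' @param cutoff the patch cutoff the truth must hold for, Angstrom.
#' @param seed integer seed for placement jitter and scores.
#' @param min_gap minimum sequence separation between runs in one chain.
#' @return list with `sites` (an `InteractionSiteSet`) and `truth` (list
#'   with `patches` = list of residue-key vectors, `n_patches`, `seed`).
#' @export
plant_sites <- function(model, k_patches, patch_size = 3, cutoff = 6.0,
                        seed = 1, min_gap = 5) {
  stopifnot(k_patches >= 0, patch_size >= 1, min_gap >= 1)
  rt <- residue_table(model)
  if (k_patches == 0) {
    empty <- data.frame(key = character(), chain = character(),
                        resno = integer(), icode = character(),
                        resid = character(), score = numeric(),
                        stringsAsFactors = FALSE)
    return(list(sites = site_set(empty, "planted", 0),
                truth = list(patches = list(), n_patches = 0L, seed = seed)))
  }
  chains <- split(rt, rt$chain)
  capacity <- vapply(chains, function(ch)
    max(0, (nrow(ch) + min_gap) %/% (patch_size + min_gap)), 0)
  if (sum(capacity) < k_patches)
    stop("generation error: model too small to host ", k_patches,
         " patches of size ", patch_size, " with gap ", min_gap)

  runs <- with_seed(seed, {
    remaining <- k_patches
    acc <- list()
    for (ch in chains) {
      if (remaining == 0) break
      L <- nrow(ch)
      m <- min(max(0L, (L + min_gap) %/% (patch_size + min_gap)), remaining)
      if (m == 0) next
      slack <- L - (m * patch_size + (m - 1) * min_gap)
      extra <- if (slack > 0) sort(sample(0:slack, m, replace = TRUE))
               else rep(0L, m)
      for (j in seq_len(m)) {
        start <- (j - 1) * (patch_size + min_gap) + extra[j] + 1
        acc[[length(acc) + 1]] <- ch$key[start:(start + patch_size - 1)]
      }
      remaining <- remaining - m
    }
    acc
  })

  # verify the planted truth geometrically: inter-run CA separation > cutoff
  if (length(runs) > 1) {
    cas <- lapply(runs, function(k) ca_coords(model, k, warn = FALSE))
    for (i in seq_len(length(runs) - 1)) {
      for (j in (i + 1):length(runs)) {
        dmin <- min(vapply(seq_len(nrow(cas[[i]])), function(r)
          min(sqrt(rowSums(sweep(cas[[j]], 2, cas[[i]][r, ])^2))), 0))
        if (dmin <= cutoff)
          stop(sprintf("generation error: planted runs %d and %d are %.2f A apart (<= cutoff %.1f)",
                       i, j, dmin, cutoff))
      }
    }
  }

  keys <- unlist(runs)
  idx <- match(keys, rt$key)
  scores <- with_seed(seed + 1L, runif(length(keys), 0.5, 1))
  df <- data.frame(key = keys, chain = rt$chain[idx], resno = rt$resno[idx],
                   icode = rt$icode[idx], resid = rt$resid[idx],
                   score = scores, stringsAsFactors = FALSE)
  list(sites = site_set(df, "planted", 0),
       truth = list(patches = runs, n_patches = length(runs), seed = seed))
}

#' Plant ions at a known offset from chosen residues
#'
#' Places one ion per (deduplicated) target residue at exactly `offset`
#' Angstrom from one of its atoms (the side-chain pseudo-atom if present,
#' else the C-alpha), pointing away from the structure so that the chosen
#' atom is the nearest atom of the whole model and all atoms of non-target
#' residues stay at least `clearance` Angstrom away. Directions are searched
#' under the seed; an impossible placement is an error naming the residue.
#'
#' @param model a [StructureModel()].
#' @param targets character vector of residue keys (duplicates collapsed).
#' @param offset exact ion-to-chosen-atom distance, Angstrom.
#' @param seed integer seed for the direction search.
#' @param clearance minimum distance to atoms of non-target residues.
#' @return list with `ions` (an `IonSiteSet` labeled by target key) and
#'   `truth` (data.frame `x`, `y`, `z`, `target`, `atom`, `offset`).
#' @export
plant_ions <- function(model, targets, offset = 3.0, seed = 1,
                       clearance = 5.0) {
  stopifnot(offset > 0)
  targets <- unique(targets)
  a <- model$atoms
  bad <- setdiff(targets, a$key)
  if (length(bad)) stop("unknown target residue(s): ",
                        paste(bad, collapse = ", "))
  if (!length(targets)) {
    return(list(ions = ion_site_set(matrix(numeric(), ncol = 3)),
                truth = data.frame(x = numeric(), y = numeric(),
                                   z = numeric(), target = character(),
                                   atom = character(), offset = numeric())))
  }
  centroid <- colMeans(a[, c("x", "y", "z")])
  xyz_all <- as.matrix(a[, c("x", "y", "z")])

  placed <- with_seed(seed, {
    lapply(targets, function(key) {
      res_atoms <- a[a$key == key, , drop = FALSE]
      pick <- match(TRUE, res_atoms$elety == "CB")
      if (is.na(pick)) pick <- match(TRUE, res_atoms$elety == "CA")
      if (is.na(pick)) pick <- 1L
      atom <- as.numeric(res_atoms[pick, c("x", "y", "z")])
      base <- tryCatch(unit(atom - centroid), error = function(e) c(0, 0, 1))
      rand <- matrix(stats::rnorm(3 * 200), ncol = 3)
      dirs <- rbind(base, rand / sqrt(rowSums(rand^2)))
      chosen_row <- which(a$key == key)[pick]
      nontarget <- !(a$key %in% targets)
      best <- NULL; best_clear <- -Inf
      for (r in seq_len(nrow(dirs))) {
        ion <- atom + offset * dirs[r, ]
        dall <- sqrt(rowSums(sweep(xyz_all, 2, ion)^2))
        if (any(dall[-chosen_row] < offset - 1e-9)) next  # chosen atom must be nearest
        cl <- if (any(nontarget)) min(dall[nontarget]) else Inf
        if (cl > best_clear) { best_clear <- cl; best <- ion }
        if (best_clear >= clearance) break
      }
      if (is.null(best) || best_clear < clearance)
        stop("infeasible ion placement for residue ", key,
             sprintf(" (best clearance %.2f A < %.1f A)", best_clear, clearance))
      list(ion = best, atom = res_atoms$elety[pick])
    })
  })

  pts <- do.call(rbind, lapply(placed, `[[`, "ion"))
  truth <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      target = targets,
                      atom = vapply(placed, `[[`, "", "atom"),
                      offset = offset, stringsAsFactors = FALSE)
  list(ions = ion_site_set(pts, labels = targets), truth = truth)
}
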