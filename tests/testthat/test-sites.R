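write_track <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("site tracks load, validate against the model, and filter by score", {
  b <- build_helix_bundle(1, 20, seed = 3)
  rt <- residue_table(b$model)

  # empty track -> empty set
  empty <- write_track(rt[0, c("chain", "resno", "icode", "resid")])
  es <- load_site_track(empty, b$model)
  expect_equal(nrow(es), 0)

  df <- data.frame(chain = rt$chain[1:6], resno = rt$resno[1:6],
                   icode = "", resid = rt$resid[1:6],
                   score = c(0.9, 0.8, 0.7, 0.6, 0.3, 0.2))
  ss <- load_site_track(write_track(df), b$model)
  expect_equal(nrow(ss), 6)
  expect_setequal(ss$key, rt$key[1:6])
  expect_equal(nrow(load_site_track(write_track(df), b$model,
                                    score_threshold = 0.5)), 4)

  # unresolvable keys are a validation error listing offenders
  bad <- df; bad$resno[1] <- 999
  expect_error(load_site_track(write_track(bad), b$model), "absent")
  # residue-type mismatches are reported
  mism <- df; mism$resid[2] <- setdiff(c("ALA", "GLY"), df$resid[2])[1]
  expect_warning(load_site_track(write_track(mism), b$model), "mismatch")
  # scores outside [0,1] rejected
  oob <- df; oob$score[1] <- 1.5
  expect_error(load_site_track(write_track(oob), b$model), "0, 1")
})

test_that("a generator-planted track reloads with all keys validated", {
  b <- build_helix_bundle(2, 30, seed = 5)
  ps <- plant_sites(b$model, k_patches = 5, patch_size = 5, seed = 5)
  path <- write_track(as.data.frame(ps$sites)[, c("chain", "resno", "icode",
                                                  "resid", "score")])
  ss <- load_site_track(path, b$model)
  expect_equal(nrow(ss), 25)
  expect_setequal(ss$key, ps$sites$key)
})

test_that("patch boundary semantics are strict: edge only below the cutoff", {
  mk <- function(d) toy_model(rbind(c(0, 0, 0), c(d, 0, 0)), elesy = "C")
  m5 <- mk(5); m5$atoms$elety <- "CA"
  m6 <- mk(6); m6$atoms$elety <- "CA"
  keys <- residue_table(m5)$key
  expect_equal(cluster_patches(keys, m5, cutoff = 6)$n_patches, 1)
  expect_equal(cluster_patches(keys, m6, cutoff = 6)$n_patches, 2)
  expect_equal(cluster_patches(character(), m5)$n_patches, 0)
})

test_that("patch clustering recovers planted counts and matches union-find", {
  b <- build_helix_bundle(4, 50, spacing = 12, seed = 13)
  for (k in c(0, 1, 5, 20)) {
    ps <- plant_sites(b$model, k_patches = k, patch_size = 3, seed = k + 1)
    pt <- cluster_patches(ps$sites, b$model, cutoff = 6)
    expect_equal(pt$n_patches, k)
    if (k > 0) {
      expect_setequal(unlist(pt$patches), ps$sites$key)
      xyz <- ca_coords(b$model, ps$sites$key)
      oracle <- oracle_components(rownames(xyz), xyz, 6)
      expect_equal(canonical_partition(pt$patches),
                   canonical_partition(oracle))
      expect_equal(canonical_partition(pt$patches),
                   canonical_partition(ps$truth$patches))
    }
  }
})

test_that("patch count shrinks as the cutoff grows, with the documented limits", {
  b <- build_helix_bundle(2, 40, seed = 17)
  ps <- plant_sites(b$model, k_patches = 6, patch_size = 4, seed = 2)
  cutoffs <- c(0.5, 4, 6, 12, 1e6)
  counts <- vapply(cutoffs, function(co)
    cluster_patches(ps$sites, b$model, cutoff = co)$n_patches, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], nrow(ps$sites))      # cutoff -> 0: all singletons
  expect_equal(counts[length(counts)], 1L)     # cutoff -> Inf: one patch
})

test_that("ion neighborhoods use inclusive all-heavy-atom distances", {
  b <- build_helix_bundle(2, 25, seed = 19)
  # far ion sees nothing
  far <- ion_site_set(matrix(c(500, 500, 500), ncol = 3))
  expect_equal(ion_neighborhood(far, b$model), character())

  pi3 <- plant_ions(b$model, c("A:4:", "B:12:"), offset = 3.0, seed = 6)
  expect_setequal(ion_neighborhood(pi3$ions, b$model, radius = 3.5),
                  c("A:4:", "B:12:"))
  # exactly at the radius boundary: inclusive (exact fp representable case)
  mtoy <- toy_model(c(0, 0, 0)); mtoy$atoms$elety <- "CA"
  ion_at <- ion_site_set(matrix(c(3.5, 0, 0), ncol = 3))
  expect_equal(ion_neighborhood(ion_at, mtoy, radius = 3.5), "A:1:")
  # planted outside the radius: empty
  pi4 <- plant_ions(b$model, c("A:4:"), offset = 4.0, seed = 6)
  expect_equal(ion_neighborhood(pi4$ions, b$model, radius = 3.5), character())
  # monotone in radius
  sizes <- vapply(c(1, 3.5, 6, 10), function(r)
    length(ion_neighborhood(pi3$ions, b$model, radius = r)), 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("duplicate targets collapse to a single planted ion and entry", {
  b <- build_helix_bundle(1, 15, seed = 23)
  p <- plant_ions(b$model, c("A:7:", "A:7:"), offset = 3.0, seed = 1)
  expect_equal(nrow(p$ions$points), 1)
  expect_equal(ion_neighborhood(p$ions, b$model), "A:7:")
})

test_that("overlap reports set algebra correctly", {
  ov0 <- overlap(c("A:1:", "A:2:"), c("A:3:", "A:4:"))
  expect_equal(ov0$n_intersection, 0)
  expect_equal(ov0$jaccard, 0)
  ov1 <- overlap(c("A:1:", "A:2:", "A:3:"), c("A:3:", "A:2:", "A:1:"))
  expect_equal(ov1$n_intersection, 3)
  expect_equal(ov1$jaccard, 1)
  ovp <- overlap(c("A:1:", "A:2:"), c("A:2:", "A:3:"))
  expect_equal(ovp$intersection, "A:2:")
  expect_equal(ovp$n_union, 3)
  expect_equal(ovp$jaccard, 1 / 3)
  expect_lte(ovp$n_intersection, min(ovp$n_a, ovp$n_b))
})

test_that("domain assignment follows the first-match rule and an interval oracle", {
  doms <- data.frame(name = c("membrane-binding", "tail"),
                     start = c(166, 444), end = c(443, 600))
  counts <- assign_domains("A:200:", doms)
  expect_equal(unname(counts["membrane-binding"]), 1L)
  expect_equal(unname(counts["unassigned"]), 0L)
  # empty set -> all zeros
  expect_true(all(assign_domains(character(), doms) == 0))
  # overlapping intervals warn, first match wins
  ovl <- data.frame(name = c("a", "b"), start = c(1, 50), end = c(100, 150))
  expect_warning(counts2 <- assign_domains("A:60:", ovl), "overlapping")
  expect_equal(unname(counts2["a"]), 1L)

  set.seed(31)
  for (rep in 1:5) {
    starts <- sort(sample(1:500, 3))
    doms_r <- data.frame(name = c("d1", "d2", "d3"), start = starts,
                         end = starts + sample(10:80, 3))
    resno <- sample(1:600, 40)
    keys <- res_key("A", resno)
    got <- suppressWarnings(assign_domains(keys, doms_r))
    want <- setNames(rep(0L, 4), c("d1", "d2", "d3", "unassigned"))
    for (no in resno) {
      hit <- which(doms_r$start <= no & no <= doms_r$end)
      nm <- if (length(hit)) doms_r$name[hit[1]] else "unassigned"
      want[nm] <- want[nm] + 1L
    }
    expect_equal(got, want)
  }
})
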