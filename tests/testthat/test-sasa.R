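test_that("an isolated atom's SASA equals the sphere closed form", {
  m <- toy_model(c(0, 0, 0))                  # one carbon
  s <- compute_sasa(m, probe_radius = 1.4, n_points = 960)
  expect_equal(s$sasa, 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("two intersecting spheres match the closed-form exposed area within 2%", {
  m <- toy_model(rbind(c(0, 0, 0), c(2, 0, 0)))   # two carbons 2.0 A apart
  s <- compute_sasa(m, n_points = 960)
  expect_equal(sum(s$sasa), two_sphere_area(3.1, 3.1, 2.0), tolerance = 0.02)

  # asymmetric radii: carbon + sulfur at several separations
  for (d in c(1.2, 2.5, 3.4)) {
    m2 <- toy_model(rbind(c(0, 0, 0), c(d, 0, 0)), elesy = c("C", "S"))
    s2 <- compute_sasa(m2, n_points = 960)
    expect_equal(sum(s2$sasa), two_sphere_area(3.1, 3.2, d), tolerance = 0.02)
  }
})

test_that("an atom caged inside an icosahedral shell is fully buried", {
  cage <- icosahedron_vertices() * 3.0
  m <- toy_model(rbind(c(0, 0, 0), cage), elesy = c("C", rep("S", 12)))
  s <- compute_sasa(m, n_points = 960)
  # the center residue (resno 1) has zero accessible area
  expect_equal(s$sasa[s$resno == 1], 0)
})

test_that("unknown elements without a radius are a configuration error", {
  expect_error(toy_model(c(0, 0, 0), elesy = "XX"), "radius")
  m <- StructureModel(data.frame(
    chain = "A", resno = 1L, icode = "", resid = "ALA", elety = "XX",
    elesy = "XX", x = 0, y = 0, z = 0), vdw_extra = c(XX = 1.9))
  expect_equal(m$atoms$vdw, 1.9)
})

test_that("isolated-atom SASA is monotone in probe radius", {
  m <- toy_model(c(0, 0, 0))
  areas <- vapply(c(0.5, 1.0, 1.4, 2.0),
                  function(p) compute_sasa(m, probe_radius = p,
                                           n_points = 480)$sasa, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("adding an occluder chain never increases any residue's SASA", {
  b1 <- build_helix_bundle(1, 15, seed = 5)
  b2 <- build_helix_bundle(2, 15, spacing = 7, seed = 5)
  alone <- compute_sasa(b1$model, n_points = 240)
  together <- compute_sasa(b2$model, n_points = 240, chain = "A")
  expect_true(all(together$sasa <= alone$sasa + 1e-9))
  # chain_only mode ignores the neighbor entirely
  solo_scope <- compute_sasa(b2$model, n_points = 240,
                             occluder_scope = "chain_only", chain = "A")
  expect_equal(solo_scope$sasa, alone$sasa, tolerance = 1e-12)
})

test_that("SASA at 960 points is converged within 3% of 10,000 points", {
  set.seed(99)
  for (rep in 1:3) {
    xyz <- matrix(runif(15, 0, 4), ncol = 3)     # random 5-atom toys
    m <- toy_model(xyz, elesy = sample(c("C", "N", "O", "S"), 5, TRUE))
    s960 <- compute_sasa(m, n_points = 960)
    s10k <- compute_sasa(m, n_points = 10000)
    expect_equal(sum(s960$sasa), sum(s10k$sasa), tolerance = 0.03)
  }
})

test_that("per-atom SASA matches an independent Monte-Carlo estimator (3 sigma)", {
  set.seed(7)
  xyz <- matrix(runif(3 * 12, 0, 6), ncol = 3)
  elesy <- sample(c("C", "N", "O"), 12, TRUE)
  m <- toy_model(xyz, elesy = elesy)              # 12 one-atom residues
  s <- compute_sasa(m, n_points = 960)
  ext <- m$atoms$vdw + 1.4
  for (i in seq_len(12)) {
    mc <- oracle_sasa_mc(xyz, ext, i)
    lattice_err <- 0.01 * 4 * pi * ext[i]^2      # lattice discretization slack
    expect_lt(abs(s$sasa[s$resno == i] - mc$sasa), 3 * mc$se + lattice_err)
  }
})

test_that("RSA normalization handles boundary cases and flags RSA > 1", {
  s <- compute_sasa(toy_model(c(0, 0, 0), resid = "GLY"), n_points = 960)
  # zero SASA gives zero RSA
  s0 <- s; s0$sasa <- 0
  expect_equal(compute_rsa(s0)$rsa, 0)
  # SASA equal to the reference area gives RSA exactly 1
  s1 <- s; s1$sasa <- max_asa()[["GLY"]]
  expect_equal(compute_rsa(s1)$rsa, 1.0)
  # a bare atom exceeds the reference state and is logged, not an error
  expect_message(r <- compute_rsa(s), "RSA > 1")
  expect_gt(r$rsa, 1)
  # a missing reference entry names the residue type
  ref <- max_asa()[setdiff(names(max_asa()), "GLY")]
  attr(ref, "table") <- "truncated"
  expect_error(compute_rsa(s, ref = ref), "GLY")
})

test_that("an extended central residue is near-maximally exposed", {
  # Ala-Ala-Ala along a line at the 3.8 A virtual bond spacing
  rows <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(chain = "A", resno = i, icode = "",
               resid = "ALA", elety = c("N", "CA", "C", "O", "CB"),
               elesy = c("N", "C", "C", "O", "C"),
               x = (i - 1) * 3.8 + c(-1.2, 0, 1.2, 1.4, 0),
               y = c(0.5, 0, 0.5, 1.6, -1.5), z = 0)
  }))
  m <- StructureModel(rows)
  r <- suppressMessages(compute_rsa(compute_sasa(m, n_points = 960)))
  expect_gte(r$rsa[r$resno == 2], 0.8)
})

test_that("the surface set is exactly the RSA-thresholded residue set", {
  b <- build_helix_bundle(2, 20, seed = 9)
  sasa <- suppressMessages(compute_rsa(compute_sasa(b$model, n_points = 240)))
  surf <- select_surface(sasa, threshold = 0.20)
  expect_setequal(surf$keys, sasa$key[sasa$rsa >= 0.20])
  expect_equal(surf$total_area, sum(sasa$sasa[sasa$key %in% surf$keys]))

  # threshold 0 keeps every residue (>= comparison)
  expect_setequal(select_surface(sasa, 0)$keys, sasa$key)
  # growing the threshold never grows the set
  sizes <- vapply(c(0, 0.1, 0.2, 0.5, 0.9),
                  function(t) length(select_surface(sasa, t)$keys), 0)
  expect_true(all(diff(sizes) <= 0))
  expect_error(select_surface(sasa, 1.2), "threshold")
})
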