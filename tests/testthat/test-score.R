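# Helper: a pose of two short helices, the second shifted so the closest
# inter-chain atom pair sits at a requested distance (found by root search:
# a bare x-shift is not the closest-atom distance because of helix extent).
two_helix_pose <- function(min_dist) {
  a <- make_helix(6, chain_id = "A")
  b0 <- make_helix(6, chain_id = "B")
  mind <- function(s) {
    b <- b0; b$xyz <- sweep(b0$xyz, 2, c(s, 0, 0), `+`)
    min(flexidock:::cross_dist(a$xyz, b$xyz)) - min_dist
  }
  s <- stats::uniroot(mind, c(min_dist, min_dist + 60), tol = 1e-6)$root
  b <- b0; b$xyz <- sweep(b0$xyz, 2, c(s, 0, 0), `+`)
  coarse_pose(a, b)
}

test_that("LJ terms: cutoff, sign, monotone repulsion, closed form", {
  p <- lj_params()
  # chains far beyond the cutoff: inter-chain contribution zero, so the
  # total equals the (constant) intra-chain part
  base <- lj_terms(two_helix_pose(1000), p)
  far <- lj_terms(two_helix_pose(12), p)
  expect_equal(far, base, tolerance = 1e-9)
  expect_gte(base["e_rep"], 0)
  expect_lte(base["e_attr"], 0)
  # monotone repulsion as a distance below r_min shrinks
  r <- seq(p$r_min * 0.99, 0.1, length.out = 60)
  reps <- vapply(r, function(ri) lj_split(ri, p)$rep, 0)
  expect_true(all(diff(reps) > 0))
  # closed-form check at stated radii (independent hand evaluation)
  lj_ref <- function(rr) p$eps * ((p$r_min / rr)^12 - 2 * (p$r_min / rr)^6)
  s <- lj_split(c(2.5, 3.0, 5.0), p)
  expect_equal(s$rep[1], lj_ref(2.5) + p$eps, tolerance = 1e-12)
  expect_equal(s$rep[2], lj_ref(3.0) + p$eps, tolerance = 1e-12)
  expect_equal(s$rep[3], 0)
  expect_equal(s$attr[3], lj_ref(5.0), tolerance = 1e-12)
  expect_equal(s$attr[1], 0)
  # linear cap below cap_frac * r_min: finite and still monotone
  expect_true(is.finite(lj_split(1e-3, p)$rep))
})

test_that("torsion statistics behave as knowledge-based surrogates", {
  helix <- make_helix(10)
  twisted <- make_chain_from_dihedrals(rep(60, 10), rep(60, 10))
  ts_h <- torsion_stats(helix)
  ts_t <- torsion_stats(twisted)
  expect_lt(ts_h["e_rama"], ts_t["e_rama"])
  # planar trans omega costs nothing; cis costs nothing; twisted omega does
  expect_equal(unname(ts_h["e_omega"]), 0, tolerance = 1e-9)
  cis <- make_chain_from_dihedrals(rep(-57, 6), rep(-47, 6), rep(0, 6))
  expect_equal(unname(torsion_stats(cis)["e_omega"]), 0, tolerance = 1e-9)
  twist_om <- make_chain_from_dihedrals(rep(-57, 6), rep(-47, 6), rep(160, 6))
  expect_equal(unname(torsion_stats(twist_om)["e_omega"]), 5 * 0.005 * 20^2,
               tolerance = 1e-6)
  # single residue at a surface maximum scores -log(packaged peak density)
  grid <- expand.grid(phi = seq(-180, 175, by = 5), psi = seq(-180, 175, by = 5))
  dens <- rama_density(grid$phi, grid$psi, "general")
  peak <- grid[which.max(dens), ]
  ch1 <- make_chain_from_dihedrals(rep(peak$phi, 3), rep(peak$psi, 3))
  ts1 <- torsion_stats(ch1)
  expect_equal(unname(ts1["e_rama"]),
               -log(rama_density(peak$phi, peak$psi, "general")),
               tolerance = 1e-9)
  # undefined dihedrals contribute nothing: single-residue chains score 0
  single <- make_helix(4)
  single$xyz <- single$xyz[1:6, , drop = FALSE]
  single$n <- 1L; single$chain <- single$chain[1]
  single$seq <- single$seq[1]; single$aa <- single$aa[1]
  single$cb_virtual <- single$cb_virtual[1]
  expect_equal(unname(torsion_stats(single)), c(0, 0, 0))
})

test_that("pair-transform scoring is range-limited and rigid-invariant", {
  toy <- toy36()
  pose <- toy$bound
  sep <- pose_perturb_jump(pose, rigid_transform(diag(3), c(200, 0, 0)))
  expect_equal(pair_transform_score(sep), 0)
  e0 <- pair_transform_score(pose)
  expect_lt(e0, 0)
  for (s in 1:3) {
    expect_equal(pair_transform_score(transform_pose(pose, random_rigid(s))),
                 e0, tolerance = 1e-8)
  }
})

test_that("a hand-filled single-bin table scores by enumeration", {
  toy <- toy36()
  pose <- toy$bound
  t_edges <- seq(-10, 10, by = 1)
  r_edges <- seq(-pi, pi, length.out = 13)
  tmpl <- list(t_edges = t_edges, r_edges = r_edges, range = 10)
  # enumerate the contact pairs and their bin keys by hand
  ca_r <- atom_xyz(pose$receptor, "CA")
  ca_l <- atom_xyz(pose$ligand, "CA")
  cls_r <- flexidock:::aa_pair_class(pose$receptor$aa)
  cls_l <- flexidock:::aa_pair_class(pose$ligand$aa)
  keys <- character(0)
  for (i in seq_len(pose$receptor$n)) for (j in seq_len(pose$ligand$n)) {
    if (sqrt(sum((ca_r[i, ] - ca_l[j, ])^2)) <= 10) {
      tr <- pair_transform(pose$receptor, i, pose$ligand, j)
      keys <- c(keys, flexidock:::pair_bin_key(cls_r[i], cls_l[j], tr, tmpl))
    }
  }
  keys <- keys[!is.na(keys)]
  key1 <- names(sort(table(keys), decreasing = TRUE))[1]
  n1 <- sum(keys == key1)
  # fill exactly that bin: count 3 vs expected 1, pseudocount 1
  tab <- pair_table(stats::setNames(3, key1), stats::setNames(1, key1),
                    t_edges, r_edges, range = 10, pseudocount = 1)
  expect_equal(pair_transform_score(pose, tab), n1 * -log((3 + 1) / (1 + 1)),
               tolerance = 1e-10)
  # empty bin with pseudocount: score 0 when expected also empty
  tab0 <- pair_table(stats::setNames(numeric(0), character(0)),
                     stats::setNames(numeric(0), character(0)),
                     t_edges, r_edges, 10, 1)
  expect_equal(pair_transform_score(pose, tab0), 0)
})

test_that("trained tables discriminate the native orientation and round-trip", {
  toy <- toy36()
  pose <- toy$bound
  tab <- build_pair_table(list(pose), seed = 5)
  e_native <- pair_transform_score(pose, tab)
  lc <- colMeans(atom_xyz(pose$ligand, "CA"))
  flipped <- pose_perturb_jump(pose, rotation_about_point(
    axis_angle_matrix(c(1, 0, 0), 180), lc))
  expect_lt(e_native, pair_transform_score(flipped, tab))
  f <- withr::local_tempfile(fileext = ".json")
  save_pair_table(tab, f)
  tab2 <- load_pair_table(f)
  expect_equal(pair_transform_score(pose, tab2), e_native, tolerance = 1e-12)
  expect_error(build_pair_table(list(
    pose_perturb_jump(pose, rigid_transform(diag(3), c(500, 0, 0)))
  )), "no contacts")
})

test_that("the composite score is linear in the weights and re-sums", {
  toy <- toy36()
  pose <- toy$bound
  b <- muds(pose)
  # total equals independent re-summation of the term array
  terms <- c(b$e_motif, b$e_lj_rep, b$e_lj_attr, b$e_rama, b$e_omega,
             b$e_aa_propensity)
  expect_equal(b$total, sum(unname(muds_weights()) * terms), tolerance = 1e-10)
  # all-zero weights
  w0 <- muds_weights(0, 0, 0, 0, 0, 0)
  expect_equal(muds(pose, w0)$total, 0)
  # doubling one weight moves the total by exactly that contribution
  w2 <- muds_weights(w_lj_rep = 0.2)
  expect_equal(muds(pose, w2)$total - b$total, 0.1 * b$e_lj_rep,
               tolerance = 1e-10)
  # deterministic and rigid-invariant
  expect_equal(muds(pose)$total, b$total)
  moved <- transform_pose(pose, random_rigid(4))
  expect_equal(muds(moved)$total, b$total, tolerance = 1e-7)
})

test_that("interface score vanishes for separated chains, flags clashes", {
  toy <- toy36()
  pose <- toy$bound
  sep <- pose_perturb_jump(pose, rigid_transform(diag(3), c(100, 0, 0)))
  expect_equal(interface_score(sep), 0, tolerance = 1e-9)
  # artificial overlap: slam the ligand into the receptor
  rc <- colMeans(atom_xyz(pose$receptor, "CA"))
  lc <- colMeans(atom_xyz(pose$ligand, "CA"))
  clashed <- pose_perturb_jump(pose, rigid_transform(diag(3), 0.8 * (rc - lc)))
  expect_gt(interface_score(clashed), 0)
  # equals an independently computed difference of three evaluations
  w <- refine_weights()
  tot <- function(rec, lig, gapshift) {
    if (gapshift) lig$xyz <- sweep(lig$xyz, 2, c(1e5, 0, 0), `+`)
    muds(coarse_pose(rec, lig), w, model = NULL)$total
  }
  whole <- muds(pose, w, model = NULL)$total
  apart <- tot(pose$receptor, pose$ligand, TRUE)
  expect_equal(interface_score(pose), whole - apart, tolerance = 1e-7)
})
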