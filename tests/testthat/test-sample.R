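test_that("interface selection matches brute force and is cutoff-monotone", {
  toy <- toy36()
  pose <- toy$bound
  for (cutoff in c(5.5, 8)) {
    sel <- select_interface(pose, cutoff)
    oracle <- brute_interface(pose, cutoff)
    expect_equal(sel$receptor, oracle$receptor)
    expect_equal(sel$ligand, oracle$ligand)
  }
  s55 <- select_interface(pose, 5.5)
  s8 <- select_interface(pose, 8)
  expect_true(all(s55$receptor %in% s8$receptor))
  expect_true(all(s55$ligand %in% s8$ligand))
  # controlled geometry: closest inter-chain atoms at exactly ~4 A vs ~6 A
  # (root search on the shift; a bare x-offset is not the closest distance)
  a <- make_helix(4, chain_id = "A")
  b <- make_helix(4, chain_id = "B")
  gap <- function(d) {
    mind <- function(s) {
      bb <- b; bb$xyz <- sweep(b$xyz, 2, c(s, 0, 0), `+`)
      min(flexidock:::cross_dist(a$xyz, bb$xyz)) - d
    }
    s <- stats::uniroot(mind, c(d, d + 60), tol = 1e-6)$root
    bb <- b; bb$xyz <- sweep(b$xyz, 2, c(s, 0, 0), `+`)
    coarse_pose(a, bb)
  }
  p4 <- gap(4)
  expect_gt(length(select_interface(p4, 5.5)$receptor), 0)
  p6 <- gap(6)
  expect_equal(length(select_interface(p6, 5.5)$receptor), 0)
  expect_gt(length(select_interface(p6, 8)$receptor), 0)
  # separated chains: empty selection, no error
  p100 <- gap(100)
  expect_equal(select_interface(p100, 8),
               list(receptor = integer(0), ligand = integer(0)))
})

test_that("loop augmentation unions the L-labeled residues", {
  helix <- make_helix(12)
  expect_equal(add_loop_residues(c(3L, 4L), rep("H", 12)), c(3L, 4L))
  labels <- c(rep("H", 5), rep("L", 4), rep("H", 5))
  expect_equal(add_loop_residues(c(2L, 6L), labels), c(2L, 6:9))
  expect_equal(add_loop_residues(integer(0), rep("L", 6)), 1:6)
})

test_that("contiguous fragments follow author numbering within chains", {
  ch <- make_helix(14)
  fr <- contiguous_fragments(c(3:5, 9:12), ch)
  expect_equal(length(fr), 2L)
  expect_equal(unlist(fr[[1]]), c(first = 3, last = 5))
  expect_equal(unlist(fr[[2]]), c(first = 9, last = 12))
  expect_equal(contiguous_fragments(c(3L, 4L), ch), list())
  # runs never cross a seq-numbering gap
  gapped <- ch
  gapped$seq <- c(1:7, 20:26)
  fr2 <- contiguous_fragments(5:10, gapped)
  expect_equal(lapply(fr2, unlist), list(c(first = 5, last = 7),
                                         c(first = 8, last = 10)))
})

test_that("mobile_selection modes and the directed list parser", {
  toy <- toy36()
  pose <- toy$bound
  sel <- mobile_selection(pose, "interface_8")
  expect_s3_class(sel, "mobile_selection")
  expect_true(all(vapply(sel$fragments, function(f) f$last - f$first >= 2, TRUE)))
  # plus_loops adds the receptor loop residues
  sel_l <- mobile_selection(pose, "interface_8_plus_loops")
  rec8 <- sel$residues$idx[sel$residues$partner == "receptor"]
  recl <- sel_l$residues$idx[sel_l$residues$partner == "receptor"]
  expect_true(all(toy$loop %in% recl))
  expect_true(all(rec8 %in% recl))
  # directed
  dd <- parse_residue_list(c("A:10-13", "# comment", "B:3"))
  expect_equal(dd$seq, c(10:13, 3))
  seld <- mobile_selection(pose, "directed", directed = dd)
  expect_setequal(seld$residues$seq[seld$residues$partner == "receptor"], 10:13)
  expect_error(mobile_selection(pose, "directed"), "requires")
  expect_error(parse_residue_list("A10"), "cannot parse")
})

test_that("rigid moves are seeded-reproducible with correct statistics", {
  toy <- toy36()
  pose <- toy$bound
  sched <- move_schedule(rigid_trans_sigma = 0.7, rigid_rot_sigma = 5)
  set.seed(11); p1 <- rigid_move(pose, sched)
  set.seed(11); p2 <- rigid_move(pose, sched)
  expect_identical(p1$ligand$xyz, p2$ligand$xyz)
  # receptor never moves
  expect_identical(p1$receptor$xyz, pose$receptor$xyz)
  # jump invariant maintained
  expect_lt(max(abs(rt_apply(p1$jump, p1$ligand_local) - p1$ligand$xyz)), 1e-8)
  # sigma -> 0 limit: pose unchanged
  tiny <- move_schedule(rigid_trans_sigma = 1e-12, rigid_rot_sigma = 1e-12)
  p0 <- rigid_move(pose, tiny)
  expect_lt(max(abs(p0$ligand$xyz - pose$ligand$xyz)), 1e-9)
  # mean displacement of the centroid matches the Gaussian norm expectation:
  # E||t|| for an isotropic 3-D Gaussian is sigma * sqrt(8/pi)
  set.seed(99)
  lc <- colMeans(atom_xyz(pose$ligand, "CA"))
  disp <- replicate(3000, {
    pm <- rigid_move(pose, sched)
    sqrt(sum((colMeans(atom_xyz(pm$ligand, "CA")) - lc)^2))
  })
  mu <- 0.7 * sqrt(8 / pi)
  se <- stats::sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp) - mu), 3 * se)
})

test_that("backbone moves are restricted to the chosen fragments", {
  toy <- toy36()
  pose <- toy$bound
  sel <- mobile_selection(pose, "directed",
                          directed = data.frame(chain = "A", seq = 9:14))
  expect_equal(length(sel$fragments), 1L)
  sched <- move_schedule(backrub_max_angle = 15)
  interior <- (sel$fragments[[1]]$first + 1):(sel$fragments[[1]]$last - 1)
  outside_rows <- setdiff(seq_len(nrow(pose$receptor$xyz)),
                          as.vector(sapply(interior, function(i) (i - 1) * 6 + 1:6)))
  set.seed(5)
  for (k in 1:50) {
    prop <- backbone_move(pose, sel, sched)
    expect_identical(prop$receptor$xyz[outside_rows, ],
                     pose$receptor$xyz[outside_rows, ])
    expect_identical(prop$ligand$xyz, pose$ligand$xyz)
  }
  # max_angle ~ 0 is the identity
  still <- backbone_move(pose, sel, move_schedule(backrub_max_angle = 1e-13))
  expect_lt(max(abs(still$receptor$xyz - pose$receptor$xyz)), 1e-9)
  # no fragments is an error the scheduler can fall back from
  empty_sel <- structure(list(mode = "directed", residues = NULL,
                              fragments = list()), class = "mobile_selection")
  expect_error(backbone_move(pose, empty_sel, sched), "no mobile fragments")
})

test_that("local initialization applies the stated offsets exactly", {
  toy <- toy36(unbound_angle = 0)
  rec <- toy$bound$receptor; lig <- toy$bound$ligand
  start <- init_local(rec, lig, perturb = FALSE)
  rc <- colMeans(atom_xyz(rec, "CA"))
  lc0 <- colMeans(atom_xyz(lig, "CA"))
  lc1 <- colMeans(atom_xyz(start$ligand, "CA"))
  # centroid separation grows by exactly 15 A (rotation is about an axis
  # through the ligand centroid, so it does not move the centroid)
  expect_equal(vnorm(lc1 - rc) - vnorm(lc0 - rc), 15, tolerance = 1e-8)
  # the applied rotation angle is exactly 45 degrees
  u <- (lc0 - rc) / vnorm(lc0 - rc)
  fit <- kabsch(lig$xyz, start$ligand$xyz)
  rv <- matrix_to_rotvec(fit$transform$R)
  expect_equal(vnorm(rv), deg2rad(45), tolerance = 1e-8)
  expect_equal(abs(sum(rv / vnorm(rv) * u)), 1, tolerance = 1e-8)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  # perturbed starts are seeded-reproducible
  set.seed(3); a <- init_local(rec, lig, perturb = TRUE)
  set.seed(3); b <- init_local(rec, lig, perturb = TRUE)
  expect_identical(a$ligand$xyz, b$ligand$xyz)
  # perturbation statistics: per-axis Gaussian sigma 1 A on the centroid
  set.seed(31)
  lc_exact <- colMeans(atom_xyz(init_local(rec, lig, perturb = FALSE)$ligand, "CA"))
  offs <- replicate(2000, {
    p <- init_local(rec, lig, perturb = TRUE)
    sqrt(sum((colMeans(atom_xyz(p$ligand, "CA")) - lc_exact)^2))
  })
  mu <- sqrt(8 / pi)
  expect_lt(abs(mean(offs) - mu), 3 * stats::sd(offs) / sqrt(length(offs)))
  # coincident centroids are rejected
  lig0 <- lig
  lig0$xyz <- sweep(lig$xyz, 2, colMeans(atom_xyz(lig, "CA")) - rc, `-`)
  expect_error(init_local(rec, lig0, perturb = FALSE),
               "undefined separation axis")
})

test_that("superposition onto a bound reference precedes the offsets", {
  toy <- toy36(unbound_angle = 0)
  rec <- toy$bound$receptor; lig <- toy$bound$ligand
  # scramble the monomers far away; the bound reference must bring them back
  moved_rec <- rec; moved_rec$xyz <- rt_apply(random_rigid(8), rec$xyz)
  moved_lig <- lig; moved_lig$xyz <- rt_apply(random_rigid(9), lig$xyz)
  start <- init_local(moved_rec, moved_lig, bound_reference = toy$bound,
                      perturb = FALSE)
  expect_lt(max(abs(backbone_xyz(start$receptor) - backbone_xyz(rec))), 1e-6)
  lc0 <- colMeans(atom_xyz(lig, "CA"))
  lc1 <- colMeans(atom_xyz(start$ligand, "CA"))
  rc <- colMeans(atom_xyz(rec, "CA"))
  expect_equal(vnorm(lc1 - rc) - vnorm(lc0 - rc), 15, tolerance = 1e-6)
})

test_that("global initialization is uniform over directions and in contact", {
  toy <- toy36(unbound_angle = 0)
  rec <- toy$bound$receptor; lig <- toy$bound$ligand
  set.seed(21)
  dirs <- matrix(0, 300, 3)
  for (k in seq_len(nrow(dirs))) {
    p <- init_global(rec, lig)
    d <- min(flexidock:::cross_dist(p$receptor$xyz, p$ligand$xyz))
    expect_lte(d, 4.5 + 1e-9)
    expect_gte(d, 2.2)
    u <- colMeans(atom_xyz(p$ligand, "CA")) - colMeans(atom_xyz(p$receptor, "CA"))
    dirs[k, ] <- u / vnorm(u)
  }
  # chi-squared uniformity over the 8 octants of the sphere
  oct <- 1 + (dirs[, 1] > 0) + 2 * (dirs[, 2] > 0) + 4 * (dirs[, 3] > 0)
  cs <- stats::chisq.test(tabulate(oct, 8))
  expect_gt(cs$p.value, 0.001)
  # seeded reproducibility
  set.seed(77); g1 <- init_global(rec, lig)
  set.seed(77); g2 <- init_global(rec, lig)
  expect_identical(g1$ligand$xyz, g2$ligand$xyz)
})

test_that("slide_into_contact lands in the contact window", {
  toy <- toy36(unbound_angle = 0)
  pose <- toy$bound
  mind <- function(p) min(flexidock:::cross_dist(p$receptor$xyz, p$ligand$xyz))
  # already in contact: unchanged
  expect_identical(slide_into_contact(pose)$ligand$xyz, pose$ligand$xyz)
  # 50 A out along the centroid axis
  rc <- colMeans(atom_xyz(pose$receptor, "CA"))
  lc <- colMeans(atom_xyz(pose$ligand, "CA"))
  u <- (lc - rc) / vnorm(lc - rc)
  far <- pose_perturb_jump(pose, rigid_transform(diag(3), 50 * u))
  slid <- slide_into_contact(far)
  d <- mind(slid)
  expect_gte(d, 3.5 - 0.2 - 1e-9)  # may back off one step from below lo
  expect_lte(d, 4.5 + 1e-9)
  # line-search oracle: no coarser placement along the approach that is
  # still outside the window but closer than the result
  expect_error(slide_into_contact(
    pose_perturb_jump(pose, rigid_transform(diag(3), 500 * u))), "200")
})
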