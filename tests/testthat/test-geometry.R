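test_that("superposing a set onto itself is the identity", {
  set.seed(10)
  m <- matrix(rnorm(30), 10, 3)
  sp <- kabsch_superpose(m, m)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
})

test_that("an exact rigid motion is inverted to machine precision", {
  set.seed(11)
  m <- matrix(rnorm(30), 10, 3)
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  ref <- sweep(m %*% R, 2, c(1, 2, 3), `+`)
  sp <- kabsch_superpose(m, ref)
  expect_lt(sp$rmsd, 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_superposition(m, sp), ref, tolerance = 1e-8)
})

test_that("Kabsch RMSD matches the quaternion oracle on random noisy instances", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(4:30, 1)
      m <- matrix(rnorm(n * 3), n, 3)
      ref <- random_rigid(m, seed = seed + 1000) + matrix(rnorm(n * 3, 0, 0.1), n, 3)
      sp <- kabsch_superpose(m, ref)
      expect_equal(sp$rmsd, quaternion_superpose_rmsd(m, ref), tolerance = 1e-6)
      expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    })
  }
})

test_that("superposition RMSD is invariant under pre-applied rigid motions", {
  set.seed(12)
  m <- matrix(rnorm(24), 8, 3)
  ref <- m + matrix(rnorm(24, 0, 0.3), 8, 3)
  base <- kabsch_superpose(m, ref)$rmsd
  for (seed in 1:10) {
    moved <- random_rigid(m, seed = seed)
    expect_equal(kabsch_superpose(moved, ref)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("superposition rejects mismatched or tiny point sets", {
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               class = "iface_congruence_error")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "iface_rank_error")
})

test_that("the average complex is the coordinate mean after receptor fit", {
  rec <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0, 5, 5, 1), 4, 3, byrow = TRUE)
  lig0 <- matrix(c(2, 2, 5), 1)
  d <- 1.5
  p1 <- toy_structure(A = rec, L = lig0 + c(d, 0, 0))
  p2 <- toy_structure(A = rec, L = lig0 - c(d, 0, 0))
  av <- average_complex(list(p1, p2), receptor_chains = "A")
  lig_mean <- av$reference[av$reference$chain == "L", ]
  expect_equal(c(lig_mean$x, lig_mean$y, lig_mean$z), as.numeric(lig0),
               tolerance = 1e-8)
  # identical poses: average equals the pose, medoid is pose 1
  av2 <- average_complex(list(p1, p1, p1), receptor_chains = "A")
  expect_equal(av2$medoid, 1)
  expect_equal(as.data.frame(av2$reference), as.data.frame(p1), tolerance = 1e-10)
})

test_that("the medoid equals the brute-force argmin of mean pairwise RMSD", {
  rec <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0, 5, 5, 1, 2, 2, 2), 5, 3,
                byrow = TRUE)
  poses <- lapply(1:5, function(k) {
    withr::with_seed(k, {
      toy_structure(A = rec, L = matrix(c(2, 2, 6), 1) +
                      matrix(rnorm(3, 0, k / 4), 1))
    })
  })
  av <- average_complex(poses, receptor_chains = "A")
  coords <- lapply(av$aligned, function(p) as.matrix(p[, c("x", "y", "z")]))
  mean_rmsd <- sapply(1:5, function(i) {
    mean(sapply(setdiff(1:5, i), function(j) {
      sqrt(mean(rowSums((coords[[i]] - coords[[j]])^2)))
    }))
  })
  expect_equal(av$medoid, which.min(mean_rmsd))
})

test_that("iRMSD is zero for the reference and follows the closed form", {
  rec <- matrix(cbind(seq(0, 20, length.out = 5), 0, 0), 5, 3)
  lig <- matrix(cbind(seq(0, 20, length.out = 5), 5, 0), 5, 3)
  ref <- toy_structure(A = rec, L = lig)
  expect_equal(interface_rmsd(ref, ref, "A", "L"), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  # ligand rigidly translated 2 A, equal interface CA counts on both sides
  pose <- ref
  pose$z[pose$chain == "L"] <- pose$z[pose$chain == "L"] + 2
  expect_equal(interface_rmsd(pose, ref, "A", "L"), 2 / sqrt(2),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("iRMSD equals a direct per-atom recomputation on jittered poses", {
  base <- make_dimer_complex(site_residues = c(3, 6, 9), seed = 20)
  ens <- make_pose_ensemble(base, n_poses = 20, target_freqs = 1, seed = 21)
  poses <- split(ens, ens$pose)
  ref <- poses[[1]][, setdiff(names(poses[[1]]), "pose")]
  for (k in c(2, 7, 13, 20)) {
    pose <- poses[[k]][, setdiff(names(poses[[k]]), "pose")]
    v <- interface_rmsd(pose, ref, c("A", "B"), "L")
    iface <- attr(v, "interface")
    # receptor is identical across poses -> fit is identity; recompute directly
    keys_p <- paste(pose$chain, pose$resno, pose$icode, sep = "|")
    keys_r <- paste(ref$chain, ref$resno, ref$icode, sep = "|")
    sel_p <- pose[keys_p %in% iface & pose$atom == "CA", ]
    sel_r <- ref[keys_r %in% iface & ref$atom == "CA", ]
    direct <- sqrt(mean((sel_p$x - sel_r$x)^2 + (sel_p$y - sel_r$y)^2 +
                          (sel_p$z - sel_r$z)^2))
    expect_equal(as.numeric(v), direct, tolerance = 1e-9)
  }
})

test_that("enlarging the interface cutoff never shrinks the interface set", {
  base <- make_dimer_complex(site_residues = c(3, 6, 9), seed = 22)
  prev <- 0
  for (cut in c(5, 10, 20, 40)) {
    v <- interface_rmsd(base, base, c("A", "B"), "L", interface_cutoff = cut)
    n <- length(attr(v, "interface"))
    expect_gte(n, prev)
    prev <- n
  }
  expect_error(interface_rmsd(base, base, c("A", "B"), "L",
                              interface_cutoff = 0.1),
               class = "iface_definition_error")
})

test_that("funnel analysis classifies perfect monotone relations", {
  x <- seq(0.5, 10, length.out = 50)
  up <- tibble::tibble(score = x, irmsd = x)
  f <- funnel_analysis(up)
  expect_equal(f$rho, 1.0)
  expect_true(f$is_funnel)
  down <- tibble::tibble(score = -x, irmsd = x)
  f2 <- funnel_analysis(down)
  expect_equal(f2$rho, -1.0)
  expect_false(f2$is_funnel)
})

test_that("funnel rho matches a from-scratch rank correlation", {
  for (seed in 1:30) {
    withr::with_seed(seed, {
      pts <- tibble::tibble(score = rnorm(60), irmsd = runif(60, 0, 10))
      f <- funnel_analysis(pts)
      expect_equal(f$rho, spearman_scratch(pts$score, pts$irmsd),
                   tolerance = 1e-12)
    })
  }
})

test_that("a planted funnel is detected and its shuffled null is not", {
  pts <- make_funnel_points(n = 200, seed = 42)
  null <- make_funnel_points(n = 200, shuffle = TRUE, seed = 42)
  expect_true(funnel_analysis(pts)$is_funnel)
  expect_false(funnel_analysis(null)$is_funnel)
})

test_that("funnel analysis rejects degenerate inputs", {
  expect_error(funnel_analysis(tibble::tibble(score = 1:10, irmsd = 1:10)),
               class = "iface_sample_size_error")
  expect_error(funnel_analysis(tibble::tibble(score = rep(1, 25),
                                              irmsd = runif(25))),
               class = "iface_degenerate_error")
})

test_that("RMSD traces are zero for static or rigidly drifting trajectories", {
  topo <- toy_structure(A = matrix(rnorm(30), 10, 3))
  static <- new_trajectory(topo, array(rep(as.matrix(topo[, c("x", "y", "z")]),
                                           each = 5),
                                       dim = c(5, 10, 3)), dt = 2)
  # array built above repeats per-element; rebuild properly
  coords <- array(NA_real_, dim = c(5, 10, 3))
  for (f in 1:5) coords[f, , ] <- as.matrix(topo[, c("x", "y", "z")])
  static <- new_trajectory(topo, coords, dt = 2)
  tr <- rmsd_trace(static)
  expect_equal(tr$rmsd, rep(0, 5), tolerance = 1e-10)
  expect_equal(tr$time_ps, (0:4) * 2)
  # pure translations are removed by the fit
  for (f in 1:5) coords[f, , ] <- sweep(coords[f, , ], 2, c(0.1, 0.2, 0.3) * f, `+`)
  moved <- new_trajectory(topo, coords, dt = 2)
  expect_equal(rmsd_trace(moved)$rmsd, rep(0, 5), tolerance = 1e-10)
})

test_that("trace values match a per-frame superposition oracle", {
  topo <- toy_structure(A = matrix(rnorm(30), 10, 3))
  trj <- make_trajectory(topo, sigma = 0.4, n_frames = 20, dt = 2, seed = 31)
  tr <- rmsd_trace(trj)
  for (f in c(1, 7, 20)) {
    expect_equal(tr$rmsd[f],
                 quaternion_superpose_rmsd(trj$coords[f, , ],
                                           as.matrix(topo[, c("x", "y", "z")])),
                 tolerance = 1e-8)
  }
})

test_that("equilibration detection finds the earliest stable window", {
  flat <- tibble::tibble(time_ps = (0:49) * 2, rmsd = rep(1, 50))
  eq <- equilibration_time(flat)
  expect_true(eq$reached)
  expect_equal(eq$time_ps, 0)
  rising <- tibble::tibble(time_ps = (0:49) * 2, rmsd = 0.1 * (0:49))
  expect_false(equilibration_time(rising)$reached)
  # flat after frame 26 (1-based), i.e. from index 25 in 0-based frame terms
  y <- c(seq(5, 1, length.out = 25), rep(1, 25))
  pw <- tibble::tibble(time_ps = (0:49) * 2, rmsd = y)
  eq2 <- equilibration_time(pw, window = 10, band = 0.5)
  expect_true(eq2$reached)
  expect_lte(eq2$time_ps, 25 * 2)
  expect_equal(equilibration_time(pw, window = 10, band = 0.5)$frame,
               which(sapply(1:41, function(j) {
                 all(sapply(j:41, function(i) diff(range(y[i:(i + 9)])) <= 0.5))
               }))[1])
  expect_error(equilibration_time(flat, window = 100),
               class = "iface_parameter_error")
})

test_that("RMSF is zero for a static trajectory and exact for an oscillator", {
  topo <- toy_structure(A = matrix(rnorm(30, sd = 5), 10, 3))
  coords <- array(NA_real_, dim = c(8, 10, 3))
  for (f in 1:8) coords[f, , ] <- as.matrix(topo[, c("x", "y", "z")])
  static <- new_trajectory(topo, coords, dt = 2)
  expect_equal(rmsf(static)$rmsf, rep(0, 10), tolerance = 1e-10)
  # atom 1 oscillates +/- d along x around its mean; align = FALSE
  d <- 0.7
  coords2 <- coords
  coords2[, 1, 1] <- coords2[, 1, 1] + rep(c(d, -d), 4)
  osc <- new_trajectory(topo, coords2, dt = 2)
  pr <- rmsf(osc, align = FALSE)
  expect_equal(pr$rmsf[1], d, tolerance = 1e-10)
  expect_equal(pr$rmsf[-1], rep(0, 9), tolerance = 1e-10)
  expect_error(rmsf(new_trajectory(topo, coords[1, , , drop = FALSE], dt = 2)),
               class = "iface_input_error")
})

test_that("RMSF is invariant to frame order", {
  topo <- toy_structure(A = matrix(rnorm(18), 6, 3))
  trj <- make_trajectory(topo, sigma = 0.5, n_frames = 40, dt = 2, seed = 33)
  shuf <- trj
  withr::with_seed(1, {
    shuf$coords <- trj$coords[sample(40), , , drop = FALSE]
  })
  expect_equal(rmsf(shuf)$rmsf, rmsf(trj)$rmsf, tolerance = 1e-10)
})

test_that("planted isotropic sigma is recovered as sigma * sqrt(3)", {
  # enough atoms that the 6 rigid-fit degrees of freedom absorb <2% of the
  # fluctuation variance; MC error of the across-atom mean is negligible
  withr::with_seed(34, {
    topo <- toy_structure(A = matrix(rnorm(180, sd = 8), 60, 3))
  })
  trj <- make_trajectory(topo, sigma = 0.5, n_frames = 500, dt = 2, seed = 34)
  pr <- rmsf(trj)
  expect_equal(mean(pr$rmsf), 0.5 * sqrt(3), tolerance = 0.03)
})

test_that("proximal/distant RMSF deltas summarise rigidification", {
  base <- make_dimer_complex(n_res_per_subunit = 20, site_residues = c(2),
                             seed = 40)
  keys <- unique(paste(base$chain, base$resno, base$icode, sep = "|"))
  sig <- stats::setNames(ifelse(startsWith(keys, "A|"), 0.25, 0.5), keys)
  trj <- make_trajectory(base, sigma = sig, n_frames = 300, dt = 2, seed = 41)
  prof <- rmsf(trj)
  smap <- symmetry_map_chains(base, "A", "B")
  iface <- tibble::tibble(chain = "A", resno = 1:20, icode = "")
  dl <- rmsf_delta(prof, smap, iface)
  expect_equal(attr(dl, "fraction_lower"), 1.0)
  expect_true(all(dl$delta < 0))
  # symmetric planting: fraction near 0.5
  trj2 <- make_trajectory(base, sigma = 0.4, n_frames = 300, dt = 2, seed = 42)
  dl2 <- rmsf_delta(rmsf(trj2), smap, iface)
  expect_gt(attr(dl2, "fraction_lower"), 0.2)
  expect_lt(attr(dl2, "fraction_lower"), 0.8)
  expect_error(rmsf_delta(prof, smap, iface[0, ]), class = "iface_input_error")
  expect_error(rmsf_delta(prof, smap,
                          tibble::tibble(chain = "Q", resno = 1, icode = "")),
               class = "iface_map_coverage_error")
})
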