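test_that("contact inclusion follows the distance cutoff exactly", {
  near <- toy_structure(A = matrix(c(0, 0, 0), 1), L = matrix(c(2.9, 0, 0), 1))
  far <- toy_structure(A = matrix(c(0, 0, 0), 1), L = matrix(c(3.1, 0, 0), 1))
  expect_equal(nrow(residue_contacts(near, "A", "L", cutoff = 3)), 1)
  expect_equal(nrow(residue_contacts(far, "A", "L", cutoff = 3)), 0)
})

test_that("cell-list search equals all-pairs brute force on random complexes", {
  for (seed in 1:40) {
    n_rec <- sample(5:40, 1)
    n_lig <- sample(5:40, 1)
    s <- random_complex(n_rec, n_lig, box = 15, seed = seed)
    cs <- residue_contacts(s, "A", "L", cutoff = 3)
    expect_equal(contact_pairs_as_keys(cs),
                 brute_force_contacts(s, "A", "L", cutoff = 3),
                 info = paste("seed", seed))
  }
})

test_that("contacts grow monotonically with the cutoff", {
  s <- random_complex(30, 30, box = 12, seed = 99)
  prev <- character(0)
  for (cutoff in c(2, 3, 4.5, 6)) {
    cur <- contact_pairs_as_keys(residue_contacts(s, "A", "L", cutoff = cutoff))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("hydrogens are excluded from the default heavy-atom selection", {
  s <- toy_structure(A = matrix(c(0, 0, 0), 1), L = matrix(c(10, 0, 0), 1))
  h <- tibble::tibble(chain = "L", resno = 1L, icode = "", resid = "ALA",
                      atom = "H1", element = "H", x = 2, y = 0, z = 0,
                      occupancy = 1, altloc = "", hetero = FALSE)
  s2 <- dplyr::bind_rows(s, h)
  expect_equal(nrow(residue_contacts(s2, "A", "L", cutoff = 3)), 0)
  expect_equal(nrow(residue_contacts(s2, "A", "L", cutoff = 3, atoms = "all")), 1)
})

test_that("chain partition errors are typed", {
  s <- random_complex(5, 5, seed = 1)
  expect_error(residue_contacts(s, "A", "A"), class = "iface_partition_error")
  expect_error(residue_contacts(s, character(0), "L"),
               class = "iface_partition_error")
  expect_error(residue_contacts(s, "A", "Z"), class = "iface_lookup_error")
  expect_error(residue_contacts(s, "A", "L", cutoff = -1),
               class = "iface_input_error")
})

test_that("prevalence counts poses, reproducing planted frequencies exactly", {
  base <- make_dimer_complex(site_residues = c(4, 8, 12), seed = 2)
  ens <- make_pose_ensemble(base, n_poses = 30,
                            target_freqs = c(0.8, 0.5, 0.1), seed = 5)
  prof <- prevalence_profile(ens, c("A", "B"), "L")
  rec <- dplyr::filter(prof, side == "receptor", chain == "A",
                       resno %in% c(4, 8, 12))
  expect_equal(rec$freq[order(rec$resno)], c(0.8, 0.5, 0.1))
  # frequency x n_poses is integral for every residue
  expect_true(all(abs(prof$freq * prof$n_poses -
                        round(prof$freq * prof$n_poses)) < 1e-12))
  # all other receptor residues never touch the ligand
  other <- dplyr::filter(prof, side == "receptor", !(chain == "A" & resno %in% c(4, 8, 12)))
  expect_true(all(other$freq == 0))
  # ligand-side profile produced in the same call
  expect_true(any(prof$side == "ligand"))
})

test_that("prevalence is invariant under a rigid motion of each complex", {
  base <- make_dimer_complex(site_residues = c(4, 8), seed = 3)
  ens <- make_pose_ensemble(base, n_poses = 10, target_freqs = c(0.7, 0.3),
                            seed = 7)
  moved <- dplyr::bind_rows(lapply(split(ens, ens$pose), function(p) {
    transform_structure(p, seed = p$pose[1])
  }))
  p1 <- prevalence_profile(ens, c("A", "B"), "L")
  p2 <- prevalence_profile(moved, c("A", "B"), "L")
  expect_equal(p2$freq, p1$freq)
})

test_that("symmetry folding applies the union rule over poses", {
  # copy A in contact in pose 1 only, copy B in pose 2 only -> folded 1.0
  base <- make_dimer_complex(n_res_per_subunit = 6, n_res_ligand = 4,
                             site_residues = tibble::tibble(
                               chain = c("A", "B"), resno = c(2, 2)),
                             seed = 4)
  rec <- base[base$chain != "L", ]
  lig <- base[base$chain == "L", ]
  # pose 1: only the A-site probe in contact; pose 2: only the B-site probe
  mk_pose <- function(on_idx, k) {
    lg <- lig
    for (j in 1:2) {
      if (j != on_idx) lg$z[j] <- lg$z[j] + 10
    }
    p <- dplyr::bind_rows(rec, lg); p$pose <- k; p
  }
  ens <- dplyr::bind_rows(mk_pose(1, 1), mk_pose(2, 2))
  prof <- prevalence_profile(ens, c("A", "B"), "L")
  expect_equal(dplyr::filter(prof, chain == "A", resno == 2)$freq, 0.5)
  expect_equal(dplyr::filter(prof, chain == "B", resno == 2)$freq, 0.5)
  folded <- fold_dimer_symmetry(prof, symmetry_map_chains(base, "A", "B"))
  expect_equal(dplyr::filter(folded, resno == 2)$freq, 1.0)
  expect_equal(dplyr::filter(folded, resno == 3)$freq, 0.0)
  expect_true(all(folded$chain == "A"))
})

test_that("folded frequency respects the union bounds on random ensembles", {
  base <- make_dimer_complex(site_residues = tibble::tibble(
    chain = c("A", "B", "A"), resno = c(3, 3, 9)), seed = 6)
  ens <- make_pose_ensemble(base, n_poses = 20,
                            target_freqs = c(0.6, 0.5, 0.3), seed = 8)
  prof <- prevalence_profile(ens, c("A", "B"), "L")
  folded <- fold_dimer_symmetry(prof, symmetry_map_chains(base, "A", "B"))
  fa <- dplyr::filter(prof, chain == "A")
  fb <- dplyr::filter(prof, chain == "B")
  ff <- folded$freq[match(fa$resno, folded$resno)]
  expect_true(all(ff >= pmax(fa$freq, fb$freq) - 1e-12))
  expect_true(all(ff <= pmin(fa$freq + fb$freq, 1) + 1e-12))
  # brute-force union count over the planted pose sets
  truth <- attr(ens, "truth")
  for (r in unique(truth$site_residues$resno)) {
    idx <- which(truth$site_residues$resno == r)
    union_poses <- sort(unique(unlist(truth$contact_poses[idx])))
    expect_equal(dplyr::filter(folded, resno == r)$count, length(union_poses))
  }
})

test_that("folding rejects non-bijective or incomplete maps", {
  base <- make_dimer_complex(site_residues = c(2), seed = 1)
  ens <- make_pose_ensemble(base, n_poses = 4, target_freqs = 1, seed = 1)
  prof <- prevalence_profile(ens, c("A", "B"), "L")
  cm <- symmetry_map_chains(base, "A", "B")
  bad <- cm; bad$resno_b[2] <- bad$resno_b[1]
  expect_error(fold_dimer_symmetry(prof, bad), class = "iface_symmetry_map_error")
  expect_error(fold_dimer_symmetry(prof, cm[-1, ]),
               class = "iface_symmetry_map_error")
})

test_that("profile averaging is unweighted with sample SD", {
  mk <- function(freqs, seed) {
    base <- make_dimer_complex(site_residues = c(3, 6), seed = seed)
    ens <- make_pose_ensemble(base, n_poses = 10, target_freqs = freqs,
                              seed = seed)
    prevalence_profile(ens, c("A", "B"), "L")
  }
  p1 <- mk(c(1.0, 0.2), 1); p2 <- mk(c(1.0, 0.6), 1); p3 <- mk(c(1.0, 0.4), 1)
  av <- average_profiles(list(p1, p2, p3))
  r3 <- dplyr::filter(av, side == "receptor", chain == "A", resno == 3)
  r6 <- dplyr::filter(av, side == "receptor", chain == "A", resno == 6)
  expect_equal(r3$mean, 1.0)
  expect_equal(r3$sd, 0.0)
  expect_equal(r6$mean, mean(c(0.2, 0.6, 0.4)))
  expect_equal(r6$sd, sd(c(0.2, 0.6, 0.4)))
  expect_error(average_profiles(list(p1)), class = "iface_input_error")
  # mismatched key space
  p4 <- mk(c(1.0, 0.5), 2)
  p4$resno[1] <- 999L
  expect_error(average_profiles(list(p1, p4)), class = "iface_congruence_error")
})

test_that("two-profile averaging of 0 and 1 gives 0.5", {
  base <- make_dimer_complex(site_residues = c(5), seed = 9)
  e1 <- make_pose_ensemble(base, n_poses = 10, target_freqs = 0, seed = 1)
  e2 <- make_pose_ensemble(base, n_poses = 10, target_freqs = 1, seed = 1)
  p1 <- prevalence_profile(e1, c("A", "B"), "L")
  p2 <- prevalence_profile(e2, c("A", "B"), "L")
  av <- average_profiles(list(p1, p2))
  expect_equal(dplyr::filter(av, chain == "A", resno == 5)$mean, 0.5)
})

test_that("domain localization index and flag follow the top-k shares", {
  prof <- tibble::tibble(
    side = "receptor", chain = "A", resno = 1:40, icode = "", resid = "ALA",
    mean = c(rep(0.9, 16), rep(0.8, 4), rep(0.05, 20)), sd = 0,
    n_ensembles = 3
  )
  part <- tibble::tibble(domain = c("kinase", "sulfurylase"), chain = "A",
                         start = c(1, 17), end = c(16, 40))
  loc <- domain_localization(prof, part, top_k = 20)
  expect_equal(attr(loc, "localization_index"), 0.8)
  expect_true(attr(loc, "localized"))
  # all in one domain
  part1 <- tibble::tibble(domain = "kinase", chain = "A", start = 1, end = 40)
  loc1 <- domain_localization(prof, part1, top_k = 20)
  expect_equal(attr(loc1, "localization_index"), 1.0)
  # 10/10 split
  part2 <- tibble::tibble(domain = c("d1", "d2"), chain = "A",
                          start = c(1, 11), end = c(10, 40))
  prof2 <- dplyr::mutate(prof, mean = c(rep(0.9, 20), rep(0.05, 20)))
  loc2 <- domain_localization(prof2, part2, top_k = 20)
  expect_equal(attr(loc2, "localization_index"), 0.5)
  expect_false(attr(loc2, "localized"))
  # ties broken by ascending residue number: deterministic top set
  top <- attr(domain_localization(prof, part, top_k = 20), "top_residues")
  expect_equal(top$resno, 1:20)
  expect_error(domain_localization(prof[0, ], part, top_k = 2),
               class = "iface_input_error")
  expect_error(domain_localization(prof, part, top_k = 99),
               class = "iface_input_error")
  over <- tibble::tibble(domain = c("a", "b"), chain = "A",
                         start = c(1, 5), end = c(10, 12))
  expect_error(domain_localization(prof, over, top_k = 5),
               class = "iface_input_error")
})

test_that("composite-site fraction counts poses with both subunits engaged", {
  base <- make_dimer_complex(
    n_res_per_subunit = 12, n_res_ligand = 8,
    site_residues = tibble::tibble(chain = rep(c("A", "B"), each = 3),
                                   resno = c(2, 5, 8, 2, 5, 8)),
    seed = 3)
  ens <- make_pose_ensemble(base, n_poses = 10, target_freqs = 1, seed = 2)
  res <- composite_site_fraction(ens, c("A", "B"), "L")
  expect_equal(attr(res, "fraction"), 1.0)
  expect_true(all(res$composite))
  # one-sided site is never composite
  base1 <- make_dimer_complex(n_res_per_subunit = 12, n_res_ligand = 8,
                              site_residues = c(2, 5, 8, 10, 11), seed = 3)
  ens1 <- make_pose_ensemble(base1, n_poses = 5, target_freqs = 1, seed = 2)
  res1 <- composite_site_fraction(ens1, c("A", "B"), "L")
  expect_equal(attr(res1, "fraction"), 0.0)
  expect_error(composite_site_fraction(ens, "A", "L"),
               class = "iface_partition_error")
})

test_that("a planted 7-of-10 composite ensemble yields fraction 0.7", {
  base <- make_dimer_complex(
    n_res_per_subunit = 12, n_res_ligand = 8,
    site_residues = tibble::tibble(chain = rep(c("A", "B"), each = 3),
                                   resno = c(2, 5, 8, 2, 5, 8)),
    seed = 3)
  rec <- base[base$chain != "L", ]
  lig <- base[base$chain == "L", ]
  poses <- lapply(1:10, function(k) {
    lg <- lig
    if (k > 7) lg$z[4:6] <- lg$z[4:6] + 10  # retract all B-side probes
    p <- dplyr::bind_rows(rec, lg); p$pose <- k; p
  })
  res <- composite_site_fraction(dplyr::bind_rows(poses), c("A", "B"), "L")
  expect_equal(attr(res, "fraction"), 0.7)
})
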