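# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments (seed included) and attaches its planted ground truth as the
# `truth` attribute, so each downstream stage can be tested by recovery.

#' Generate a C2-symmetric dimer with a docked ligand and planted contacts
#'
#' Builds a minimal dimeric receptor (two chains, `A` and `B`, related by an
#' exact C2 rotation about z) plus a monomeric ligand chain `L` placed so
#' that exactly the requested receptor residues have heavy atoms within
#' 3.0 Å of the ligand, with a guard margin on both sides of the cutoff
#' (planted contacts at <= 2.7 Å, everything else >= 3.3 Å). Geometry is
#' deliberately minimal — two pseudo-atoms (CA, CB) per receptor residue and
#' one per ligand residue — the contact semantics, not the stereochemistry,
#' are what downstream stages consume.
#'
#' @param n_res_per_subunit Residues per receptor subunit.
#' @param n_res_ligand Residues in the ligand chain (must be >= number of
#'   planted contacts).
#' @param site_residues Planted contact residues: integer vector of chain-A
#'   residue numbers, or a tibble with columns `chain` (`"A"`/`"B"`) and
#'   `resno` for composite sites.
#' @param composite If `TRUE` and `site_residues` is a bare vector, planted
#'   contacts alternate between chains A and B.
#' @param seed Integer seed (all randomness local to the call).
#' @return A structure tibble; attribute `truth` records the planted site,
#'   the chain roles and the exact C2 operator.
#' @export
make_dimer_complex <- function(n_res_per_subunit = 40, n_res_ligand = 12,
                               site_residues = integer(0), composite = FALSE,
                               seed = 1) {
  if (is.numeric(site_residues)) {
    chains <- if (composite && length(site_residues) > 1) {
      rep(c("A", "B"), length.out = length(site_residues))
    } else rep("A", length(site_residues))
    site <- tibble(chain = chains, resno = as.integer(site_residues))
  } else {
    site <- as_tibble(site_residues)
  }
  if (nrow(site) > 0 &&
      (any(!site$chain %in% c("A", "B")) ||
       any(site$resno < 1 | site$resno > n_res_per_subunit))) {
    abort("site_residues outside receptor numbering.",
          class = "iface_generation_error")
  }
  if (nrow(site) > n_res_ligand) {
    abort("more planted contacts than ligand residues.",
          class = "iface_generation_error")
  }
  withr::with_seed(seed, {
    i <- seq_len(n_res_per_subunit)
    # chain A backbone: along x with mild out-of-line variation (z = 0)
    ca_a <- cbind(5 * i, 8 + 0.6 * sin(i), 0)
    cb_a <- ca_a + matrix(rep(c(0, 0, -1.5), each = n_res_per_subunit), ncol = 3)
    # exact C2 about z: (x, y, z) -> (-x, -y, z)
    c2 <- diag(c(-1, -1, 1))
    ca_b <- ca_a %*% c2
    cb_b <- cb_a %*% c2
    res_block <- function(chain, ca, cb) {
      n <- nrow(ca)
      tibble(
        chain = chain,
        resno = rep(i, each = 2),
        icode = "", resid = "ALA",
        atom = rep(c("CA", "CB"), n),
        element = "C",
        x = as.vector(rbind(ca[, 1], cb[, 1])),
        y = as.vector(rbind(ca[, 2], cb[, 2])),
        z = as.vector(rbind(ca[, 3], cb[, 3])),
        occupancy = 1, altloc = "", hetero = FALSE
      )
    }
    rec <- bind_rows(res_block("A", ca_a, cb_a), res_block("B", ca_b, cb_b))
    # ligand: first nrow(site) residues are contact probes, rest far anchors
    lig_rows <- vector("list", n_res_ligand)
    for (j in seq_len(n_res_ligand)) {
      if (j <= nrow(site)) {
        ca_site <- if (site$chain[j] == "A") ca_a[site$resno[j], ] else ca_b[site$resno[j], ]
        pos <- ca_site + c(0, 0, 2.4 + 0.25 * runif(1))  # <= 2.65 < 2.7
      } else {
        pos <- c(5 * j, 0.7 * sin(j), 30 + 0.5 * cos(j))
      }
      lig_rows[[j]] <- tibble(chain = "L", resno = j, icode = "", resid = "GLY",
                              atom = "CA", element = "C",
                              x = pos[1], y = pos[2], z = pos[3],
                              occupancy = 1, altloc = "", hetero = FALSE)
    }
    out <- new_structure(bind_rows(rec, bind_rows(lig_rows)),
                         id = "synthetic_dimer_complex", source = "generator")
    attr(out, "truth") <- list(
      site_residues = site,
      receptor_chains = c("A", "B"), ligand_chain = "L",
      c2_rotation = c2, n_res_per_subunit = n_res_per_subunit
    )
    out
  })
}

#' Generate a docked-pose ensemble with planted contact frequencies
#'
#' From a base complex ([make_dimer_complex()]), produces `n_poses` poses in
#' which each target residue is in contact in exactly `round(f * n_poses)`
#' poses (exact counts by construction, so prevalence recovery is exact; a
#' Bernoulli mode samples contacts independently instead). Non-contact
#' probes are retracted 8 Å away from the receptor; far ligand anchors get
#' small Gaussian positional jitter so poses differ in coordinates but not
#' in planted contact counts.
#'
#' @param base Complex from [make_dimer_complex()], whose planted site
#'   residues become the contact targets.
#' @param n_poses Number of poses (default 30).
#' @param target_freqs Numeric vector of target frequencies in `[0, 1]`, one
#'   per planted site residue of `base` (recycled if length 1).
#' @param jitter_sigma SD (Å) of the anchor jitter.
#' @param mode `"exact"` (default: exact counts) or `"bernoulli"`.
#' @param seed Integer seed.
#' @return An ensemble tibble (atoms with a `pose` column); attribute
#'   `truth` holds per-residue planted frequencies, realised counts and the
#'   pose index sets.
#' @export
make_pose_ensemble <- function(base, n_poses = 30, target_freqs = 1,
                               jitter_sigma = 0.05,
                               mode = c("exact", "bernoulli"), seed = 1) {
  mode <- match.arg(mode)
  truth0 <- attr(base, "truth")
  if (is.null(truth0) || nrow(truth0$site_residues) == 0) {
    abort("base complex has no planted site residues.",
          class = "iface_generation_error")
  }
  site <- truth0$site_residues
  target_freqs <- rep_len(target_freqs, nrow(site))
  if (any(target_freqs < 0 | target_freqs > 1)) {
    abort("target frequencies must lie in [0, 1].", class = "iface_generation_error")
  }
  rec <- base[base$chain != truth0$ligand_chain, , drop = FALSE]
  lig <- base[base$chain == truth0$ligand_chain, , drop = FALSE]
  withr::with_seed(seed, {
    contact_poses <- vector("list", nrow(site))
    for (r in seq_len(nrow(site))) {
      contact_poses[[r]] <- if (mode == "exact") {
        n_on <- round(target_freqs[r] * n_poses)
        sort(sample.int(n_poses, n_on))
      } else {
        which(runif(n_poses) < target_freqs[r])
      }
    }
    rec_ca <- rec[rec$atom == "CA", , drop = FALSE]
    site_ca <- coord_matrix(rec_ca[match(paste(site$chain, site$resno),
                                         paste(rec_ca$chain, rec_ca$resno)), ])
    poses <- vector("list", n_poses)
    for (k in seq_len(n_poses)) {
      lg <- lig
      for (j in seq_len(nrow(lg))) {
        if (j <= nrow(site)) {
          on <- k %in% contact_poses[[j]]
          dz <- if (on) 2.4 + 0.25 * runif(1) else 8 + abs(rnorm(1, 0, 0.5))
          lg$x[j] <- site_ca[j, 1]
          lg$y[j] <- site_ca[j, 2]
          lg$z[j] <- site_ca[j, 3] + dz
        } else {
          lg$x[j] <- lg$x[j] + rnorm(1, 0, jitter_sigma)
          lg$y[j] <- lg$y[j] + rnorm(1, 0, jitter_sigma)
          lg$z[j] <- lg$z[j] + rnorm(1, 0, jitter_sigma)
        }
      }
      pk <- bind_rows(rec, lg)
      pk$pose <- k
      poses[[k]] <- pk
    }
    out <- bind_rows(poses)
    attr(out, "truth") <- list(
      site_residues = site,
      target_freqs = target_freqs,
      realized_counts = vapply(contact_poses, length, integer(1)),
      contact_poses = contact_poses,
      n_poses = n_poses,
      receptor_chains = truth0$receptor_chains,
      ligand_chain = truth0$ligand_chain
    )
    out
  })
}

#' Generate a trajectory with planted per-residue fluctuation amplitudes
#'
#' Frames are the topology coordinates plus iid isotropic Gaussian
#' displacements with a per-residue standard deviation `sigma` (per axis),
#' so the expected RMSF of residue i is `sigma_i * sqrt(3)`. An optional
#' global rigid drift (growing rotation + translation) exercises the
#' alignment step without changing internal fluctuations.
#'
#' @param topology Structure tibble.
#' @param sigma Per-axis displacement SD in Å: scalar, or vector named by
#'   `chain|resno|icode` residue keys (unnamed vectors are matched to the
#'   topology residue order).
#' @param n_frames Number of frames.
#' @param dt Frame spacing, ps (default 2).
#' @param drift Apply a global rigid drift across frames (default FALSE).
#' @param seed Integer seed.
#' @return An `iface_trajectory`; attribute `truth` holds the per-residue
#'   sigma and the expected RMSF (`sigma * sqrt(3)`).
#' @export
make_trajectory <- function(topology, sigma = 0.3, n_frames = 100, dt = 2,
                            drift = FALSE, seed = 1) {
  stopifnot_structure(topology)
  res_keys <- unique(residue_key(topology$chain, topology$resno, topology$icode))
  if (length(sigma) == 1) {
    sig_res <- setNames(rep(sigma, length(res_keys)), res_keys)
  } else if (!is.null(names(sigma))) {
    if (!all(res_keys %in% names(sigma))) {
      abort("named sigma does not cover all residues.",
            class = "iface_generation_error")
    }
    sig_res <- sigma[res_keys]
  } else {
    if (length(sigma) != length(res_keys)) {
      abort("sigma length must match residue count.",
            class = "iface_generation_error")
    }
    sig_res <- setNames(sigma, res_keys)
  }
  atom_sig <- sig_res[residue_key(topology$chain, topology$resno, topology$icode)]
  base <- coord_matrix(topology)
  n_atoms <- nrow(base)
  withr::with_seed(seed, {
    coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
    for (f in seq_len(n_frames)) {
      disp <- matrix(rnorm(n_atoms * 3, 0, atom_sig), ncol = 3)
      fr <- base + disp
      if (drift) {
        th <- 0.002 * f
        R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
        fr <- fr %*% R + matrix(rep(c(0.01, 0.02, 0.005) * f, each = n_atoms), ncol = 3)
      }
      coords[f, , ] <- fr
    }
    out <- new_trajectory(topology, coords, dt)
    attr(out, "truth") <- list(sigma = sig_res,
                               expected_rmsf = sig_res * sqrt(3),
                               drift = drift)
    out
  })
}

#' Generate an MSA with planted clade-specific columns
#'
#' Background columns carry a per-column consensus residue; out-clade rows
#' receive substitution noise, but one designated out-clade "keeper" row per
#' column always retains the consensus and is never gapped, so background
#' noise can never fabricate clade specificity. Planted specific columns
#' give all in-clade rows one residue that no out-clade row carries. Gaps
#' are sampled only at background columns.
#'
#' @param n_rows Total rows.
#' @param clade_size Number of in-clade rows (the first `clade_size` ids).
#' @param n_cols Alignment columns.
#' @param specific_columns Integer positions of planted clade-specific
#'   columns.
#' @param gap_rate Per-cell gap probability at background columns.
#' @param sub_rate Per-cell substitution probability for non-keeper
#'   out-clade rows.
#' @param seed Integer seed.
#' @return An MSA tibble (`id`, `clade`, `seq`) as from [read_msa()];
#'   attribute `truth` lists the planted columns and their in-clade
#'   residues.
#' @export
make_msa <- function(n_rows = 12, clade_size = 3, n_cols = 60,
                     specific_columns = integer(0), gap_rate = 0.02,
                     sub_rate = 0.1, seed = 1) {
  if (clade_size < 1 || clade_size >= n_rows) {
    abort("clade must be a non-empty proper subset of rows.",
          class = "iface_generation_error")
  }
  if (any(specific_columns < 1 | specific_columns > n_cols)) {
    abort("specific columns outside the alignment.",
          class = "iface_generation_error")
  }
  aa <- aa_alphabet
  ids <- sprintf("seq%02d", seq_len(n_rows))
  in_clade <- seq_len(clade_size)
  out_rows <- setdiff(seq_len(n_rows), in_clade)
  withr::with_seed(seed, {
    m <- matrix("", n_rows, n_cols)
    planted <- character(0)
    for (col in seq_len(n_cols)) {
      cons <- sample(aa, 1)
      if (col %in% specific_columns) {
        s <- sample(setdiff(aa, cons), 1)
        m[in_clade, col] <- s
        m[out_rows, col] <- cons
        # extra out-clade variation that never equals the clade residue
        vary <- out_rows[runif(length(out_rows)) < sub_rate]
        m[vary, col] <- vapply(vary, function(r) sample(setdiff(aa, s), 1), "")
        planted[as.character(col)] <- s
      } else {
        m[, col] <- cons
        keeper <- out_rows[1]
        vary <- setdiff(out_rows, keeper)
        vary <- vary[runif(length(vary)) < sub_rate]
        m[vary, col] <- vapply(vary, function(r) sample(setdiff(aa, cons), 1), "")
        gap <- setdiff(seq_len(n_rows), keeper)
        gap <- gap[runif(length(gap)) < gap_rate]
        m[gap, col] <- "-"
      }
    }
    out <- tibble(id = ids,
                  clade = ifelse(seq_len(n_rows) %in% in_clade, "in", "out"),
                  seq = apply(m, 1, paste, collapse = ""))
    attr(out, "width") <- n_cols
    attr(out, "truth") <- list(
      specific_columns = sort(specific_columns),
      in_clade_residues = planted[as.character(sort(specific_columns))],
      clade_ids = ids[in_clade]
    )
    out
  })
}

#' Generate a titration curve from an exact forward model
#'
#' @param model `"single_site"` (ligand depletion), `"hill"` or
#'   `"displacement"` (competitive equilibrium).
#' @param params Named list of model parameters:
#'   single_site `KD`, `L`, `f_min`, `f_max`;
#'   hill `K_half`, `n`, `f_min`, `f_max`;
#'   displacement `probe_kd`, `kd_comp`, `P`, `L`, `top`, `bottom`.
#' @param x_grid Titrant concentrations, μM (strictly increasing).
#' @param noise_sigma SD of iid Gaussian noise added to the signal (same
#'   units as the signal; 0 = noiseless).
#' @param seed Integer seed.
#' @return An [titration_curve()]; attribute `truth` carries the model and
#'   parameters.
#' @export
make_titration <- function(model = c("single_site", "hill", "displacement"),
                           params = list(), x_grid, noise_sigma = 0, seed = 1) {
  model <- match.arg(model)
  p <- params
  y0 <- switch(model,
    single_site = single_site_signal(x_grid, p$KD,
                                     p$f_min %||% 0, p$f_max %||% 1, L = p$L),
    hill = hill_signal(x_grid, p$K_half, p$n, p$f_min %||% 0, p$f_max %||% 1),
    displacement = {
      pl <- bound_probe_competitive(x_grid, P = p$P, L = p$L,
                                    kd_probe = p$probe_kd, kd_comp = p$kd_comp)
      pl0 <- bound_probe_competitive(0, P = p$P, L = p$L,
                                     kd_probe = p$probe_kd, kd_comp = p$kd_comp)
      (p$bottom %||% 0) + ((p$top %||% 1) - (p$bottom %||% 0)) * pl / pl0
    }
  )
  withr::with_seed(seed, {
    y <- y0 + rnorm(length(x_grid), 0, noise_sigma)
    out <- titration_curve(x_grid, y,
                           probe_conc = p$L %||% 1,
                           protein_conc = p$P %||% NA_real_)
    attr(out, "truth") <- list(model = model, params = p,
                               noise_sigma = noise_sigma, signal_clean = y0)
    out
  })
}

#' Generate a synthetic docking funnel (or its shuffled null)
#'
#' Scores follow `score = irmsd + N(0, noise)` over an iRMSD cloud, the
#' pattern of a docking funnel (good poses both score well and sit close to
#' the reference). With `shuffle = TRUE` the scores are permuted, destroying
#' the score-geometry association while keeping both margins — the null
#' against which funnel detection is tested.
#'
#' @param n Number of points (default 200).
#' @param noise SD of the score noise (default 1).
#' @param shuffle Permute scores (default FALSE).
#' @param seed Integer seed.
#' @return Tibble with columns `score` and `irmsd`; attribute `truth`
#'   records whether a funnel was planted.
#' @export
make_funnel_points <- function(n = 200, noise = 1, shuffle = FALSE, seed = 1) {
  withr::with_seed(seed, {
    irmsd <- runif(n, 0.5, 12)
    score <- irmsd + rnorm(n, 0, noise)
    if (shuffle) score <- sample(score)
    out <- tibble(score = score, irmsd = irmsd)
    attr(out, "truth") <- list(funnel = !shuffle, noise = noise)
    out
  })
}
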