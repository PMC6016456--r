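#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired point sets. The reflection branch is excluded by the usual sign
#' correction on the smallest singular value, so the returned rotation always
#' has determinant +1.
#'
#' @param mobile,reference Numeric matrices `n x 3` (Å), `n >= 3`, row i of
#'   `mobile` paired with row i of `reference`.
#' @return A list of class `iface_superposition`: `rotation` (3x3, acts on
#'   row vectors), `translation` (length-3), `rmsd` (Å). Apply with
#'   [apply_superposition()]: `mobile %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    abort(sprintf("point counts differ: %d vs %d.", nrow(mobile), nrow(reference)),
          class = "iface_congruence_error")
  }
  if (nrow(mobile) < 3) {
    abort("need >= 3 points for a unique superposition.", class = "iface_rank_error")
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  S <- crossprod(A, B)            # 3x3 cross-covariance
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  resid <- A %*% R - B
  res <- list(rotation = R,
              translation = as.numeric(cr - cm %*% R),
              rmsd = sqrt(mean(rowSums(resid^2))))
  class(res) <- "iface_superposition"
  res
}

#' Apply a superposition to a coordinate matrix
#' @param coords Numeric matrix `n x 3`.
#' @param sp An `iface_superposition`.
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, `+`)
}

#' @export
print.iface_superposition <- function(x, ...) {
  cat(sprintf("<iface_superposition> rmsd = %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

# Superpose a whole structure using a fit computed on a subset of its atoms.
superpose_structure <- function(pose, reference, fit_atoms = "CA",
                                fit_chains = NULL) {
  sel_p <- select_atoms(pose, fit_atoms)
  sel_r <- select_atoms(reference, fit_atoms)
  if (!is.null(fit_chains)) {
    sel_p <- sel_p[sel_p$chain %in% fit_chains, , drop = FALSE]
    sel_r <- sel_r[sel_r$chain %in% fit_chains, , drop = FALSE]
  }
  kp <- paste(sel_p$chain, sel_p$resno, sel_p$icode, sel_p$atom)
  kr <- paste(sel_r$chain, sel_r$resno, sel_r$icode, sel_r$atom)
  common <- intersect(kp, kr)
  if (length(common) < 3) {
    abort("fewer than 3 shared fit atoms between pose and reference.",
          class = "iface_congruence_error")
  }
  sp <- kabsch_superpose(coord_matrix(sel_p[match(common, kp), ]),
                         coord_matrix(sel_r[match(common, kr), ]))
  set_coords(pose, apply_superposition(coord_matrix(pose), sp))
}

#' Average complex of a pose ensemble
#'
#' Superposes every pose onto the first pose's receptor C-alpha atoms and
#' returns (i) the per-atom coordinate mean as the reference ("average")
#' complex and (ii) the medoid pose — the pose with minimum mean all-atom
#' RMSD to the other superposed poses — as a robust fallback, since a
#' coordinate-mean structure can be stereochemically unphysical.
#'
#' @inheritParams prevalence_profile
#' @param receptor_chains Chain ids defining the superposition frame.
#' @return A list with `reference` (structure tibble, mean coordinates),
#'   `medoid` (pose index) and `aligned` (list of superposed pose tibbles).
#' @export
average_complex <- function(ensemble, receptor_chains) {
  poses <- as_pose_list(ensemble)
  if (length(poses) < 2) abort("need >= 2 poses.", class = "iface_input_error")
  n_atoms <- nrow(poses[[1]])
  for (k in seq_along(poses)[-1]) {
    if (nrow(poses[[k]]) != n_atoms) {
      abort(sprintf("pose %d has %d atoms; pose 1 has %d.",
                    k, nrow(poses[[k]]), n_atoms),
            class = "iface_congruence_error")
    }
  }
  aligned <- vector("list", length(poses))
  aligned[[1]] <- poses[[1]]
  for (k in seq_along(poses)[-1]) {
    aligned[[k]] <- superpose_structure(poses[[k]], poses[[1]],
                                        fit_atoms = "CA",
                                        fit_chains = receptor_chains)
  }
  stack <- array(NA_real_, dim = c(length(poses), n_atoms, 3))
  for (k in seq_along(aligned)) stack[k, , ] <- coord_matrix(aligned[[k]])
  ref <- set_coords(poses[[1]], apply(stack, c(2, 3), mean))
  # medoid over plain coordinate RMSD in the common frame
  np <- length(poses)
  pd <- matrix(0, np, np)
  for (i in seq_len(np - 1)) for (j in seq(i + 1, np)) {
    d <- sqrt(mean(rowSums((stack[i, , ] - stack[j, , ])^2)))
    if (d < 1e-9) d <- 0   # ties resolve to the lowest pose index
    pd[i, j] <- d; pd[j, i] <- d
  }
  medoid <- which.min(rowSums(pd) / (np - 1))
  list(reference = ref, medoid = medoid, aligned = aligned)
}

#' Interface RMSD of a pose against a reference complex
#'
#' The interface is defined once, on the reference: every residue with a
#' heavy atom within `interface_cutoff` (default 10 Å) of the partner
#' protein. The pose is superposed onto the reference on receptor C-alpha
#' atoms, and the iRMSD is the C-alpha RMSD over the union of receptor- and
#' ligand-side interface residues, without re-fitting on the interface set.
#'
#' @param pose,reference Structure tibbles sharing a residue key space.
#' @param receptor_chains,ligand_chains Chain partition of the complex.
#' @param interface_cutoff Heavy-atom distance (Å) defining interface
#'   residues on the reference.
#' @return iRMSD in Å (single numeric). The interface residue keys are
#'   attached as attribute `interface`.
#' @export
interface_rmsd <- function(pose, reference, receptor_chains, ligand_chains,
                           interface_cutoff = 10.0) {
  cs <- residue_contacts(reference, receptor_chains, ligand_chains,
                         cutoff = interface_cutoff)
  if (nrow(cs) == 0) {
    abort("empty interface set at this cutoff; increase interface_cutoff.",
          class = "iface_definition_error")
  }
  iface <- bind_rows(
    distinct(cs, chain = .data$rec_chain, resno = .data$rec_resno,
             icode = .data$rec_icode),
    distinct(cs, chain = .data$lig_chain, resno = .data$lig_resno,
             icode = .data$lig_icode)
  ) |> distinct()
  fitted <- superpose_structure(pose, reference, fit_atoms = "CA",
                                fit_chains = receptor_chains)
  ca_p <- select_atoms(fitted, "CA")
  ca_r <- select_atoms(reference, "CA")
  keys_iface <- residue_key(iface$chain, iface$resno, iface$icode)
  kp <- residue_key(ca_p$chain, ca_p$resno, ca_p$icode)
  kr <- residue_key(ca_r$chain, ca_r$resno, ca_r$icode)
  use <- intersect(keys_iface, intersect(kp, kr))
  if (length(use) == 0) {
    abort("no interface C-alpha atoms shared between pose and reference.",
          class = "iface_congruence_error")
  }
  dp <- coord_matrix(ca_p[match(use, kp), ])
  dr <- coord_matrix(ca_r[match(use, kr), ])
  out <- sqrt(mean(rowSums((dp - dr)^2)))
  attr(out, "interface") <- use
  out
}

#' Funnel analysis of docking score versus interface RMSD
#'
#' Summarises whether a cloud of (score, iRMSD) points shows a docking
#' funnel: better (lower) scores coinciding with smaller deviations from the
#' reference complex. A funnel is declared when the Spearman rank correlation
#' between score and iRMSD is at least `rho_min` AND the median iRMSD of the
#' best-scoring `low_fraction` of poses is below the global median iRMSD.
#' Both thresholds are reported, never silently applied.
#'
#' @param points Data frame with numeric columns `score` (lower is better)
#'   and `irmsd` (Å); at least 20 rows.
#' @param low_fraction Fraction of best-scoring poses for the low-score
#'   median (default 0.1).
#' @param rho_min Rank-correlation threshold for the funnel call
#'   (default 0.4).
#' @return A one-row tibble of class `iface_funnel`: `rho`,
#'   `low_score_median_irmsd`, `global_median_irmsd`, `is_funnel`, `n`,
#'   `low_fraction`, `rho_min`.
#' @export
funnel_analysis <- function(points, low_fraction = 0.1, rho_min = 0.4) {
  if (!all(c("score", "irmsd") %in% names(points))) {
    abort("points needs columns `score` and `irmsd`.", class = "iface_input_error")
  }
  n <- nrow(points)
  if (n < 20) {
    abort(sprintf("need >= 20 points (got %d).", n), class = "iface_sample_size_error")
  }
  if (diff(range(points$score)) == 0) {
    abort("scores are constant; rank correlation undefined.",
          class = "iface_degenerate_error")
  }
  rho <- cor(points$score, points$irmsd, method = "spearman")
  n_low <- max(1L, round(n * low_fraction))
  best <- points[order(points$score), , drop = FALSE][seq_len(n_low), ]
  low_med <- median(best$irmsd)
  glob_med <- median(points$irmsd)
  out <- tibble(rho = rho,
                low_score_median_irmsd = low_med,
                global_median_irmsd = glob_med,
                is_funnel = rho >= rho_min && low_med < glob_med,
                n = n, low_fraction = low_fraction, rho_min = rho_min)
  class(out) <- c("iface_funnel", class(out))
  out
}

rownames_safe <- function(s) {
  paste(s$chain, s$resno, s$icode, s$atom, sep = "|")
}

#' RMSD trace of a trajectory against a reference structure
#'
#' Each frame is rigid-body superposed onto the reference on the selected
#' atoms; the per-frame RMSD over those atoms is reported against simulation
#' time (frame index x `dt`, first frame at 0 ps).
#'
#' @param t An `iface_trajectory`.
#' @param reference Reference structure tibble (default: the trajectory
#'   topology).
#' @param selection Atom selection for both fit and measurement: `"CA"`
#'   (default), `"heavy"` or `"all"`.
#' @return A tibble with columns `frame` (1-based), `time_ps` and `rmsd` (Å).
#' @export
rmsd_trace <- function(t, reference = NULL, selection = "CA") {
  reference <- reference %||% t$topology
  idx <- match(rownames_safe(select_atoms(t$topology, selection)),
               rownames_safe(t$topology))
  ref_sel <- select_atoms(reference, selection)
  kr <- rownames_safe(ref_sel)
  kt <- rownames_safe(t$topology)[idx]
  if (!setequal(kr, kt)) {
    abort("reference selection does not match the trajectory selection.",
          class = "iface_congruence_error")
  }
  ref_m <- coord_matrix(ref_sel[match(kt, kr), ])
  nf <- n_frames(t)
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    sp <- kabsch_superpose(t$coords[f, idx, , drop = TRUE], ref_m)
    rmsd[f] <- sp$rmsd
  }
  tibble(frame = seq_len(nf), time_ps = (seq_len(nf) - 1) * t$dt, rmsd = rmsd)
}

#' Earliest equilibration time of an RMSD trace
#'
#' Finds the earliest time from which the trace stays flat: the smallest
#' start index such that EVERY subsequent sliding window of `window` frames
#' has a max-min range at or below `band`.
#'
#' @param trace Tibble from [rmsd_trace()] (columns `time_ps`, `rmsd`), or a
#'   numeric RMSD vector with `dt` supplied.
#' @param window Sliding window width in frames (default 10).
#' @param band Allowed within-window range in Å (default 0.5).
#' @param dt Frame spacing (ps) when `trace` is a bare numeric vector.
#' @return One-row tibble: `reached` (logical), `time_ps` (NA when never
#'   flat), `frame` (1-based start frame).
#' @export
equilibration_time <- function(trace, window = 10, band = 0.5, dt = NULL) {
  if (is.data.frame(trace)) {
    y <- trace$rmsd
    times <- trace$time_ps
  } else {
    y <- as.numeric(trace)
    if (is.null(dt)) abort("supply dt for a bare numeric trace.",
                           class = "iface_input_error")
    times <- (seq_along(y) - 1) * dt
  }
  n <- length(y)
  if (window > n) {
    abort(sprintf("window (%d) exceeds trace length (%d).", window, n),
          class = "iface_parameter_error")
  }
  starts <- seq_len(n - window + 1)
  rng <- vapply(starts, function(j) {
    w <- y[j:(j + window - 1)]
    max(w) - min(w)
  }, numeric(1))
  ok <- rng <= band
  all_after <- rev(cumprod(rev(ok))) > 0
  if (!any(all_after)) {
    return(tibble(reached = FALSE, time_ps = NA_real_, frame = NA_integer_))
  }
  j0 <- which(all_after)[1]
  tibble(reached = TRUE, time_ps = times[j0], frame = starts[j0])
}

#' Per-residue root-mean-square fluctuation of a trajectory
#'
#' Frames are aligned to the evolving mean structure by a 2-pass iterative
#' Kabsch fit (align to the topology, compute the mean, re-align to that
#' mean, recompute), then `RMSF_i = sqrt(mean_f |x_fi - xbar_i|^2)` per selected
#' atom, averaged (in the mean-square sense) per residue.
#'
#' @param t An `iface_trajectory` with >= 2 frames.
#' @param selection Atom selection (default `"CA"`).
#' @param align Align frames before measuring (default TRUE). With `FALSE`
#'   fluctuations are measured in the raw frame coordinates.
#' @return A tibble of class `iface_rmsf`: `chain`, `resno`, `icode`,
#'   `resid`, `rmsf` (Å).
#' @export
rmsf <- function(t, selection = "CA", align = TRUE) {
  nf <- n_frames(t)
  if (nf < 2) abort("RMSF undefined for a single frame.",
                    class = "iface_input_error")
  sel <- select_atoms(t$topology, selection)
  idx <- match(rownames_safe(sel), rownames_safe(t$topology))
  X <- t$coords[, idx, , drop = FALSE]
  if (align) {
    # pass 1 aligns to the topology (frame-order independent), pass 2 to the
    # resulting mean structure
    for (pass in 1:2) {
      ref <- if (pass == 1) coord_matrix(sel) else apply(X, c(2, 3), mean)
      ref <- matrix(ref, ncol = 3)
      for (f in seq_len(nf)) {
        sp <- kabsch_superpose(matrix(X[f, , ], ncol = 3), ref)
        X[f, , ] <- apply_superposition(matrix(X[f, , ], ncol = 3), sp)
      }
    }
  }
  mean_xyz <- apply(X, c(2, 3), mean)
  msf <- rowMeans(vapply(seq_len(nf), function(f) {
    rowSums((matrix(X[f, , ], ncol = 3) - mean_xyz)^2)
  }, numeric(nrow(mean_xyz))))
  per_atom <- sel |> mutate(msf = msf)
  out <- per_atom |>
    group_by(.data$chain, .data$resno, .data$icode, .data$resid) |>
    summarise(rmsf = sqrt(mean(.data$msf)), .groups = "drop") |>
    arrange(.data$chain, .data$resno, .data$icode)
  class(out) <- c("iface_rmsf", class(out))
  out
}

#' Proximal-minus-distant RMSF differences across a dimer
#'
#' For each interface residue of the proximal subunit, computes
#' `delta = RMSF(proximal copy) - RMSF(distant copy)` using a residue
#' symmetry map, and summarises how many interface positions fluctuate less
#' on the proximal side (negative delta — the signature of interface
#' rigidification by a bound partner).
#'
#' @param p An `iface_rmsf` profile covering both subunits.
#' @param symmetry_map Residue bijection from [symmetry_map_chains()]
#'   (proximal = `_a` side, distant = `_b` side).
#' @param interface_residues Tibble with columns `chain`, `resno`, `icode`
#'   (keys within the proximal subunit).
#' @return A tibble with one row per interface residue: `chain`, `resno`,
#'   `icode`, `rmsf_proximal`, `rmsf_distant`, `delta`; attributes
#'   `n_lower` and `fraction_lower` summarise `delta < 0`.
#' @export
rmsf_delta <- function(p, symmetry_map, interface_residues) {
  if (nrow(interface_residues) == 0) {
    abort("empty interface residue set.", class = "iface_input_error")
  }
  if (!"icode" %in% names(interface_residues)) interface_residues$icode <- ""
  ka <- residue_key(symmetry_map$chain_a, symmetry_map$resno_a, symmetry_map$icode_a)
  kb <- residue_key(symmetry_map$chain_b, symmetry_map$resno_b, symmetry_map$icode_b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    abort("symmetry map is not a bijection.", class = "iface_symmetry_map_error")
  }
  ki <- residue_key(interface_residues$chain, interface_residues$resno,
                    interface_residues$icode)
  pos <- match(ki, ka)
  if (anyNA(pos)) {
    abort(paste0("interface residue(s) not covered by the symmetry map: ",
                 paste(ki[is.na(pos)], collapse = ", ")),
          class = "iface_map_coverage_error")
  }
  kp <- residue_key(p$chain, p$resno, p$icode)
  prox <- p$rmsf[match(ki, kp)]
  dist <- p$rmsf[match(kb[pos], kp)]
  if (anyNA(prox) || anyNA(dist)) {
    abort("RMSF profile does not cover all mapped residues.",
          class = "iface_map_coverage_error")
  }
  out <- tibble(chain = interface_residues$chain,
                resno = interface_residues$resno,
                icode = interface_residues$icode,
                rmsf_proximal = prox, rmsf_distant = dist,
                delta = prox - dist)
  attr(out, "n_lower") <- sum(out$delta < 0)
  attr(out, "fraction_lower") <- mean(out$delta < 0)
  out
}
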