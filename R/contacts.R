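#' Residue-residue contacts across a protein-protein interface
#'
#' Finds all (receptor residue, ligand residue) pairs whose minimum
#' inter-atomic distance is at or below `cutoff` (default 3 Å, the
#' within-3-Å-of-the-other-protein criterion used for interface prevalence).
#' The search is cell-list accelerated: atoms are binned into cubic cells of
#' edge `cutoff` and only atoms in the 27 neighbouring cells are compared,
#' which is exact for a distance cutoff equal to the cell edge.
#'
#' @param s Structure tibble of one complex (receptor + ligand chains).
#' @param receptor_chains,ligand_chains Character vectors of chain ids; must
#'   be non-empty, disjoint and present in `s`.
#' @param cutoff Contact distance cutoff in Å (> 0).
#' @param atoms Atom selection: `"heavy"` (default; hydrogens excluded) or
#'   `"all"`.
#' @return A tibble with one row per contacting residue pair: `rec_chain`,
#'   `rec_resno`, `rec_icode`, `rec_resid`, `lig_chain`, `lig_resno`,
#'   `lig_icode`, `lig_resid`, `min_dist` (Å). The `cutoff` used is stored as
#'   an attribute.
#' @export
residue_contacts <- function(s, receptor_chains, ligand_chains, cutoff = 3.0,
                             atoms = c("heavy", "all")) {
  atoms <- match.arg(atoms)
  stopifnot_structure(s)
  if (cutoff <= 0) abort("cutoff must be > 0 Å.", class = "iface_input_error")
  if (length(receptor_chains) == 0 || length(ligand_chains) == 0) {
    abort("receptor and ligand chain sets must be non-empty.",
          class = "iface_partition_error")
  }
  if (length(intersect(receptor_chains, ligand_chains)) > 0) {
    abort("receptor and ligand chain sets overlap.",
          class = "iface_partition_error")
  }
  missing <- setdiff(c(receptor_chains, ligand_chains), unique(s$chain))
  if (length(missing) > 0) {
    abort(paste0("chain(s) not present in structure: ",
                 paste(missing, collapse = ", ")),
          class = "iface_lookup_error")
  }
  sel <- select_atoms(s, atoms)
  rec <- sel[sel$chain %in% receptor_chains, , drop = FALSE]
  lig <- sel[sel$chain %in% ligand_chains, , drop = FALSE]
  pairs <- cell_list_contacts(coord_matrix(rec), coord_matrix(lig), cutoff)
  if (nrow(pairs) == 0) {
    out <- tibble(rec_chain = character(), rec_resno = integer(),
                  rec_icode = character(), rec_resid = character(),
                  lig_chain = character(), lig_resno = integer(),
                  lig_icode = character(), lig_resid = character(),
                  min_dist = numeric())
    attr(out, "cutoff") <- cutoff
    return(out)
  }
  out <- tibble(
    rec_chain = rec$chain[pairs$i], rec_resno = rec$resno[pairs$i],
    rec_icode = rec$icode[pairs$i], rec_resid = rec$resid[pairs$i],
    lig_chain = lig$chain[pairs$j], lig_resno = lig$resno[pairs$j],
    lig_icode = lig$icode[pairs$j], lig_resid = lig$resid[pairs$j],
    dist = pairs$dist
  ) |>
    group_by(.data$rec_chain, .data$rec_resno, .data$rec_icode, .data$rec_resid,
             .data$lig_chain, .data$lig_resno, .data$lig_icode, .data$lig_resid) |>
    summarise(min_dist = min(.data$dist), .groups = "drop") |>
    arrange(.data$rec_chain, .data$rec_resno, .data$rec_icode,
            .data$lig_chain, .data$lig_resno, .data$lig_icode)
  attr(out, "cutoff") <- cutoff
  out
}

# Exact cell-list neighbour search between two atom sets. Returns atom index
# pairs (i into A, j into B) with distance <= cutoff.
cell_list_contacts <- function(A, B, cutoff) {
  empty <- tibble(i = integer(), j = integer(), dist = numeric())
  if (nrow(A) == 0 || nrow(B) == 0) return(empty)
  cell_of <- function(M) {
    cbind(floor(M[, 1] / cutoff), floor(M[, 2] / cutoff), floor(M[, 3] / cutoff))
  }
  ca <- cell_of(A)
  cb <- cell_of(B)
  key <- function(cm) paste(cm[, 1], cm[, 2], cm[, 3], sep = ",")
  a_tab <- tibble(i = seq_len(nrow(A)), cell = key(ca))
  # expand each B atom into its 27 neighbouring cells
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nrow(B)
  j_rep <- rep(seq_len(nb), times = 27)
  cell_rep <- cb[j_rep, , drop = FALSE] +
    offsets[rep(seq_len(27), each = nb), , drop = FALSE]
  b_tab <- tibble(j = j_rep, cell = key(cell_rep))
  cand <- inner_join(b_tab, a_tab, by = "cell", relationship = "many-to-many")
  if (nrow(cand) == 0) return(empty)
  d2 <- (A[cand$i, 1] - B[cand$j, 1])^2 +
        (A[cand$i, 2] - B[cand$j, 2])^2 +
        (A[cand$i, 3] - B[cand$j, 3])^2
  keep <- d2 <= cutoff^2
  tibble(i = cand$i[keep], j = cand$j[keep], dist = sqrt(d2[keep]))
}

#' Per-residue contact prevalence over a pose ensemble
#'
#' For every residue of the receptor (and, analogously, of the ligand) the
#' prevalence is the fraction of poses in which that residue makes at least
#' one contact with the partner protein. Contact is per pose and binary: a
#' residue touching the partner through several atoms in one pose still
#' counts once for that pose.
#'
#' @param ensemble Pose ensemble: a tibble with a `pose` column (see
#'   [read_pdb_models()], [make_pose_ensemble()]) or a list of structure
#'   tibbles. All poses must share the receptor residue key space.
#' @inheritParams residue_contacts
#' @param label Optional ensemble label stored on the result.
#' @return A tibble of class `iface_prevalence` with columns `side`
#'   (`"receptor"`/`"ligand"`), `chain`, `resno`, `icode`, `resid`, `count`
#'   (poses with >= 1 contact), `n_poses` and `freq` (`count / n_poses`).
#'   Per-pose contact membership is kept in the `pose_contacts` attribute so
#'   that [fold_dimer_symmetry()] can recompute union counts.
#' @export
prevalence_profile <- function(ensemble, receptor_chains, ligand_chains,
                               cutoff = 3.0, atoms = c("heavy", "all"),
                               label = "ensemble") {
  atoms <- match.arg(atoms)
  poses <- as_pose_list(ensemble)
  if (length(poses) < 1) abort("need >= 1 pose.", class = "iface_input_error")
  key_space <- function(s, chains) {
    r <- s |> filter(.data$chain %in% chains, !.data$hetero) |>
      distinct(.data$chain, .data$resno, .data$icode, .data$resid)
    r[order(r$chain, r$resno, r$icode), ]
  }
  rec_keys <- key_space(poses[[1]], receptor_chains)
  lig_keys <- key_space(poses[[1]], ligand_chains)
  contact_rows <- vector("list", length(poses))
  for (k in seq_along(poses)) {
    rk <- key_space(poses[[k]], receptor_chains)
    if (!identical(rk[c("chain", "resno", "icode")],
                   rec_keys[c("chain", "resno", "icode")])) {
      abort(sprintf("pose %d has a different receptor residue key space.", k),
            class = "iface_congruence_error")
    }
    cs <- residue_contacts(poses[[k]], receptor_chains, ligand_chains,
                           cutoff = cutoff, atoms = atoms)
    rec_hit <- distinct(cs, chain = .data$rec_chain, resno = .data$rec_resno,
                        icode = .data$rec_icode)
    lig_hit <- distinct(cs, chain = .data$lig_chain, resno = .data$lig_resno,
                        icode = .data$lig_icode)
    contact_rows[[k]] <- bind_rows(
      if (nrow(rec_hit)) mutate(rec_hit, side = "receptor", pose = k),
      if (nrow(lig_hit)) mutate(lig_hit, side = "ligand", pose = k)
    )
  }
  hits <- bind_rows(contact_rows)
  if (nrow(hits) == 0) {
    hits <- tibble(chain = character(), resno = integer(), icode = character(),
                   side = character(), pose = integer())
  }
  n_poses <- length(poses)
  tally_side <- function(keys, side_name) {
    h <- hits |> filter(.data$side == side_name) |>
      count(.data$chain, .data$resno, .data$icode, name = "count")
    keys |>
      left_join(h, by = c("chain", "resno", "icode")) |>
      mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
             side = side_name, n_poses = n_poses,
             freq = .data$count / n_poses)
  }
  out <- bind_rows(tally_side(rec_keys, "receptor"),
                   tally_side(lig_keys, "ligand")) |>
    select("side", "chain", "resno", "icode", "resid",
           "count", "n_poses", "freq")
  attr(out, "pose_contacts") <- hits
  attr(out, "label") <- label
  attr(out, "cutoff") <- cutoff
  class(out) <- c("iface_prevalence", class(out))
  out
}

#' Build a residue symmetry map between two homodimer subunits
#'
#' Pairs residues of two chains of one structure by order within the chain
#' (the C2-related subunits of a homodimer share numbering and length).
#'
#' @inheritParams write_pdb
#' @param chain_a,chain_b The two subunit chain ids.
#' @return A tibble with columns `chain_a`, `resno_a`, `icode_a`, `chain_b`,
#'   `resno_b`, `icode_b`; one row per residue pair.
#' @export
symmetry_map_chains <- function(s, chain_a, chain_b) {
  stopifnot_structure(s)
  res <- function(ch) {
    r <- s |> filter(.data$chain == ch, !.data$hetero) |>
      distinct(.data$resno, .data$icode)
    r[order(r$resno, r$icode), ]
  }
  ra <- res(chain_a); rb <- res(chain_b)
  if (nrow(ra) != nrow(rb)) {
    abort(sprintf("chains %s and %s differ in residue count (%d vs %d).",
                  chain_a, chain_b, nrow(ra), nrow(rb)),
          class = "iface_symmetry_map_error")
  }
  tibble(chain_a = chain_a, resno_a = ra$resno, icode_a = ra$icode,
         chain_b = chain_b, resno_b = rb$resno, icode_b = rb$icode)
}

#' Fold a prevalence profile over the C2 symmetry of a dimeric receptor
#'
#' The two equivalent binding sites of a homodimer are pooled: the folded
#' count of a residue position is the number of poses in which that residue
#' OR its symmetry mate makes a contact (union rule), and the folded
#' frequency is that count divided by the pose count. The folded profile is
#' indexed by the first subunit's numbering.
#'
#' @param p An `iface_prevalence` profile (receptor side is folded; the
#'   ligand side is dropped).
#' @param chain_map Residue bijection between the two subunits, as from
#'   [symmetry_map_chains()].
#' @return An `iface_prevalence` tibble (receptor side only, first subunit's
#'   keys).
#' @export
fold_dimer_symmetry <- function(p, chain_map) {
  if (!inherits(p, "iface_prevalence")) {
    abort("`p` must be a prevalence profile.", class = "iface_input_error")
  }
  need <- c("chain_a", "resno_a", "icode_a", "chain_b", "resno_b", "icode_b")
  if (!all(need %in% names(chain_map))) {
    abort("chain_map needs columns chain_a/resno_a/icode_a/chain_b/resno_b/icode_b.",
          class = "iface_symmetry_map_error")
  }
  ka <- residue_key(chain_map$chain_a, chain_map$resno_a, chain_map$icode_a)
  kb <- residue_key(chain_map$chain_b, chain_map$resno_b, chain_map$icode_b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    abort("chain_map is not a bijection (duplicated residue keys).",
          class = "iface_symmetry_map_error")
  }
  rec <- p |> filter(.data$side == "receptor")
  rec_keys <- residue_key(rec$chain, rec$resno, rec$icode)
  covered <- rec_keys %in% c(ka, kb)
  if (!all(covered)) {
    abort("chain_map does not cover the full receptor residue key space.",
          class = "iface_symmetry_map_error")
  }
  hits <- attr(p, "pose_contacts")
  if (is.null(hits)) {
    abort("profile lacks per-pose contact records; recompute with prevalence_profile().",
          class = "iface_input_error")
  }
  hits <- hits |> filter(.data$side == "receptor")
  hit_keys <- residue_key(hits$chain, hits$resno, hits$icode)
  n_poses <- rec$n_poses[1] %||% 0L
  base <- rec[match(ka, rec_keys), c("chain", "resno", "icode", "resid")]
  counts <- integer(length(ka))
  for (i in seq_along(ka)) {
    sel <- hit_keys == ka[i] | hit_keys == kb[i]
    counts[i] <- length(unique(hits$pose[sel]))
  }
  out <- base |>
    mutate(side = "receptor", count = counts, n_poses = n_poses,
           freq = counts / n_poses) |>
    select("side", "chain", "resno", "icode", "resid",
           "count", "n_poses", "freq")
  folded_hits <- hits
  mate <- match(hit_keys, kb)
  swap <- !is.na(mate)
  folded_hits$chain[swap] <- chain_map$chain_a[mate[swap]]
  folded_hits$resno[swap] <- chain_map$resno_a[mate[swap]]
  folded_hits$icode[swap] <- chain_map$icode_a[mate[swap]]
  attr(out, "pose_contacts") <- distinct(folded_hits)
  attr(out, "label") <- attr(p, "label")
  attr(out, "cutoff") <- attr(p, "cutoff")
  attr(out, "folded") <- TRUE
  class(out) <- c("iface_prevalence", class(out))
  out
}

#' Average prevalence profiles across ensembles
#'
#' Unweighted per-residue mean and sample SD of the contact frequency across
#' two or more ensembles (equal weight per ensemble regardless of pose
#' count, matching the convention of averaging several independent docking
#' sets of equal standing).
#'
#' @param ps List of >= 2 `iface_prevalence` profiles with identical residue
#'   key spaces (fold first if comparing folded profiles).
#' @return A tibble of class `iface_averaged` with columns `side`, `chain`,
#'   `resno`, `icode`, `resid`, `mean`, `sd` and `n_ensembles`.
#' @export
average_profiles <- function(ps) {
  if (!is.list(ps) || length(ps) < 2) {
    abort("need a list of >= 2 prevalence profiles.", class = "iface_input_error")
  }
  key_of <- function(p) paste(p$side, residue_key(p$chain, p$resno, p$icode))
  k0 <- key_of(ps[[1]])
  for (i in seq_along(ps)[-1]) {
    if (!identical(sort(key_of(ps[[i]])), sort(k0))) {
      abort(sprintf("profile %d has a different residue key space.", i),
            class = "iface_congruence_error")
    }
  }
  freq_mat <- vapply(ps, function(p) p$freq[match(k0, key_of(p))],
                     numeric(length(k0)))
  base <- ps[[1]][, c("side", "chain", "resno", "icode", "resid")]
  out <- base |>
    mutate(mean = rowMeans(freq_mat),
           sd = apply(freq_mat, 1, sd),
           n_ensembles = length(ps))
  class(out) <- c("iface_averaged", class(out))
  out
}

#' Domain localization of the most frequent interface residues
#'
#' Takes the `top_k` residues by mean contact frequency (ties broken by lower
#' residue number, then chain) and reports how they distribute over a named
#' domain partition. The localization index is the largest single-domain
#' fraction; the profile is flagged "localized" when the index reaches
#' `threshold` (interface residues cluster in one domain rather than being
#' scattered over the protein).
#'
#' @param a An `iface_averaged` profile (or a prevalence profile; its `freq`
#'   is then used). Only the receptor side is considered if a `side` column
#'   is present.
#' @param partition Tibble with columns `domain`, `chain`, `start`, `end`
#'   (inclusive author residue numbers); intervals must not overlap within a
#'   chain. Residues outside all intervals fall into `"unassigned"`.
#' @param top_k Number of top residues to localize (default 20).
#' @param threshold Localization index needed to flag "localized"
#'   (default 0.8).
#' @return A tibble of class `iface_localization` with one row per domain
#'   (`domain`, `n_top`, `fraction`), plus attributes `localization_index`,
#'   `localized` and `top_residues`.
#' @export
domain_localization <- function(a, partition, top_k = 20, threshold = 0.8) {
  score_col <- if ("mean" %in% names(a)) "mean" else "freq"
  df <- as_tibble(a)
  if ("side" %in% names(df)) df <- df[df$side == "receptor", , drop = FALSE]
  if (nrow(df) == 0) abort("empty profile.", class = "iface_input_error")
  if (top_k > nrow(df)) {
    abort(sprintf("top_k = %d exceeds the %d profiled residues.", top_k, nrow(df)),
          class = "iface_input_error")
  }
  ov <- partition |> arrange(.data$chain, .data$start) |> group_by(.data$chain) |>
    summarise(bad = any(.data$start[-1] <= cummax(.data$end)[-n()]),
              .groups = "drop")
  if (any(ov$bad, na.rm = TRUE)) {
    abort("domain intervals overlap within a chain.", class = "iface_input_error")
  }
  df <- df[order(-df[[score_col]], df$resno, df$chain), , drop = FALSE]
  top <- df[seq_len(top_k), , drop = FALSE]
  assign_domain <- function(chain, resno) {
    hit <- partition$domain[partition$chain == chain &
                            partition$start <= resno & partition$end >= resno]
    if (length(hit) == 0) "unassigned" else hit[1]
  }
  top$domain <- mapply(assign_domain, top$chain, top$resno)
  shares <- top |> count(.data$domain, name = "n_top") |>
    mutate(fraction = .data$n_top / top_k) |>
    arrange(dplyr::desc(.data$fraction))
  idx <- max(shares$fraction)
  out <- shares
  attr(out, "localization_index") <- idx
  attr(out, "localized") <- idx >= threshold
  attr(out, "top_residues") <- top
  class(out) <- c("iface_localization", class(out))
  out
}

#' @export
print.iface_localization <- function(x, ...) {
  NextMethod()
  cat(sprintf("localization index: %.3f (%s)\n",
              attr(x, "localization_index"),
              if (attr(x, "localized")) "localized" else "not localized"))
  invisible(x)
}

#' Fraction of poses with a composite (two-subunit) binding site
#'
#' A pose is composite when at least `min_per_subunit` contacting receptor
#' residues come from EACH of the two subunit chains — i.e. the ligand sits
#' on a binding site built jointly by both copies of the dimer.
#'
#' @inheritParams prevalence_profile
#' @param receptor_chains Exactly two subunit chain ids.
#' @param min_per_subunit Minimum contacting residues per subunit (default 3).
#' @return A tibble with one row per pose: `pose`, `n_subunit_1`,
#'   `n_subunit_2`, `composite` (logical). The composite-pose fraction is in
#'   the `fraction` attribute (also `mean(out$composite)`).
#' @export
composite_site_fraction <- function(ensemble, receptor_chains, ligand_chains,
                                    cutoff = 3.0, min_per_subunit = 3) {
  if (length(receptor_chains) != 2) {
    abort("composite-site analysis needs exactly 2 receptor subunit chains.",
          class = "iface_partition_error")
  }
  poses <- as_pose_list(ensemble)
  rows <- vector("list", length(poses))
  for (k in seq_along(poses)) {
    cs <- residue_contacts(poses[[k]], receptor_chains, ligand_chains,
                           cutoff = cutoff)
    per_chain <- cs |> distinct(.data$rec_chain, .data$rec_resno, .data$rec_icode) |>
      count(.data$rec_chain)
    n1 <- per_chain$n[match(receptor_chains[1], per_chain$rec_chain)] %||% NA
    n2 <- per_chain$n[match(receptor_chains[2], per_chain$rec_chain)] %||% NA
    n1 <- ifelse(is.na(n1), 0L, n1); n2 <- ifelse(is.na(n2), 0L, n2)
    rows[[k]] <- tibble(pose = k, n_subunit_1 = n1, n_subunit_2 = n2,
                        composite = n1 >= min_per_subunit & n2 >= min_per_subunit)
  }
  out <- bind_rows(rows)
  attr(out, "fraction") <- mean(out$composite)
  out
}
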