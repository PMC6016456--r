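#' Read a PDB file into an atom table
#'
#' Parses `ATOM`/`HETATM` records (via [bio3d::read.pdb()]) into a tidy
#' one-row-per-atom tibble, the structure representation used throughout the
#' package. Alternate-location duplicates are resolved to a single atom per
#' (chain, residue number, insertion code, atom name).
#'
#' @param path Path to a PDB file.
#' @param altloc Altloc resolution policy: `"highest-occupancy"` keeps the
#'   conformer with the largest occupancy (ties broken alphabetically by
#'   altloc identifier), `"keep-first"` keeps the first record encountered.
#' @param model For multi-model files, which `MODEL` block to return
#'   (default 1). Use [read_pdb_models()] to get all models.
#'
#' @return A tibble with columns `chain`, `resno`, `icode`, `resid` (3-letter
#'   residue name), `atom` (atom name), `element`, `x`, `y`, `z` (Å),
#'   `occupancy`, `altloc` and `hetero` (logical, `HETATM` origin). Hydrogens
#'   are retained; downstream selections default to heavy atoms.
#' @seealso [write_pdb()], [chain_sequence()], [read_trajectory()]
#' @export
read_pdb <- function(path, altloc = c("highest-occupancy", "keep-first"),
                     model = 1L) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "iface_input_error")
  }
  validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE))
  n_models <- nrow(pdb$xyz)
  if (model > n_models) {
    abort(sprintf("requested model %d but file has %d model(s).", model, n_models),
          class = "iface_input_error")
  }
  s <- bio3d_to_structure(pdb, model = model,
                          id = tools::file_path_sans_ext(basename(path)),
                          source = path)
  resolve_altloc(s, policy = altloc)
}

#' Read every MODEL of a multi-model PDB as a pose ensemble
#'
#' `MODEL`-delimited blocks are exploded, in file order, into separate
#' structures sharing one topology and stacked into an ensemble tibble with a
#' `pose` column (the representation consumed by [prevalence_profile()] and
#' friends).
#'
#' @inheritParams read_pdb
#' @return A tibble of atoms with an integer `pose` column (1-based, file
#'   order).
#' @export
read_pdb_models <- function(path, altloc = c("highest-occupancy", "keep-first")) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "iface_input_error")
  }
  validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE))
  n_models <- nrow(pdb$xyz)
  poses <- lapply(seq_len(n_models), function(m) {
    s <- bio3d_to_structure(pdb, model = m,
                            id = sprintf("model_%d", m), source = path)
    s <- resolve_altloc(s, policy = altloc)
    s$pose <- m
    s
  })
  bind_rows(poses)
}

# Pre-scan raw lines so malformed coordinate fields are reported with their
# line number (bio3d would coerce them to NA silently).
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) {
    abort(paste0("no ATOM/HETATM records in ", path),
          class = "iface_empty_structure_error")
  }
  idx <- which(is_atom)
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    vals <- substr(lines[idx], fld[1], fld[2])
    bad <- is.na(suppressWarnings(as.numeric(vals)))
    if (any(bad)) {
      abort(sprintf("non-numeric coordinate field on line %d of %s",
                    idx[which(bad)[1]], path),
            class = "iface_parse_error")
    }
  }
  invisible(TRUE)
}

bio3d_to_structure <- function(pdb, model = 1L, id = "structure",
                               source = "file") {
  at <- pdb$atom
  xyz <- pdb$xyz[model, ]
  m <- matrix(xyz, ncol = 3, byrow = TRUE)
  df <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    atom = as.character(at$elety),
    element = ifelse(is.na(at$elesy), "", as.character(at$elesy)),
    x = m[, 1], y = m[, 2], z = m[, 3],
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    hetero = at$type == "HETATM"
  )
  df$chain[is.na(df$chain)] <- " "
  new_structure(df, id = id, source = source)
}

resolve_altloc <- function(s, policy = "highest-occupancy") {
  if (all(s$altloc == "")) return(s)
  key <- paste(s$chain, s$resno, s$icode, s$atom, sep = "|")
  ord <- if (policy == "highest-occupancy") {
    order(key, -s$occupancy, s$altloc)
  } else {
    order(key, seq_len(nrow(s)))
  }
  s2 <- s[ord, , drop = FALSE]
  s2 <- s2[!duplicated(paste(s2$chain, s2$resno, s2$icode, s2$atom, sep = "|")), ,
           drop = FALSE]
  # restore file order
  s2[order(match(paste(s2$chain, s2$resno, s2$icode, s2$atom, sep = "|"),
                 unique(key))), , drop = FALSE]
}

#' Write an atom table as a fixed-column PDB file
#'
#' Emits standard `ATOM`/`HETATM` records (coordinates to 3 decimals), a `TER`
#' record after each chain and a final `END`.
#'
#' @param s Structure tibble as produced by [read_pdb()] or the synthetic
#'   generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot_structure(s)
  if (nrow(s) == 0) {
    abort("cannot write an empty structure.", class = "iface_empty_structure_error")
  }
  if (any(nchar(trimws(s$chain)) > 1)) {
    abort("PDB chain identifiers must be a single character.",
          class = "iface_format_error")
  }
  xyz <- as.vector(t(coord_matrix(s)))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(s$hetero, "HETATM", "ATOM"),
    resno = s$resno, resid = s$resid,
    eleno = seq_len(nrow(s)), elety = s$atom,
    chain = s$chain,
    insert = ifelse(s$icode == "", NA, s$icode),
    alt = ifelse(s$altloc == "", NA, s$altloc),
    o = s$occupancy, b = rep(0, nrow(s)),
    elesy = s$element, end = TRUE
  )
  insert_ter_records(path)
  invisible(path)
}

# bio3d::write.pdb (vector interface) does not emit TER between chains; add
# one after the last record of every chain.
insert_ter_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) return(invisible(path))
  chains <- substr(lines, 22, 22)
  chains[!is_atom] <- NA
  idx <- which(is_atom)
  last_of_chain <- idx[c(chains[idx][-1] != chains[idx][-length(idx)], TRUE)]
  out <- character(0)
  prev <- 1
  for (i in last_of_chain) {
    out <- c(out, lines[prev:i], "TER")
    prev <- i + 1
  }
  if (prev <= length(lines)) out <- c(out, lines[prev:length(lines)])
  writeLines(out, path)
  invisible(path)
}

#' One-letter amino-acid sequence of a chain
#'
#' Maps the 3-letter residue names of the non-hetero residues of one chain to
#' one-letter code, in file order. Unknown residue names become `"X"`;
#' `HETATM`-only residues (ligands, waters) are skipped entirely.
#'
#' @inheritParams write_pdb
#' @param chain_id Single chain identifier.
#' @return A single string.
#' @export
chain_sequence <- function(s, chain_id) {
  stopifnot_structure(s)
  if (!chain_id %in% s$chain) {
    abort(paste0("chain not present: ", chain_id), class = "iface_lookup_error")
  }
  res <- s |>
    filter(.data$chain == chain_id, !.data$hetero) |>
    distinct(.data$resno, .data$icode, .data$resid)
  if (nrow(res) == 0) return("")
  one <- suppressWarnings(bio3d::aa321(res$resid))
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Build a trajectory from ordered PDB frames
#'
#' Reads an ordered set of PDB files (one frame each), or a single multi-model
#' PDB, into a trajectory object: a fixed topology plus an ordered coordinate
#' stack with a frame spacing `dt` in picoseconds.
#'
#' @param paths Character vector of PDB file paths in frame order; a single
#'   path may contain multiple `MODEL` blocks.
#' @param dt Frame spacing in ps (must be > 0).
#' @return An object of class `iface_trajectory`: a list with `topology`
#'   (structure tibble of frame 1), `coords` (array `n_frames x n_atoms x 3`,
#'   Å) and `dt` (ps).
#' @export
read_trajectory <- function(paths, dt) {
  if (dt <= 0) abort("dt must be > 0 ps.", class = "iface_input_error")
  frames <- list()
  for (p in paths) {
    ens <- read_pdb_models(p)
    for (m in sort(unique(ens$pose))) {
      frames[[length(frames) + 1]] <- ens[ens$pose == m, setdiff(names(ens), "pose")]
    }
  }
  if (length(frames) == 0) abort("no frames read.", class = "iface_input_error")
  topo <- as_tibble(frames[[1]])
  n_atoms <- nrow(topo)
  coords <- array(NA_real_, dim = c(length(frames), n_atoms, 3))
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != n_atoms) {
      abort(sprintf("frame %d has %d atoms; topology has %d.",
                    i, nrow(frames[[i]]), n_atoms),
            class = "iface_congruence_error")
    }
    coords[i, , ] <- coord_matrix(frames[[i]])
  }
  new_trajectory(topo, coords, dt)
}

#' Construct a trajectory object from a topology and a coordinate array
#'
#' @param topology Structure tibble defining atom identity/order.
#' @param coords Numeric array `n_frames x n_atoms x 3` (Å).
#' @param dt Frame spacing, ps.
#' @return An `iface_trajectory` object.
#' @export
new_trajectory <- function(topology, coords, dt) {
  stopifnot_structure(topology, "topology")
  if (dt <= 0) abort("dt must be > 0 ps.", class = "iface_input_error")
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be an n_frames x n_atoms x 3 array.",
          class = "iface_input_error")
  }
  if (dim(coords)[2] != nrow(topology)) {
    abort(sprintf("coords has %d atoms per frame; topology has %d.",
                  dim(coords)[2], nrow(topology)),
          class = "iface_congruence_error")
  }
  structure(list(topology = as_tibble(topology), coords = coords, dt = dt),
            class = "iface_trajectory")
}

#' @export
print.iface_trajectory <- function(x, ...) {
  cat(sprintf("<iface_trajectory> %d frames x %d atoms, dt = %g ps (%.1f ps total)\n",
              dim(x$coords)[1], dim(x$coords)[2], x$dt,
              (dim(x$coords)[1] - 1) * x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param t An `iface_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(t) dim(t$coords)[1]
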