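# Internal helpers shared across modules.

# Canonical residue key "chain|resno|icode". Insertion codes are part of the
# identity because author numbering with insertions is ambiguous without them.
residue_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, resno, icode, sep = "|")
}

split_residue_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  tibble(
    chain = vapply(parts, `[`, "", 1),
    resno = as.integer(vapply(parts, `[`, "", 2)),
    icode = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", "")
  )
}

`%||%` <- rlang::`%||%`

stopifnot_structure <- function(s, arg = "structure") {
  needed <- c("chain", "resno", "icode", "resid", "atom", "element",
              "x", "y", "z", "occupancy", "altloc", "hetero")
  if (!is.data.frame(s) || !all(needed %in% names(s))) {
    abort(sprintf(
      "`%s` must be an atom table with columns %s (see read_pdb()).",
      arg, paste(needed, collapse = ", ")
    ), class = "iface_input_error")
  }
  invisible(s)
}

# Coordinate matrix (n x 3) for a structure tibble / atom subset
coord_matrix <- function(s) {
  as.matrix(s[, c("x", "y", "z")])
}

set_coords <- function(s, m) {
  s$x <- m[, 1]; s$y <- m[, 2]; s$z <- m[, 3]
  s
}

# Heavy-atom filter: everything that is not hydrogen/deuterium.
is_hydrogen <- function(element, atom_name) {
  el <- toupper(trimws(element))
  known <- el %in% c("H", "D")
  # fall back to the atom name when the element column is blank
  blank <- is.na(el) | el == ""
  nm <- toupper(trimws(atom_name))
  by_name <- grepl("^[0-9]*[HD]", nm)
  known | (blank & by_name)
}

select_atoms <- function(s, atoms = c("heavy", "all", "CA")) {
  atoms <- match.arg(atoms)
  switch(atoms,
    all   = s,
    heavy = s[!is_hydrogen(s$element, s$atom), , drop = FALSE],
    CA    = s[!s$hetero & s$atom == "CA", , drop = FALSE]
  )
}

# Accept an ensemble either as a tibble with a `pose` column or a list of
# structures; return a named list of structure tibbles in pose order.
as_pose_list <- function(ensemble) {
  if (is.data.frame(ensemble)) {
    if (!"pose" %in% names(ensemble)) {
      abort("ensemble data frame must carry a `pose` column.",
            class = "iface_input_error")
    }
    poses <- split(ensemble, ensemble$pose)
    poses <- poses[order(as.integer(names(poses)))]
    lapply(poses, function(p) as_tibble(p[setdiff(names(p), "pose")]))
  } else if (is.list(ensemble)) {
    lapply(ensemble, as_tibble)
  } else {
    abort("ensemble must be a data frame with a `pose` column or a list of structures.",
          class = "iface_input_error")
  }
}

new_structure <- function(df, id = "structure", source = "memory") {
  out <- as_tibble(df)
  attr(out, "structure_id") <- id
  attr(out, "source") <- source
  out
}
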