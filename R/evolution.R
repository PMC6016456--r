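#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path Aligned FASTA file (gaps as `-`).
#' @param clades Optional data frame with columns `id` and `clade` to attach
#'   clade labels, or a path to a two-column TSV with a header.
#' @return A tibble with columns `id`, `seq` (aligned, uppercase) and, when
#'   provided, `clade`. The alignment width is in attribute `width`.
#' @export
read_msa <- function(path, clades = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  out <- tibble(id = names(ss), seq = unname(toupper(as.character(ss))))
  w <- unique(nchar(out$seq))
  if (length(w) != 1) {
    abort("alignment rows differ in length; not a valid MSA.",
          class = "iface_input_error")
  }
  if (!is.null(clades)) {
    if (is.character(clades) && length(clades) == 1) {
      clades <- utils::read.delim(clades, stringsAsFactors = FALSE)
    }
    out <- left_join(out, as_tibble(clades)[, c("id", "clade")], by = "id")
  }
  attr(out, "width") <- w
  out
}

#' Map structure residues to MSA columns
#'
#' Aligns a structure chain sequence to one (gapped) MSA row: the k-th
#' non-gap character of the row corresponds to the k-th structure residue.
#' The degapped row may also be a substring or superstring of the structure
#' sequence (expression constructs and crystal structures rarely cover
#' identical residue ranges); unmatched tails are reported via attributes.
#'
#' @param seq One-letter structure chain sequence (e.g. from
#'   [chain_sequence()]).
#' @param row Aligned row from the MSA (with `-` gaps).
#' @return A tibble with columns `residue_index` (1-based position in `seq`)
#'   and `column` (1-based MSA column), strictly increasing in both.
#'   Attributes `unmatched_seq` and `unmatched_row` give the number of
#'   unmapped leading/trailing residues on either side.
#' @export
map_residues_to_columns <- function(seq, row) {
  degapped <- gsub("-", "", row, fixed = TRUE)
  nongap_cols <- which(strsplit(row, "")[[1]] != "-")
  n_seq <- nchar(seq); n_row <- nchar(degapped)
  if (n_seq == 0 || n_row == 0) {
    abort("empty sequence.", class = "iface_input_error")
  }
  if (degapped == seq) {
    res_idx <- seq_len(n_seq); cols <- nongap_cols
    un_seq <- c(0L, 0L); un_row <- c(0L, 0L)
  } else if (n_seq < n_row && grepl(seq, degapped, fixed = TRUE)) {
    off <- regexpr(seq, degapped, fixed = TRUE)[1] - 1L
    res_idx <- seq_len(n_seq); cols <- nongap_cols[off + seq_len(n_seq)]
    un_seq <- c(0L, 0L); un_row <- c(off, n_row - off - n_seq)
  } else if (n_row < n_seq && grepl(degapped, seq, fixed = TRUE)) {
    off <- regexpr(degapped, seq, fixed = TRUE)[1] - 1L
    res_idx <- off + seq_len(n_row); cols <- nongap_cols
    un_seq <- c(off, n_seq - off - n_row); un_row <- c(0L, 0L)
  } else {
    a <- strsplit(seq, "")[[1]]; b <- strsplit(degapped, "")[[1]]
    k <- min(length(a), length(b))
    mism <- which(a[seq_len(k)] != b[seq_len(k)])[1]
    abort(sprintf("structure sequence and degapped row disagree at position %d ('%s' vs '%s').",
                  mism, a[mism], b[mism]),
          class = "iface_mapping_error")
  }
  out <- tibble(residue_index = res_idx, column = cols)
  attr(out, "unmatched_seq") <- un_seq
  attr(out, "unmatched_row") <- un_row
  out
}

#' Call lineage-specific residues at interface columns
#'
#' A column is called lineage-specific when every in-clade row carries one
#' identical non-gap residue AND that residue never occurs in any out-clade
#' row at that column (strict mode, the default). A gap in any clade row
#' disqualifies the column. A relaxed frequency mode tolerates the in-clade
#' residue in at most `max_out_freq` of the out-clade rows.
#'
#' @param msa MSA tibble from [read_msa()] (columns `id`, `seq`).
#' @param clade Character vector of in-clade row ids: non-empty, proper
#'   subset of the rows.
#' @param interface_columns Integer vector of 1-based alignment columns to
#'   test (the columns that map to interface residues).
#' @param residue_map Optional map from [map_residues_to_columns()]; when
#'   given, the matching `residue_index` is attached to each call.
#' @param max_out_freq Maximum tolerated out-clade frequency of the in-clade
#'   residue (default 0 = strict absence).
#' @return A tibble with one row per called column: `column`,
#'   `in_clade_res`, `out_clade_res` (residues observed outside the clade,
#'   collapsed) and, with a `residue_map`, `residue_index`.
#' @export
lineage_specific_residues <- function(msa, clade, interface_columns,
                                      residue_map = NULL, max_out_freq = 0) {
  if (length(clade) == 0) abort("clade is empty.", class = "iface_input_error")
  if (!all(clade %in% msa$id)) {
    abort("clade ids missing from the MSA.", class = "iface_lookup_error")
  }
  if (setequal(clade, msa$id)) {
    abort("clade covers all rows; specificity undefined.",
          class = "iface_definition_error")
  }
  width <- attr(msa, "width") %||% nchar(msa$seq[1])
  if (any(interface_columns < 1 | interface_columns > width)) {
    abort("interface column outside alignment.", class = "iface_input_error")
  }
  chars <- do.call(rbind, strsplit(msa$seq, ""))
  in_rows <- msa$id %in% clade
  calls <- list()
  for (col in sort(unique(interface_columns))) {
    cc <- chars[in_rows, col]
    oc <- chars[!in_rows, col]
    if (any(cc == "-")) next
    if (length(unique(cc)) != 1) next
    res <- cc[1]
    if (mean(oc == res) > max_out_freq) next
    calls[[length(calls) + 1]] <- tibble(
      column = col, in_clade_res = res,
      out_clade_res = paste(sort(unique(oc)), collapse = "")
    )
  }
  out <- if (length(calls)) bind_rows(calls) else {
    tibble(column = integer(), in_clade_res = character(),
           out_clade_res = character())
  }
  if (!is.null(residue_map)) {
    out <- left_join(out, residue_map, by = "column")
  }
  out
}

# --- global pairwise alignment (Gotoh, affine gaps) ----------------------

aa_alphabet <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V")

check_aa <- function(seq, allow_x = TRUE) {
  if (nchar(seq) == 0) abort("empty sequence.", class = "iface_input_error")
  ch <- strsplit(toupper(seq), "")[[1]]
  ok <- aa_alphabet
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(unique(ch), ok)
  if (length(bad) > 0) {
    abort(paste0("non-amino-acid character(s): ", paste(bad, collapse = ", ")),
          class = "iface_alphabet_error")
  }
  ch
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global percent identity between two protein sequences
#'
#' Aligns the sequences globally by dynamic programming with affine gap
#' penalties (Gotoh recursion implemented in the package; a gap of length L
#' costs `gap_open + L * gap_extend`) and reports identity as identical
#' aligned residue pairs divided by alignment columns, excluding terminal
#' gap columns and any column containing `X` from both numerator and
#' denominator.
#'
#' @param a,b Amino-acid sequences (strings; `X` allowed as unknown).
#' @param gap_open,gap_extend Affine gap penalties (default 10 / 0.5).
#' @param matrix Substitution matrix (default BLOSUM62 from Biostrings).
#' @return Percent identity, rounded to 1 decimal. The alignment (two gapped
#'   strings) and score are attached as attributes `alignment` and `score`.
#' @export
percent_identity <- function(a, b, gap_open = 10, gap_extend = 0.5,
                             matrix = NULL) {
  ca <- check_aa(a); cb <- check_aa(b)
  mat <- matrix %||% blosum62()
  aln <- align_global_affine(ca, cb, mat, gap_open, gap_extend)
  ga <- aln$a; gb <- aln$b
  n_cols <- length(ga)
  # terminal gap runs of either row
  gap_either <- ga == "-" | gb == "-"
  lead <- cumprod(gap_either) > 0
  trail <- rev(cumprod(rev(gap_either)) > 0)
  internal <- !(lead | trail)
  has_x <- ga == "X" | gb == "X"
  use <- internal & !has_x
  denom <- sum(use)
  ident <- sum(use & ga == gb & ga != "-")
  pct <- if (denom == 0) 0 else 100 * ident / denom
  out <- round(pct, 1)
  attr(out, "alignment") <- c(paste(ga, collapse = ""), paste(gb, collapse = ""))
  attr(out, "score") <- aln$score
  out
}

# Gotoh global alignment; returns gapped character vectors and the score.
align_global_affine <- function(ca, cb, mat, gap_open, gap_extend) {
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  go <- gap_open + gap_extend   # cost of a length-1 gap
  ge <- gap_extend
  M <- matrix(NEG, n + 1, m + 1)   # ca[i] aligned to cb[j]
  X <- matrix(NEG, n + 1, m + 1)   # ca[i] aligned to gap
  Y <- matrix(NEG, n + 1, m + 1)   # cb[j] aligned to gap
  ptrM <- matrix(0L, n + 1, m + 1) # 1 = from M, 2 = from X, 3 = from Y
  ptrX <- matrix(0L, n + 1, m + 1)
  ptrY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- -(go + (i - 2) * ge)
    ptrX[i, 1] <- if (i == 2) 1L else 2L
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- -(go + (j - 2) * ge)
    ptrY[1, j] <- if (j == 2) 1L else 3L
  }
  sub <- mat[ca, cb, drop = FALSE]
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(prev)
      M[i, j] <- prev[k] + sub[i - 1, j - 1]
      ptrM[i, j] <- k
      xo <- c(M[i - 1, j] - go, X[i - 1, j] - ge)
      kx <- which.max(xo)
      X[i, j] <- xo[kx]
      ptrX[i, j] <- c(1L, 2L)[kx]
      yo <- c(M[i, j - 1] - go, Y[i, j - 1] - ge)
      ky <- which.max(yo)
      Y[i, j] <- yo[ky]
      ptrY[i, j] <- c(1L, 3L)[ky]
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(fin)
  score <- fin[state]
  # traceback
  ga <- character(0); gb <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (state == 1L) {
      ga <- c(ca[i - 1], ga); gb <- c(cb[j - 1], gb)
      state <- ptrM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ga <- c(ca[i - 1], ga); gb <- c("-", gb)
      state <- ptrX[i, j]; i <- i - 1
    } else {
      ga <- c("-", ga); gb <- c(cb[j - 1], gb)
      state <- ptrY[i, j]; j <- j - 1
    }
  }
  list(a = ga, b = gb, score = score)
}

# --- isoelectric point ----------------------------------------------------

# Bjellqvist pKa set (as used by common proteomics servers): side chains plus
# residue-specific N-terminal values; generic N-terminus 7.50, C-terminus 3.55.
bjellqvist_pka <- list(
  cterm = 3.55,
  nterm_default = 7.50,
  nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
            E = 7.70, G = 7.50),
  negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  positive = c(H = 5.98, K = 10.00, R = 12.00)
)

#' Net charge of a protein sequence at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the ionizable side chains
#' (D, E, C, Y negative; H, K, R positive) with the Bjellqvist pKa set.
#' `X` positions carry no charge.
#'
#' @param seq Amino-acid sequence.
#' @param pH pH value (scalar or vector).
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(seq, pH) {
  ch <- check_aa(seq)
  pk <- bjellqvist_pka
  nt <- pk$nterm[ch[1]]
  nt <- ifelse(is.na(nt), pk$nterm_default, nt)
  pos_pka <- c(nt, pk$positive[ch[ch %in% names(pk$positive)]])
  neg_pka <- c(pk$cterm, pk$negative[ch[ch %in% names(pk$negative)]])
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Isoelectric point of a protein sequence
#'
#' The pH at which the Henderson-Hasselbalch net charge (see [net_charge()])
#' crosses zero, found by bisection on `[0, 14]`. Depends only on amino-acid
#' composition (and the identity of the N-terminal residue).
#'
#' @param seq Amino-acid sequence (`X` allowed; carries no charge).
#' @param digits Decimals reported (default 2).
#' @return pI, rounded to `digits`. The unrounded root is attached as
#'   attribute `root`.
#' @export
isoelectric_point <- function(seq, digits = 2) {
  f <- function(p) net_charge(seq, p)
  lo <- 0; hi <- 14
  if (f(lo) < 0 || f(hi) > 0) {
    abort("net charge does not change sign on [0, 14].",
          class = "iface_degenerate_error")
  }
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  root <- (lo + hi) / 2
  out <- round(root, digits)
  attr(out, "root") <- root
  out
}
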