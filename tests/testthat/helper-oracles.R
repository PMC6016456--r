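# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they validate.

# All-pairs brute-force residue contact detection via a full distance matrix.
brute_force_contacts <- function(s, receptor_chains, ligand_chains,
                                 cutoff = 3.0, atoms = "heavy") {
  sel <- if (atoms == "heavy") {
    s[!(toupper(trimws(s$element)) %in% c("H", "D")), , drop = FALSE]
  } else s
  rec <- sel[sel$chain %in% receptor_chains, , drop = FALSE]
  lig <- sel[sel$chain %in% ligand_chains, , drop = FALSE]
  if (nrow(rec) == 0 || nrow(lig) == 0) return(character(0))
  A <- as.matrix(rec[, c("x", "y", "z")])
  B <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hit) == 0) return(character(0))
  pairs <- paste(rec$chain[hit[, 1]], rec$resno[hit[, 1]], rec$icode[hit[, 1]],
                 lig$chain[hit[, 2]], lig$resno[hit[, 2]], lig$icode[hit[, 2]],
                 sep = "|")
  sort(unique(pairs))
}

contact_pairs_as_keys <- function(cs) {
  if (nrow(cs) == 0) return(character(0))
  sort(unique(paste(cs$rec_chain, cs$rec_resno, cs$rec_icode,
                    cs$lig_chain, cs$lig_resno, cs$lig_icode, sep = "|")))
}

# Horn's quaternion method for optimal rigid superposition: independent of
# the SVD-based Kabsch path. Returns the minimal RMSD.
quaternion_superpose_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- t(A) %*% B
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,      Szx - Sxz,      Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,     Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,      Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# Rank correlation computed from first principles (no stats::cor).
spearman_scratch <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Closed-form RSS of y ~ a + b * fb (the linear parameters profiled out).
profiled_rss <- function(y, fb) {
  n <- length(y)
  sxx <- sum(fb^2) - sum(fb)^2 / n
  if (sxx < 1e-14) return(sum((y - mean(y))^2))
  b <- (sum(fb * y) - sum(fb) * sum(y) / n) / sxx
  a <- mean(y) - b * mean(fb)
  sum((y - a - b * fb)^2)
}

# Grid-search oracle for the single-site depletion fit: profiles out the
# linear parameters (F_min, F_max) exactly for each KD on a fine grid.
grid_fit_single_site <- function(curve, L, kd_grid = NULL) {
  kd_grid <- kd_grid %||% exp(seq(log(0.1), log(500), length.out = 4000))
  y <- curve$signal
  best <- list(rss = Inf, KD = NA)
  for (kd in kd_grid) {
    fb <- ifacetools::bound_fraction_depletion(curve$conc, L, kd)
    rss <- profiled_rss(y, fb)
    if (rss < best$rss) best <- list(rss = rss, KD = kd)
  }
  best
}

# Grid-search oracle for the Hill fit over (K_half, n).
grid_fit_hill <- function(curve, k_grid = NULL, n_grid = NULL) {
  k_grid <- k_grid %||% exp(seq(log(1), log(200), length.out = 300))
  n_grid <- n_grid %||% seq(0.5, 2.5, by = 0.005)
  y <- curve$signal
  best <- list(rss = Inf, K_half = NA, n = NA)
  for (k in k_grid) for (n in n_grid) {
    fb <- curve$conc^n / (k^n + curve$conc^n)
    rss <- profiled_rss(y, fb)
    if (rss < best$rss) best <- list(rss = rss, K_half = k, n = n)
  }
  best
}

# Fine-grid sign-change scan for the isoelectric point.
pi_grid_oracle <- function(seq, dpH = 1e-4) {
  ph <- seq(0, 14, by = dpH)
  z <- ifacetools::net_charge(seq, ph)
  i <- which(z[-length(z)] > 0 & z[-1] <= 0)[1]
  (ph[i] + ph[i + 1]) / 2
}

# Straight per-column scan for clade-specific columns.
brute_clade_calls <- function(msa, clade, cols) {
  chars <- do.call(rbind, strsplit(msa$seq, ""))
  in_rows <- msa$id %in% clade
  called <- integer(0)
  for (col in cols) {
    cc <- chars[in_rows, col]; oc <- chars[!in_rows, col]
    if (any(cc == "-")) next
    if (length(unique(cc)) != 1) next
    if (cc[1] %in% oc) next
    called <- c(called, col)
  }
  sort(called)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
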