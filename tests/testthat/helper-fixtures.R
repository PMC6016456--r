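# Small fixture builders used across test files.

# Minimal structure tibble from per-chain CA coordinate matrices.
toy_structure <- function(..., resid = "ALA", hetero = FALSE) {
  chains <- list(...)
  rows <- lapply(names(chains), function(ch) {
    m <- chains[[ch]]
    tibble::tibble(
      chain = ch, resno = seq_len(nrow(m)), icode = "", resid = resid,
      atom = "CA", element = "C",
      x = m[, 1], y = m[, 2], z = m[, 3],
      occupancy = 1, altloc = "", hetero = hetero
    )
  })
  dplyr::bind_rows(rows)
}

# Random two-chain complex (CA-only) for contact oracle checks.
random_complex <- function(n_rec, n_lig, box = 20, seed = 1) {
  withr::with_seed(seed, {
    toy_structure(
      A = matrix(runif(n_rec * 3, 0, box), ncol = 3),
      L = matrix(runif(n_lig * 3, 0, box), ncol = 3)
    )
  })
}

# Apply a random rigid motion to a coordinate matrix.
random_rigid <- function(m, seed = 1) {
  withr::with_seed(seed, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    t <- rnorm(3, 0, 10)
    sweep(m %*% R, 2, t, `+`)
  })
}

transform_structure <- function(s, seed = 1) {
  m <- random_rigid(as.matrix(s[, c("x", "y", "z")]), seed = seed)
  s$x <- m[, 1]; s$y <- m[, 2]; s$z <- m[, 3]
  s
}

std_grid <- c(0.5, 1, 2, 5, 10, 20, 35, 50, 75, 100, 125, 150)
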