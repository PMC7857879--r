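# Shared fixtures and independent brute-force oracles.

# Small, fast parameter set for unit tests (dynamics are the same automaton,
# scaled down spatially).
small_params <- function(...) {
  args <- list(...)
  if (is.null(args$ncell)) args$ncell <- 33
  if (is.null(args$n_iter)) args$n_iter <- 40
  do.call(tumor_params, args)
}

# Independent block-average oracle: explicit enumeration of the shifted 3x3
# periodic partition, no shared code with the implementation.
brute_block_average <- function(field, t) {
  n <- nrow(field)
  s <- t %% 3
  nb <- (n + 2) %/% 3
  out <- matrix(NA_real_, n, n)
  for (br in seq_len(nb) - 1) {
    for (bc in seq_len(nb) - 1) {
      rows0 <- (br * 3):(min(br * 3 + 2, n - 1))        # 0-based band rows
      cols0 <- (bc * 3):(min(bc * 3 + 2, n - 1))
      rows <- ((rows0 + s) %% n) + 1                    # wrap by the shift
      cols <- ((cols0 + s) %% n) + 1
      vals <- field[rows, cols, drop = FALSE]
      out[rows, cols] <- mean(vals)
    }
  }
  out
}

# Brute-force one-step field update: Eq-style site-by-site application of
# alpha * A + (1 - alpha) * u - f, clamped at zero.
brute_diffusion_step <- function(fields, grid, p, t) {
  inc <- cell_metabolism(grid, fields, p)
  nm <- c("o2", "gl", "h", "gf", "if_")
  for (i in seq_along(nm)) {
    f <- nm[i]
    a <- p$alpha[[i]]
    A <- brute_block_average(fields[[f]], t)
    u <- fields[[f]]
    out <- u
    for (k in seq_along(u)) out[k] <- max(0, a * A[k] + (1 - a) * u[k] - inc[[f]][k])
    fields[[f]] <- out
  }
  fields
}

# Place a block of tumor cells on a fresh grid; returns the grid.
grid_with_square <- function(ncell, half, state = 1L, center = NULL) {
  g <- tumor_grid(ncell, center)
  rows <- (g$center[1] - half):(g$center[1] + half)
  cols <- (g$center[2] - half):(g$center[2] + half)
  g$states[rows, cols] <- state
  g
}

# Moore-connectivity check via flood fill from an arbitrary tumor cell.
tumor_connected <- function(states) {
  n <- nrow(states)
  tumor <- states > 0L
  idx <- which(tumor)
  if (length(idx) <= 1) return(TRUE)
  seen <- matrix(FALSE, n, n)
  queue <- idx[1]
  seen[queue] <- TRUE
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    r <- ((i - 1) %% n) + 1
    c <- ((i - 1) %/% n) + 1
    for (k in seq_len(8)) {
      rr <- ((r - 1 + offs$dr[k]) %% n) + 1
      cc <- ((c - 1 + offs$dc[k]) %% n) + 1
      j <- rr + (cc - 1) * n
      if (tumor[j] && !seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen[tumor])
}
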