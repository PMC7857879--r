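# Lattice containers and cached geometry helpers.
#
# States: 0 normal/empty, 1 proliferating (PC), 2 quiescent (QC), 3 necrotic
# (NeC). The `empty` flag separates empty space from living normal tissue
# within state 0 (empty sites are metabolically inert; normal cells consume).

CELL_NORMAL <- 0L
CELL_PC <- 1L
CELL_QC <- 2L
CELL_NEC <- 3L

.lattice_cache <- new.env(parent = emptyenv())

#' Create an empty cell lattice
#'
#' Builds the cell-state container: an `ncell` x `ncell` lattice of normal
#' tissue with per-site phenotype (mutant flag, meaningful for proliferating
#' cells), stall counters (consecutive failed mitosis attempts), and an
#' empty-space flag distinguishing vacated sites from living normal cells.
#'
#' @param ncell Side length of the square lattice.
#' @param center Seed coordinate (row, column), 1-based; defaults to the
#'   central site.
#' @return An object of class `cell_grid` with elements `ncell`, `center`,
#'   `states`, `mutant`, `stall`, `empty`.
#' @examples
#' g <- tumor_grid(9)
#' table(g$states)
#' @export
tumor_grid <- function(ncell, center = NULL) {
  ncell <- as.integer(ncell)
  if (ncell < 3) stop("ncell must be at least 3")
  if (is.null(center)) center <- rep((ncell + 1L) %/% 2L, 2L)
  center <- as.integer(center)
  if (any(center < 1L) || any(center > ncell))
    stop("center must lie inside the lattice")
  g <- list(
    ncell = ncell,
    center = center,
    states = matrix(CELL_NORMAL, ncell, ncell),
    mutant = matrix(FALSE, ncell, ncell),
    stall = matrix(0L, ncell, ncell),
    empty = matrix(FALSE, ncell, ncell)
  )
  class(g) <- "cell_grid"
  g
}

#' Create background metabolic fields
#'
#' Five co-registered concentration lattices: oxygen and glucose (mMol),
#' hydrogen ions (mol/L scale, so that `pH = -log10(h)`), and dimensionless
#' growth / inhibitory factors. All fields start at the uniform medium
#' backgrounds, optionally jittered by a multiplicative uniform perturbation
#' of half-width `p$init_jitter`.
#'
#' @param p A validated [tumor_params()] object.
#' @return An object of class `metabolic_fields`: list of matrices `o2`,
#'   `gl`, `h`, `gf`, `if_`.
#' @examples
#' f <- metabolic_fields(tumor_params(ncell = 9))
#' f$o2[1, 1]
#' @export
metabolic_fields <- function(p) {
  n <- p$ncell
  jit <- function(bg) {
    m <- matrix(bg, n, n)
    if (p$init_jitter > 0)
      m <- m * matrix(stats::runif(n * n, 1 - p$init_jitter,
                                   1 + p$init_jitter), n, n)
    m
  }
  f <- list(
    o2 = jit(p$c0),
    gl = jit(p$g0),
    h = jit(h_from_ph(p$pH0)),
    gf = jit(p$Gf0),
    if_ = matrix(p$If0, n, n)
  )
  class(f) <- "metabolic_fields"
  f
}

# Periodic shift of a matrix by (dr, dc); used for Moore-neighborhood sums.
shift_mat <- function(m, dr, dc) {
  n <- nrow(m)
  ri <- ((seq_len(n) - 1L + dr) %% n) + 1L
  ci <- ((seq_len(n) - 1L + dc) %% n) + 1L
  m[ri, ci, drop = FALSE]
}

MOORE_OFFSETS <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# Cached per-(ncell, center) geometry: Euclidean distance of every site from
# the seed, Moore neighbor linear indices (periodic wrap), and block-average
# group structure for the three shifted 3x3 partitions.
lattice_geometry <- function(ncell, center) {
  key <- paste(ncell, center[1], center[2], sep = "_")
  got <- .lattice_cache[[key]]
  if (!is.null(got)) return(got)
  n <- as.integer(ncell)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dist <- sqrt((rows - center[1])^2 + (cols - center[2])^2)

  idx <- seq_len(n * n)
  r0 <- (idx - 1L) %% n          # 0-based row
  c0 <- (idx - 1L) %/% n         # 0-based col
  nb <- matrix(0L, n * n, 8L)
  for (k in seq_len(8L)) {
    rr <- (r0 + MOORE_OFFSETS[k, "dr"]) %% n
    cc <- (c0 + MOORE_OFFSETS[k, "dc"]) %% n
    nb[, k] <- rr + cc * n + 1L
  }

  # Block partition for shift s: 0-based coordinate x belongs to band
  # ((x - s) mod n) %/% 3. When n is not a multiple of 3 the last band of
  # each dimension wraps as a partial (2-wide for n %% 3 == 2) block.
  groups <- vector("list", 3L)
  counts <- vector("list", 3L)
  nb_bands <- (n + 2L) %/% 3L
  for (s in 0:2) {
    rb <- ((r0 - s) %% n) %/% 3L
    cb <- ((c0 - s) %% n) %/% 3L
    rb[rb >= nb_bands] <- nb_bands - 1L
    cb[cb >= nb_bands] <- nb_bands - 1L
    grp <- rb + cb * nb_bands + 1L
    groups[[s + 1L]] <- grp
    counts[[s + 1L]] <- tabulate(grp, nbins = nb_bands * nb_bands)
  }
  geo <- list(dist = dist, nb = nb, groups = groups, counts = counts)
  .lattice_cache[[key]] <- geo
  geo
}

# Count of tumor-occupied (states > 0) Moore neighbors for every site.
moore_tumor_count <- function(states) {
  tumor <- states > CELL_NORMAL
  acc <- matrix(0L, nrow(states), ncol(states))
  for (k in seq_len(8L))
    acc <- acc + shift_mat(tumor, MOORE_OFFSETS[k, "dr"],
                           MOORE_OFFSETS[k, "dc"])
  acc
}
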