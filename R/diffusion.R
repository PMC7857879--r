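# Block-cellular-automata transport of the metabolic fields.
#
# The lattice is partitioned into 3x3 blocks; within each block every site is
# replaced by the block mean (mass-conserving redistribution). The partition
# origin shifts down one row and right one column each iteration, cycling
# through three distinct partitions so that mass propagates across block
# boundaries. Each field relaxes toward its block average with a per-field
# weight alpha in (0,1) that encodes its diffusivity:
#   u[t+1] = alpha * A + (1 - alpha) * u[t] - f
# where A is the block-average lattice and f the per-site source/sink term.

#' Block average of a concentration lattice
#'
#' Replaces every site by the mean of its 3x3 block under the shifting
#' periodic partition of iteration `t` (the partition origin is
#' `(t mod 3, t mod 3)`). The global sum of the field is conserved. Lattices
#' whose side is not a multiple of 3 are tiled with wrapped partial blocks.
#'
#' @param field Numeric matrix (square).
#' @param t Iteration index (determines the partition shift).
#' @return Matrix of the same shape holding block means.
#' @examples
#' m <- matrix(0, 6, 6); m[1, 1] <- 9
#' b <- block_average(m, 0)
#' b[1:3, 1:3]           # the 9 spreads to 1 everywhere in its block
#' sum(b) == sum(m)
#' @export
block_average <- function(field, t) {
  n <- nrow(field)
  if (ncol(field) != n) stop("field must be square")
  geo <- lattice_geometry(n, rep((n + 1L) %/% 2L, 2L))
  s <- (as.integer(t) %% 3L) + 1L
  grp <- geo$groups[[s]]
  tot <- rowsum(as.vector(field), grp, reorder = TRUE)
  lab <- as.integer(rownames(tot))   # contiguous 1..K in practice
  avg <- numeric(length(geo$counts[[s]]))
  avg[lab] <- tot[, 1] / geo$counts[[s]][lab]
  matrix(avg[grp], n, n)
}

#' Per-site metabolic source/sink increments
#'
#' Computes the per-iteration consumption (positive) or production (negative)
#' of each metabolic field at every lattice site, according to the occupying
#' cell type:
#' \itemize{
#'   \item Proliferating cells consume oxygen and glucose and produce H+.
#'     Below the hypoxia threshold `O2_thre` they switch to anaerobic
#'     glycolysis: glucose uptake and acid output are multiplied up
#'     (`k_gl_anaerobic`, `k_H_anaerobic`) and oxygen uptake is damped
#'     (`k_o2_anaerobic`).
#'   \item Quiescent cells use `quiescent_factor` times the proliferating
#'     rates (they are nearly metabolically inactive).
#'   \item Necrotic cells consume nothing and keep producing H+.
#'   \item Living normal cells consume `modulation_normal` times the
#'     proliferating oxygen/glucose rates and produce no acid.
#'   \item Empty sites are inert.
#' }
#' Tumor cells additionally consume growth factor and produce inhibitory
#' factor (these fields gate no rule). Consumption is truncated to the
#' locally available concentration so no field can be driven negative.
#'
#' @param grid A `cell_grid`.
#' @param fields A `metabolic_fields` object.
#' @param p A validated [tumor_params()] object.
#' @return List of five increment matrices (`o2`, `gl`, `h`, `gf`, `if_`),
#'   positive = consumption, negative = production.
#' @export
cell_metabolism <- function(grid, fields, p) {
  st <- grid$states
  q_o2 <- p$rate_scale * p$Cr_o2
  q_gl <- p$rate_scale * p$Cr_gl
  q_h <- p$rate_scale * p$h_scale * p$Cr_H
  q_gf <- p$gf_scale * p$Cr_Gf
  q_if <- p$gf_scale * p$Cr_If

  anaerobic <- fields$o2 < p$O2_thre
  # per-site multipliers relative to an aerobic proliferating cell
  m_o2 <- m_gl <- m_h <- m_gf <- m_if <- matrix(0, p$ncell, p$ncell)

  pc <- st == CELL_PC
  qc <- st == CELL_QC
  nec <- st == CELL_NEC
  normal <- st == CELL_NORMAL & !grid$empty

  for (mask_fac in list(list(pc, 1), list(qc, p$quiescent_factor))) {
    m <- mask_fac[[1]]; fac <- mask_fac[[2]]
    ana <- m & anaerobic
    aer <- m & !anaerobic
    m_o2[aer] <- m_o2[aer] + fac
    m_gl[aer] <- m_gl[aer] + fac
    m_h[aer] <- m_h[aer] - fac
    m_o2[ana] <- m_o2[ana] + fac * p$k_o2_anaerobic
    m_gl[ana] <- m_gl[ana] + fac * p$k_gl_anaerobic
    m_h[ana] <- m_h[ana] - fac * p$k_H_anaerobic
    m_gf[m] <- m_gf[m] + fac
    m_if[m] <- m_if[m] - fac
  }
  m_h[nec] <- -1                      # dead cells keep acidifying
  m_o2[normal] <- p$modulation_normal # normal tissue consumes O2/gl only
  m_gl[normal] <- p$modulation_normal

  inc <- list(
    o2 = pmin(m_o2 * q_o2, fields$o2),
    gl = pmin(m_gl * q_gl, fields$gl),
    h = pmin(m_h * q_h, fields$h),
    gf = pmin(m_gf * q_gf, fields$gf),
    if_ = pmin(m_if * q_if, fields$if_)
  )
  inc
}

#' One diffusion step of all five metabolic fields
#'
#' Applies the block-cellular-automata update
#' `u <- alpha * block_average(u, t) + (1 - alpha) * u - f`
#' to each field, where `f` comes from [cell_metabolism()]. Results are
#' clamped at zero.
#'
#' @inheritParams cell_metabolism
#' @param t Iteration index, passed to [block_average()].
#' @return Updated `metabolic_fields`.
#' @export
diffusion_step <- function(fields, grid, p, t) {
  if (any(p$alpha <= 0) || any(p$alpha >= 1))
    stop("alpha weights must lie strictly in (0, 1)")
  inc <- cell_metabolism(grid, fields, p)
  nm <- c("o2", "gl", "h", "gf", "if_")
  for (i in seq_along(nm)) {
    f <- nm[i]
    a <- p$alpha[[i]]
    fields[[f]] <- pmax(a * block_average(fields[[f]], t) +
                          (1 - a) * fields[[f]] - inc[[f]], 0)
  }
  fields
}

#' Replenish the medium from the vasculature
#'
#' The host tissue is perfused: at every normal/empty site, oxygen and
#' glucose are raised to at least `medium_floor_frac` times their medium
#' backgrounds and hydrogen ions are washed out down to at most the
#' background concentration divided by `medium_floor_frac` (so medium
#' concentrations never drift more than ~5% from fresh-medium values under
#' the default 0.95). Tumor-occupied sites are untouched. With
#' `replenish_mode = "boundary"` only the outermost lattice ring is
#' replenished.
#'
#' @inheritParams cell_metabolism
#' @return Updated `metabolic_fields`.
#' @export
replenish_medium <- function(fields, grid, p) {
  mask <- grid$states == CELL_NORMAL
  if (p$replenish_mode == "boundary") {
    ring <- matrix(FALSE, p$ncell, p$ncell)
    ring[c(1L, p$ncell), ] <- TRUE
    ring[, c(1L, p$ncell)] <- TRUE
    mask <- mask & ring
  }
  if (!any(mask)) return(fields)
  frac <- p$medium_floor_frac
  fields$o2[mask] <- pmax(fields$o2[mask], frac * p$c0)
  fields$gl[mask] <- pmax(fields$gl[mask], frac * p$g0)
  fields$h[mask] <- pmin(fields$h[mask], h_from_ph(p$pH0) / frac)
  fields
}
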