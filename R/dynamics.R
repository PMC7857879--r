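# State-transition rules of the automaton.
#
# Allowed transitions: 0 -> 1 (daughter placement), 1 -> 2 (stall-out or
# quiescence trigger), 1 -> 3, 2 -> 1 (reoxygenated / rim quiescent cells),
# 2 -> 3, 0 -> 0(empty) (normal-cell death). Necrosis is absorbing.

#' Microenvironmental response of a cell
#'
#' Classifies local conditions against the survival thresholds. Necrosis
#' conditions (oxygen below `O2_thre2`, glucose below `gl_thre2`, or pH below
#' `pH_thre_Ne`) are checked first; then quiescence conditions (oxygen below
#' `O2_thre`, glucose below `gl_thre`, or pH below `pH_thre_q`); otherwise
#' proliferation is permitted. A cell is additionally flagged anaerobic
#' whenever local oxygen is below `O2_thre`.
#'
#' All arguments are vectorized.
#'
#' @param o2,gl Local oxygen and glucose concentrations (mMol).
#' @param ph Local pH.
#' @param p A validated [tumor_params()] object.
#' @return List with `verdict` (character vector:
#'   `"proliferation_permitted"`, `"quiescence_trigger"`,
#'   `"necrosis_trigger"`) and logical `anaerobic`.
#' @examples
#' p <- tumor_params()
#' classify_microenvironment(c(0.5, 0.015, 0.005), 5, 7.3, p)$verdict
#' @export
classify_microenvironment <- function(o2, gl, ph, p) {
  necro <- o2 < p$O2_thre2 | gl < p$gl_thre2 | ph < p$pH_thre_Ne
  quies <- !necro & (o2 < p$O2_thre | gl < p$gl_thre | ph < p$pH_thre_q)
  verdict <- rep("proliferation_permitted", length(necro))
  verdict[quies] <- "quiescence_trigger"
  verdict[necro] <- "necrosis_trigger"
  list(verdict = verdict, anaerobic = o2 < p$O2_thre)
}

#' Division probability of a proliferating tumor cell
#'
#' Mutant cells divide with probability `p0 * (1 - r/Rmax)`, independent of
#' their surroundings. Nonmutant cells divide with probability
#' `phi0 * (n_normal/8) * (1 - r/Rmax)`: the more normal cells / free space
#' in the Moore neighborhood, the likelier the division (the count is
#' normalized by the neighborhood size so the result is a probability).
#' Beyond the maximum tumor extent `Rmax` the probability is zero, which
#' saturates growth in a Gompertz-like fashion.
#'
#' @param is_mutant Logical vector: phenotype of the dividing cell.
#' @param r Distance from the tumor seed (lattice units), non-negative.
#' @param n_normal Number of state-0 (normal or empty) Moore neighbors,
#'   0 to 8.
#' @param p A validated [tumor_params()] object.
#' @return Probability in `[0, 1]`, vectorized over the inputs.
#' @examples
#' p <- tumor_params()
#' division_probability(TRUE, 0, 0, p)        # p0
#' division_probability(FALSE, 0, 8, p)       # phi0
#' division_probability(TRUE, p$Rmax, 8, p)   # 0 at the maximum extent
#' @export
division_probability <- function(is_mutant, r, n_normal, p) {
  if (any(r < 0)) stop("distance r must be non-negative")
  if (any(n_normal < 0 | n_normal > 8))
    stop("n_normal must lie in 0..8")
  radial <- pmax(0, 1 - r / p$Rmax)
  prob <- ifelse(is_mutant, p$p0 * radial,
                 p$phi0 * (n_normal / 8) * radial)
  pmin(1, pmax(0, prob))
}

#' Attempt mitosis of one proliferating cell
#'
#' With probability [division_probability()] the cell divides: one daughter
#' keeps the parent's site, the other is placed on a uniformly chosen Moore
#' neighbor of state 0 (empty space or normal cell). A mutant parent's
#' daughter is nonmutant with probability `Nmm`, otherwise mutant; nonmutant
#' parents breed true. On success the stall counter resets. If no state-0
#' neighbor exists or the probability draw fails, the stall counter
#' increments; after `stall_limit` consecutive failures the cell falls
#' quiescent.
#'
#' Uses R's global RNG stream.
#'
#' @param site Integer (row, column) coordinate of a proliferating cell.
#' @param grid A `cell_grid`.
#' @param p A validated [tumor_params()] object.
#' @return The updated `cell_grid`.
#' @export
attempt_mitosis <- function(site, grid, p) {
  i <- site[1] + (site[2] - 1L) * grid$ncell
  if (grid$states[i] != CELL_PC)
    stop("attempt_mitosis called on a site that does not hold a PC")
  geo <- lattice_geometry(grid$ncell, grid$center)
  res <- mitosis_kernel(grid$states, grid$mutant, grid$stall, i,
                        geo$dist[i], geo$nb[i, ], p)
  grid$states <- res$states
  grid$mutant <- res$mutant
  grid$stall <- res$stall
  grid
}

# Shared mitosis logic for one PC at linear index i. Returns the three
# (possibly modified) lattices; designed so the engine loop can keep flat
# matrices and avoid repacking the grid object per cell.
mitosis_kernel <- function(states, mutant, stall, i, r, nbi, p) {
  open <- nbi[states[nbi] == CELL_NORMAL]
  n_open <- length(open)
  divided <- FALSE
  if (n_open > 0L) {
    prob <- division_probability(mutant[i], r, n_open, p)
    if (stats::runif(1) < prob) {
      j <- if (n_open == 1L) open else open[sample.int(n_open, 1L)]
      states[j] <- CELL_PC
      mutant[j] <- if (mutant[i]) stats::runif(1) >= p$Nmm else FALSE
      stall[j] <- 0L
      stall[i] <- 0L
      divided <- TRUE
    }
  }
  if (!divided) {
    stall[i] <- stall[i] + 1L
    if (stall[i] >= p$stall_limit) {
      states[i] <- CELL_QC
      stall[i] <- 0L
    }
  }
  list(states = states, mutant = mutant, stall = stall, divided = divided)
}

#' Update one quiescent cell
#'
#' A quiescent cell within the proliferative rim (distance from the seed at
#' least `Rt - Wp`) or with all three metabolic factors above the quiescence
#' thresholds recovers to a proliferating cell, its mutant phenotype restored
#' to its pre-quiescence value — access to sufficient nutrients overrides
#' position. Otherwise, a quiescent cell inside the necrotic core (distance
#' below `Rn`) turns necrotic. Any other quiescent cell is unchanged.
#'
#' @param site Integer (row, column) coordinate of a quiescent cell.
#' @param grid A `cell_grid`.
#' @param fields A `metabolic_fields` object.
#' @param geometry A `tumor_geometry` (see [compute_geometry()]) computed at
#'   the start of the iteration.
#' @param p A validated [tumor_params()] object.
#' @return The new state code for the site (`1`, `2` or `3`).
#' @export
update_quiescent <- function(site, grid, fields, geometry, p) {
  i <- site[1] + (site[2] - 1L) * grid$ncell
  if (grid$states[i] != CELL_QC)
    stop("update_quiescent called on a site that does not hold a QC")
  geo <- lattice_geometry(grid$ncell, grid$center)
  r <- geo$dist[i]
  nutrients_ok <- fields$o2[i] >= p$O2_thre && fields$gl[i] >= p$gl_thre &&
    ph_from_h(fields$h[i]) >= p$pH_thre_q
  if (r >= geometry$Rt - geometry$Wp || nutrients_ok) return(CELL_PC)
  if (r < geometry$Rn) return(CELL_NEC)
  CELL_QC
}

#' Apply necrosis across the lattice
#'
#' Every tumor cell (proliferating or quiescent) whose microenvironment
#' triggers necrosis becomes necrotic; necrotic cells are absorbing and are
#' never modified. Living normal cells under necrosis conditions die by
#' apoptosis and leave empty space (or join the necrotic count when
#' `normal_death = "necrotic"`).
#'
#' @inheritParams cell_metabolism
#' @return The updated `cell_grid`.
#' @export
apply_necrosis <- function(grid, fields, p) {
  resp <- classify_microenvironment(fields$o2, fields$gl,
                                    ph_from_h(pmax(fields$h, 1e-300)), p)
  necro <- matrix(resp$verdict == "necrosis_trigger", p$ncell, p$ncell)
  tumor_dies <- necro & (grid$states == CELL_PC | grid$states == CELL_QC)
  grid$states[tumor_dies] <- CELL_NEC
  grid$stall[tumor_dies] <- 0L
  normal_dies <- necro & grid$states == CELL_NORMAL & !grid$empty
  if (p$normal_death == "empty") {
    grid$empty[normal_dies] <- TRUE
  } else {
    grid$states[normal_dies] <- CELL_NEC
  }
  grid
}
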