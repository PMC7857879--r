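# Tumor geometry, population metrics and spatial stratification.

#' Mean tumor radius
#'
#' The tumor radius `Rt` is the mean Euclidean distance from the seed site to
#' the boundary tumor cells — tumor cells with at least one non-tumor Moore
#' neighbor (the external edge of the tumor). A single-cell tumor has radius
#' zero.
#'
#' @param grid A `cell_grid` containing at least one tumor cell.
#' @return Mean boundary distance in lattice units.
#' @examples
#' g <- tumor_grid(11)
#' g$states[6, 6] <- 1L
#' compute_radius(g)   # 0
#' @export
compute_radius <- function(grid) {
  tumor <- grid$states > CELL_NORMAL
  if (!any(tumor)) stop("compute_radius: no tumor cells on the lattice")
  boundary <- tumor & (moore_tumor_count(grid$states) < 8L)
  geo <- lattice_geometry(grid$ncell, grid$center)
  if (!any(boundary)) return(mean(geo$dist[tumor]))  # lattice-filling tumor
  mean(geo$dist[boundary])
}

#' Multicellular-layer geometry from the tumor radius
#'
#' The proliferative rim thickness and necrotic-core radius follow the
#' power-law relation `Wp = b * Rt^(2/3)` and `Rn = Rt - (a + b * Rt^(2/3))`
#' (clamped at zero).
#'
#' @param Rt Mean tumor radius (lattice units), non-negative.
#' @param p A validated [tumor_params()] object (supplies `a` and `b`).
#' @return An object of class `tumor_geometry`: list with `Rt`, `Rn`, `Wp`.
#' @examples
#' p <- tumor_params()
#' compute_geometry(8, p)    # Wp = 0.44, Rn = 7.14
#' @export
compute_geometry <- function(Rt, p) {
  stopifnot(Rt >= 0)
  Wp <- p$b * Rt^(2 / 3)
  Rn <- max(0, Rt - (p$a + Wp))
  structure(list(Rt = Rt, Rn = Rn, Wp = Wp), class = "tumor_geometry")
}

#' Growth and necrotic fractions
#'
#' `GF = PC / (PC + QC + NeC)` and `NF = NeC / (PC + QC + NeC)`.
#'
#' @param pc,qc,nec Cell counts.
#' @return Named numeric vector `c(gf = , nf = )`.
#' @examples
#' compute_fractions(10, 5, 5)   # gf 0.5, nf 0.25
#' @export
compute_fractions <- function(pc, qc, nec) {
  total <- pc + qc + nec
  if (any(total <= 0)) stop("compute_fractions: no tumor cells")
  c(gf = pc / total, nf = nec / total)
}

#' Critical point of a simulation record
#'
#' The critical point is the first iteration at which the necrotic count
#' reaches or exceeds the proliferating count, after the proliferating
#' population has been positive. The necrotic population must exist at the
#' crossing (`n_nec > 0`): a momentary all-quiescent dip of a young tumor
#' (zero proliferating, zero necrotic) is not a crossing of the two
#' populations.
#'
#' @param record A data frame with columns `iter`, `n_pc`, `n_nec` (the
#'   `record` element of a [run_simulation()] result).
#' @return The iteration index, or `NA` if the counts never cross.
#' @examples
#' rec <- data.frame(iter = 0:2, n_pc = c(10, 8, 6), n_nec = c(2, 6, 7))
#' detect_cp(rec)   # 2
#' @export
detect_cp <- function(record) {
  had_pc <- cumsum(record$n_pc > 0) > 0
  hit <- which(record$n_nec >= record$n_pc & record$n_nec > 0 & had_pc)
  if (!length(hit)) return(NA_integer_)
  record$iter[hit[1]]
}

#' Normalized spherical tumor volume
#'
#' Under the spherical-growth approximation the tumor volume is proportional
#' to `Rt^3`. Given a series, the returned volumes are normalized to the
#' final value; a single radius returns the raw cube.
#'
#' @param Rt Numeric vector of radii.
#' @param normalize Normalize the series to its final value (default when
#'   more than one radius is supplied).
#' @return Numeric vector of (normalized) volumes.
#' @examples
#' tumor_volume(2) / tumor_volume(1)   # 8
#' tumor_volume(c(1, 2, 4))            # ends at 1
#' @export
tumor_volume <- function(Rt, normalize = length(Rt) > 1) {
  stopifnot(all(Rt >= 0))
  v <- Rt^3
  if (normalize && v[length(v)] > 0) v <- v / v[length(v)]
  v
}

#' Default stratification bins
#'
#' The pH analysis uses four layers (pH >= 7.2; 7.0–7.2; 6.8–7.0; < 6.8).
#' The oxygen analysis applies three layers to the difference between an
#' `Nmm > 0` oxygen lattice and the matching `Nmm = 0` lattice, with
#' boundaries `-0.4e-8` and `-0.8e-8` on that relative scale.
#'
#' @return A list of class `layer_bins` with elements `ph_bins` and
#'   `ox_bins`, each a vector of increasing inner boundaries.
#' @export
layer_bins <- function() {
  structure(list(ph_bins = c(6.8, 7.0, 7.2),
                 ox_bins = c(-0.8e-8, -0.4e-8)),
            class = "layer_bins")
}

#' Layer occupancy of a lattice
#'
#' Fraction of lattice sites whose value falls in each layer defined by the
#' boundary vector, counted from the highest layer down (matching the pH 1-4
#' and Ox 1-3 labelling: layer 1 holds values at or above the top boundary).
#' The fractions sum to one.
#'
#' @param field Numeric matrix (e.g. a pH lattice or an oxygen difference
#'   lattice).
#' @param bins Increasing numeric vector of inner boundaries.
#' @return Named numeric vector of occupancy fractions, layer 1 first.
#' @examples
#' stratify_layers(matrix(c(7.3, 7.1, 6.9, 6.7), 2), layer_bins()$ph_bins)
#' @export
stratify_layers <- function(field, bins) {
  stopifnot(!is.unsorted(bins))
  brk <- c(-Inf, bins, Inf)
  counts <- tabulate(findInterval(as.vector(field), brk,
                                  rightmost.closed = FALSE),
                     nbins = length(brk) - 1)
  frac <- rev(counts) / length(field)
  names(frac) <- paste0("layer", seq_along(frac))
  frac
}

#' Center and edge concentrations of the tumor
#'
#' Returns each field's value at the seed site and its mean over the
#' boundary tumor cells. For a single-cell tumor, center and edge coincide.
#'
#' @param fields A `metabolic_fields` object, or a `tumor_sim` run with
#'   stored snapshots (then one profile per snapshot iteration is returned,
#'   with an `iter` column).
#' @param grid A `cell_grid` containing at least one tumor cell; ignored
#'   when `fields` is a `tumor_sim`.
#' @return Data frame with one row per field (`o2`, `gl`, `ph`) and columns
#'   `center`, `edge` (pH reported on the pH scale).
#' @export
center_edge_profile <- function(fields, grid) {
  if (inherits(fields, "tumor_sim")) {
    sim <- fields
    out <- lapply(names(sim$snapshots), function(t) {
      sn <- sim$snapshots[[t]]
      g <- sim$grid
      g$states <- sn$states
      f <- structure(sn[c("o2", "gl", "h", "gf", "if_")],
                     class = "metabolic_fields")
      if (!any(g$states > CELL_NORMAL)) return(NULL)
      cbind(iter = as.integer(t), center_edge_profile(f, g))
    })
    return(do.call(rbind, out))
  }
  tumor <- grid$states > CELL_NORMAL
  if (!any(tumor)) stop("center_edge_profile: no tumor cells")
  boundary <- tumor & (moore_tumor_count(grid$states) < 8L)
  ci <- grid$center[1] + (grid$center[2] - 1L) * grid$ncell
  ph <- ph_from_h(pmax(fields$h, 1e-300))
  data.frame(
    field = c("o2", "gl", "ph"),
    center = c(fields$o2[ci], fields$gl[ci], ph[ci]),
    edge = c(mean(fields$o2[boundary]), mean(fields$gl[boundary]),
             mean(ph[boundary]))
  )
}
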