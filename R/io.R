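# Plain-text export of simulation results.

#' Export the per-iteration time series
#'
#' Writes the simulation record as CSV, one row per iteration, in the
#' documented column order (`iter`, counts, fractions, geometry, mean
#' concentrations, lattice minimum pH).
#'
#' @param sim A `tumor_sim` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(sim, path) {
  stopifnot(inherits(sim, "tumor_sim"))
  utils::write.csv(sim$record, path, row.names = FALSE)
  invisible(path)
}

#' Export lattice snapshots
#'
#' Writes each stored snapshot as dense CSV matrices, one file per field per
#' iteration, named `<prefix>_<field>_iter<t>.csv`. The hydrogen-ion lattice
#' is written both as raw concentration (`h`) and on the pH scale (`ph`).
#'
#' @param sim A `tumor_sim` object run with `snapshot_iters`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_snapshots <- function(sim, dir, prefix = "snapshot") {
  stopifnot(inherits(sim, "tumor_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (t in names(sim$snapshots)) {
    sn <- sim$snapshots[[t]]
    sn$ph <- ph_from_h(pmax(sn$h, 1e-300))
    for (f in names(sn)) {
      path <- file.path(dir, sprintf("%s_%s_iter%s.csv", prefix, f, t))
      utils::write.table(sn[[f]], path, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Write a run manifest
#'
#' Records the full parameter set, seed and iteration count of a run as
#' JSON beside its outputs, for provenance.
#'
#' @param sim A `tumor_sim` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(sim, path) {
  stopifnot(inherits(sim, "tumor_sim"))
  pars <- unclass(sim$params)
  pars$alpha <- as.list(pars$alpha)
  jsonlite::write_json(list(package = "tumorca",
                            seed = sim$seed, n_iter = sim$n_iter,
                            params = pars),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
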