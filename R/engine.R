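# Simulation engine: initialization, the per-iteration update sequence,
# replicate runs and Nmm sweeps.

#' Initialize a simulation
#'
#' Builds the starting configuration: every site holds living normal tissue
#' except a single mutant proliferating tumor cell at the seed site, and all
#' five metabolic fields sit at their uniform medium backgrounds (oxygen
#' `c0`, glucose `g0`, H+ at `pH0`, growth factor 1, inhibitory factor 0),
#' optionally jittered. Boundary conditions are periodic.
#'
#' @param p A validated [tumor_params()] object.
#' @return List with elements `grid` (a `cell_grid`) and `fields`
#'   (a `metabolic_fields`).
#' @examples
#' s <- initialize_simulation(tumor_params(ncell = 11))
#' sum(s$grid$states == 1)   # one seeded PC
#' @export
initialize_simulation <- function(p) {
  grid <- tumor_grid(p$ncell, p$center)
  ci <- p$center[1] + (p$center[2] - 1L) * p$ncell
  grid$states[ci] <- CELL_PC
  grid$mutant[ci] <- TRUE
  fields <- metabolic_fields(p)
  list(grid = grid, fields = fields)
}

#' One full iteration of the automaton
#'
#' Executes, in order: (1) block-CA diffusion of all fields with the
#' metabolic sinks of the current lattice; (2) medium replenishment;
#' (3) necrosis determination from the updated fields; (4) tumor geometry
#' (`Rt`, `Rn`, `Wp`) computed once; (5) quiescent-cell updates against that
#' geometry; (6) proliferating-cell updates — cells under quiescence
#' conditions fall quiescent, the rest attempt mitosis in a freshly
#' shuffled random order.
#'
#' Uses R's global RNG stream; seed it (or use [run_simulation()]) for
#' reproducibility.
#'
#' @param grid A `cell_grid`.
#' @param fields A `metabolic_fields` object.
#' @param p A validated [tumor_params()] object.
#' @param t Iteration index (drives the shifting block partition).
#' @return List with the updated `grid` and `fields`.
#' @export
simulation_step <- function(grid, fields, p, t) {
  fields <- diffusion_step(fields, grid, p, t)
  fields <- replenish_medium(fields, grid, p)
  grid <- apply_necrosis(grid, fields, p)

  states <- grid$states
  mutant <- grid$mutant
  stall <- grid$stall
  geo <- lattice_geometry(p$ncell, grid$center)
  ph <- ph_from_h(pmax(fields$h, 1e-300))

  any_tumor <- any(states > CELL_NORMAL)
  if (any_tumor) {
    gm <- compute_geometry(compute_radius(grid), p)

    # (5) quiescent cells, against start-of-iteration geometry and fields
    qidx <- which(states == CELL_QC)
    if (length(qidx)) {
      r <- geo$dist[qidx]
      ok <- fields$o2[qidx] >= p$O2_thre & fields$gl[qidx] >= p$gl_thre &
        ph[qidx] >= p$pH_thre_q
      to_pc <- r >= gm$Rt - gm$Wp | ok    # recovery overrides position
      to_nec <- !to_pc & r < gm$Rn
      states[qidx[to_nec]] <- CELL_NEC
      states[qidx[to_pc]] <- CELL_PC      # phenotype kept in `mutant`
    }

    # (6) proliferating cells
    pidx <- which(states == CELL_PC)
    if (length(pidx)) {
      verdict <- classify_microenvironment(fields$o2[pidx], fields$gl[pidx],
                                           ph[pidx], p)$verdict
      qtrig <- verdict == "quiescence_trigger"
      states[pidx[qtrig]] <- CELL_QC
      stall[pidx[qtrig]] <- 0L
      live <- pidx[verdict == "proliferation_permitted"]
      if (length(live) > 1L) live <- sample(live)
      nb <- geo$nb
      for (i in live) {
        nbi <- nb[i, ]
        open <- nbi[states[nbi] == CELL_NORMAL]
        n_open <- length(open)
        divided <- FALSE
        if (n_open > 0L) {
          prob <- division_probability(mutant[i], geo$dist[i], n_open, p)
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
      }
    }
  }
  grid$states <- states
  grid$mutant <- mutant
  grid$stall <- stall
  list(grid = grid, fields = fields)
}

record_row <- function(grid, fields, p, t) {
  states <- grid$states
  pc <- states == CELL_PC
  qc <- states == CELL_QC
  nec <- states == CELL_NEC
  n_pc <- sum(pc)
  n_qc <- sum(qc)
  n_nec <- sum(nec)
  n_tumor <- n_pc + n_qc + n_nec
  tumor <- states > CELL_NORMAL
  ph <- ph_from_h(pmax(fields$h, 1e-300))
  if (n_tumor > 0) {
    gm <- compute_geometry(compute_radius(grid), p)
    rt <- gm$Rt; rn <- gm$Rn; wp <- gm$Wp
    gf <- n_pc / n_tumor
    nf <- n_nec / n_tumor
    mo <- mean(fields$o2[tumor]); mg <- mean(fields$gl[tumor])
    mp <- mean(ph[tumor])
  } else {
    rt <- rn <- wp <- gf <- nf <- mo <- mg <- mp <- NA_real_
  }
  c(iter = t, n_pc = n_pc, n_pc_mutant = sum(pc & grid$mutant),
    n_pc_nonmutant = sum(pc & !grid$mutant), n_qc = n_qc, n_nec = n_nec,
    n_tumor = n_tumor, gf = gf, nf = nf, rt = rt, rn = rn, wp = wp,
    mean_o2 = mo, mean_gl = mg, mean_ph = mp,
    min_ph = min(ph))
}

#' Run a tumor-growth simulation
#'
#' Seeds the RNG, initializes the lattice ([initialize_simulation()]) and
#' iterates [simulation_step()], recording population counts, fractions,
#' geometry and mean concentrations at every iteration. Identical `seed` and
#' parameters reproduce the run exactly.
#'
#' @param p A validated [tumor_params()] object.
#' @param n_iter Number of iterations (defaults to `p$n_iter`).
#' @param seed RNG seed (defaults to `p$seed`).
#' @param snapshot_iters Iterations at which to keep lattice snapshots
#'   (states plus all five fields). `0` snapshots the initial state.
#' @return An object of class `tumor_sim`: list with `params`, `seed`,
#'   `record` (data frame, one row per iteration from 0 to `n_iter`),
#'   `snapshots`, and the final `grid` and `fields`.
#' @examples
#' sim <- run_simulation(tumor_params(ncell = 21, n_iter = 5, seed = 7))
#' tail(sim$record, 2)
#' @export
run_simulation <- function(p, n_iter = p$n_iter, seed = p$seed,
                           snapshot_iters = integer(0)) {
  p <- validate_params(p)
  set.seed(seed)
  st <- initialize_simulation(p)
  rec <- matrix(NA_real_, n_iter + 1L, 16L)
  rec[1L, ] <- record_row(st$grid, st$fields, p, 0L)
  snapshots <- list()
  snap <- function(t) {
    snapshots[[as.character(t)]] <<- list(
      states = st$grid$states, o2 = st$fields$o2, gl = st$fields$gl,
      h = st$fields$h, gf = st$fields$gf, if_ = st$fields$if_)
  }
  if (0L %in% snapshot_iters) snap(0L)
  for (t in seq_len(n_iter)) {
    st <- simulation_step(st$grid, st$fields, p, t)
    rec[t + 1L, ] <- record_row(st$grid, st$fields, p, t)
    if (t %in% snapshot_iters) snap(t)
  }
  record <- as.data.frame(rec)
  names(record) <- c("iter", "n_pc", "n_pc_mutant", "n_pc_nonmutant",
                     "n_qc", "n_nec", "n_tumor", "gf", "nf", "rt", "rn",
                     "wp", "mean_o2", "mean_gl", "mean_ph", "min_ph")
  structure(list(params = p, seed = seed, n_iter = n_iter, record = record,
                 snapshots = snapshots, grid = st$grid, fields = st$fields),
            class = "tumor_sim")
}

#' @export
print.tumor_sim <- function(x, ...) {
  fin <- x$record[nrow(x$record), ]
  cat(sprintf("<tumor_sim> %d x %d lattice, %d iterations, seed %d, Nmm %.2f\n",
              x$params$ncell, x$params$ncell, x$n_iter, x$seed,
              x$params$Nmm))
  cat(sprintf("  final counts : PC %d (mutant %d)  QC %d  NeC %d  tumor %d\n",
              as.integer(fin$n_pc), as.integer(fin$n_pc_mutant),
              as.integer(fin$n_qc), as.integer(fin$n_nec),
              as.integer(fin$n_tumor)))
  if (is.finite(fin$gf))
    cat(sprintf("  final state  : GF %.3f  NF %.3f  Rt %.2f  min pH %.2f\n",
                fin$gf, fin$nf, fin$rt, fin$min_ph))
  invisible(x)
}

#' @export
summary.tumor_sim <- function(object, plateau_window = 20L, ...) {
  rec <- object$record
  fin <- rec[nrow(rec), ]
  nec_on <- which(rec$n_nec > 0)
  first_nec <- if (length(nec_on)) rec$iter[nec_on[1]] else NA_integer_
  rt_at_nec <- if (length(nec_on)) rec$rt[nec_on[1]] else NA_real_
  tail_idx <- utils::tail(seq_len(nrow(rec)), plateau_window)
  out <- list(
    final_gf = fin$gf, final_nf = fin$nf,
    final_counts = c(pc = fin$n_pc, qc = fin$n_qc, nec = fin$n_nec),
    pc_plateau = mean(rec$n_pc[tail_idx]),
    critical_point = detect_cp(rec),
    first_necrosis = first_nec,
    rt_at_first_necrosis = rt_at_nec,
    final_rt = fin$rt,
    min_ph = fin$min_ph
  )
  class(out) <- "summary.tumor_sim"
  out
}

#' @export
print.summary.tumor_sim <- function(x, ...) {
  cat("Tumor simulation summary\n")
  cat(sprintf("  growth fraction (final)    : %.3f\n", x$final_gf))
  cat(sprintf("  necrotic fraction (final)  : %.3f\n", x$final_nf))
  cat(sprintf("  PC plateau (tail mean)     : %.1f cells\n", x$pc_plateau))
  cat(sprintf("  critical point (NeC >= PC) : %s\n",
              ifelse(is.na(x$critical_point), "not reached",
                     x$critical_point)))
  cat(sprintf("  first necrosis             : iteration %s at Rt %.2f\n",
              ifelse(is.na(x$first_necrosis), "none", x$first_necrosis),
              x$rt_at_first_necrosis))
  cat(sprintf("  final radius / min pH      : %.2f / %.2f\n",
              x$final_rt, x$min_ph))
  invisible(x)
}

#' @export
plot.tumor_sim <- function(x, which = c("counts", "fractions"), ...) {
  which <- match.arg(which)
  rec <- x$record
  if (which == "counts") {
    graphics::matplot(rec$iter, rec[, c("n_pc", "n_qc", "n_nec", "n_tumor")],
                      type = "l", lty = 1, lwd = 2,
                      col = c("forestgreen", "orange", "gray30", "red3"),
                      xlab = "iteration", ylab = "cells", ...)
    graphics::legend("topleft", c("PC", "QC", "NeC", "tumor"), lty = 1,
                     lwd = 2, col = c("forestgreen", "orange", "gray30",
                                      "red3"), bty = "n")
  } else {
    graphics::matplot(rec$iter, rec[, c("gf", "nf")], type = "l", lty = 1,
                      lwd = 2, col = c("forestgreen", "gray30"),
                      xlab = "iteration", ylab = "fraction",
                      ylim = c(0, 1), ...)
    graphics::legend("left", c("GF", "NF"), lty = 1, lwd = 2,
                     col = c("forestgreen", "gray30"), bty = "n")
  }
  invisible(x)
}

#' Replicate experiment under the default conditions
#'
#' Runs the same parameter set under several seeds and summarizes the
#' end-state metrics per replicate.
#'
#' @param p A validated [tumor_params()] object.
#' @param seeds Integer vector of replicate RNG seeds.
#' @param n_iter Iterations per replicate.
#' @param plateau_window Tail window (iterations) for the PC plateau mean.
#' @return Data frame with one row per replicate: final GF/NF, PC plateau,
#'   critical point, first-necrosis iteration and radius, final radius,
#'   lattice minimum pH.
#' @export
run_replicates <- function(p, seeds, n_iter = p$n_iter,
                           plateau_window = 20L) {
  rows <- lapply(seeds, function(s) {
    sm <- summary(run_simulation(p, n_iter = n_iter, seed = s),
                  plateau_window = plateau_window)
    data.frame(seed = s, final_gf = sm$final_gf, final_nf = sm$final_nf,
               pc_plateau = sm$pc_plateau,
               critical_point = sm$critical_point,
               first_necrosis = sm$first_necrosis,
               rt_at_first_necrosis = sm$rt_at_first_necrosis,
               final_rt = sm$final_rt, min_ph = sm$min_ph)
  })
  do.call(rbind, rows)
}

#' Sweep the phenotype-switching probability Nmm
#'
#' Runs the simulator across a grid of `Nmm` values with paired seeds and
#' collects end-state metrics, pH-layer occupancies, and difference lattices
#' (oxygen and pH) against the matching `Nmm = 0` run with the same seed.
#'
#' @param p A validated [tumor_params()] object.
#' @param nmm_grid Numeric vector of Nmm values in `[0, 1]`.
#' @param seeds Integer vector of replicate seeds (paired across Nmm
#'   values).
#' @param n_iter Iterations per run.
#' @param bins A [layer_bins()] object.
#' @return An object of class `nmm_sweep`: list with `summary` (one row per
#'   Nmm: replicate-mean final counts, GF, NF, radius, raw `Rt^3` volume,
#'   pH-layer and oxygen-difference-layer occupancies) and `diff` (per Nmm,
#'   seed-averaged difference lattices `o2` and `ph` against Nmm = 0).
#' @export
sweep_nmm <- function(p, nmm_grid = seq(0, 1, by = 0.1), seeds = p$seed,
                      n_iter = p$n_iter, bins = layer_bins()) {
  if (any(nmm_grid < 0 | nmm_grid > 1)) stop("nmm_grid values must be in [0, 1]")
  if (!length(seeds)) stop("at least one replicate seed is required")
  base <- lapply(seeds, function(s) {
    sim <- run_simulation(tumor_params_set(p, Nmm = 0), n_iter = n_iter,
                          seed = s)
    list(o2 = sim$fields$o2, ph = ph_from_h(pmax(sim$fields$h, 1e-300)),
         sim = sim)
  })
  rows <- list()
  diffs <- list()
  for (nmm in nmm_grid) {
    acc <- NULL
    d_o2 <- d_ph <- 0
    for (k in seq_along(seeds)) {
      sim <- if (nmm == 0) base[[k]]$sim else
        run_simulation(tumor_params_set(p, Nmm = nmm), n_iter = n_iter,
                       seed = seeds[k])
      fin <- sim$record[nrow(sim$record), ]
      ph <- ph_from_h(pmax(sim$fields$h, 1e-300))
      ph_occ <- stratify_layers(ph, bins$ph_bins)
      do2 <- sim$fields$o2 - base[[k]]$o2
      ox_occ <- stratify_layers(do2, bins$ox_bins)
      row <- c(n_pc = fin$n_pc, n_pc_nonmutant = fin$n_pc_nonmutant,
               n_qc = fin$n_qc, n_nec = fin$n_nec, n_tumor = fin$n_tumor,
               gf = fin$gf, nf = fin$nf, rt = fin$rt,
               volume = fin$rt^3, min_ph = fin$min_ph,
               stats::setNames(ph_occ, paste0("ph", seq_along(ph_occ))),
               stats::setNames(ox_occ, paste0("ox", seq_along(ox_occ))))
      acc <- rbind(acc, row)
      d_o2 <- d_o2 + do2 / length(seeds)
      d_ph <- d_ph + (ph - base[[k]]$ph) / length(seeds)
    }
    rows[[length(rows) + 1L]] <- c(nmm = nmm, colMeans(acc))
    diffs[[sprintf("%.3g", nmm)]] <- list(o2 = d_o2, ph = d_ph)
  }
  structure(list(summary = as.data.frame(do.call(rbind, rows)),
                 diff = diffs, seeds = seeds, n_iter = n_iter),
            class = "nmm_sweep")
}

#' @export
print.nmm_sweep <- function(x, ...) {
  cat(sprintf("<nmm_sweep> %d Nmm values x %d seed(s), %d iterations\n",
              nrow(x$summary), length(x$seeds), x$n_iter))
  print(x$summary[, c("nmm", "n_pc", "n_pc_nonmutant", "n_nec", "n_tumor",
                      "gf", "nf", "rt")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Modify fields of a parameter set
#'
#' Convenience helper returning a revalidated copy of `p` with the supplied
#' fields replaced. Derived fields (`alpha`, necrosis thresholds) are
#' recomputed unless given explicitly.
#'
#' @param p A `tumor_params` object.
#' @param ... Named fields to replace.
#' @return A validated `tumor_params` object.
#' @examples
#' p <- tumor_params()
#' tumor_params_set(p, Nmm = 0.5)$Nmm
#' @export
tumor_params_set <- function(p, ...) {
  new <- list(...)
  drv <- intersect(c("alpha", "O2_thre2", "gl_thre2"), names(new))
  for (f in names(new)) p[[f]] <- new[[f]]
  if (!"alpha" %in% drv && any(names(new) %in%
        c("D_o2", "D_gl", "D_H", "D_Gf", "D_If", "alpha_max", "alpha_gamma")))
    p$alpha <- NULL
  if (!"O2_thre2" %in% drv && "O2_thre" %in% names(new)) p$O2_thre2 <- NULL
  if (!"gl_thre2" %in% drv && "gl_thre" %in% names(new)) p$gl_thre2 <- NULL
  validate_params(p)
}
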