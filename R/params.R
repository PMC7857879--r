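#' Model parameters for the tumor cellular automaton
#'
#' Builds the complete, validated parameter set of the simulator: the
#' microenvironmental response thresholds, diffusion coefficients and their
#' derived block-mixing weights, per-cell metabolic rates, the stochastic
#' mitosis constants, medium background concentrations, and run controls.
#' Defaults reproduce the reference avascular-growth experiment
#' (a single mutant proliferating cell seeded at the center of a 101 x 101
#' lattice, 200 iterations of 0.1 days each).
#'
#' @details
#' Cell states are coded 0 (normal tissue or empty space), 1 (proliferating
#' tumor cell, PC), 2 (quiescent tumor cell, QC) and 3 (necrotic cell, NeC).
#'
#' The response thresholds act in mMol for oxygen and glucose and on the pH
#' scale for acidity: a tumor cell falls quiescent below `O2_thre`, `gl_thre`
#' or `pH_thre_q`, and dies below `O2_thre2` (= `O2_thre/2`), `gl_thre2`
#' (= `gl_thre/2`) or `pH_thre_Ne`.
#'
#' The physical diffusion coefficients `D_*` (cm^2/s) set the per-field
#' block-mixing weights `alpha` of the block-cellular-automata transport
#' scheme through `alpha_i = alpha_max * (D_i / max(D))^alpha_gamma`,
#' preserving the monotone relation between diffusivity and mixing strength.
#' All five weights can be overridden directly via `alpha`.
#'
#' The laboratory rates `Cr_o2`, `Cr_gl`, `Cr_H` (Mol per cell per second)
#' are converted to per-site per-iteration concentration increments by
#' `rate_scale`; the hydrogen-ion increment is additionally damped by
#' `h_scale`, representing tissue pH buffering (free-proton accumulation is
#' a small fraction of the acid load produced). `gf_scale` plays the same
#' role for the dimensionless growth/inhibitory-factor fields, whose rates
#' are given in different units (cm^3/h). Growth and inhibitory factors are
#' carried and diffused but gate no transition rule.
#'
#' @param ncell Lattice side length (sites). The tumor is seeded at `center`
#'   (defaults to the central site).
#' @param center Integer length-2 (row, column) seed coordinate, 1-based.
#' @param pH_thre_q,pH_thre_Ne pH thresholds for quiescence and necrosis.
#' @param O2_thre,gl_thre Oxygen / glucose quiescence thresholds (mMol).
#' @param O2_thre2,gl_thre2 Necrosis thresholds; default to half the
#'   quiescence thresholds.
#' @param D_o2,D_gl,D_H,D_Gf,D_If Diffusion coefficients (cm^2/s).
#' @param alpha_max Mixing weight assigned to the fastest-diffusing field.
#' @param alpha_gamma Compression exponent of the diffusivity ratio in the
#'   mixing-weight derivation `alpha_i = alpha_max * (D_i / max(D))^alpha_gamma`
#'   (1 = proportional weights; smaller values compress the spread while
#'   keeping the ordering).
#' @param alpha Optional named numeric vector `c(o2=, gl=, h=, gf=, if_=)`
#'   overriding the derived mixing weights; each entry must lie in (0, 1).
#' @param Cr_o2,Cr_gl,Cr_H Base consumption/production rates (Mol/cell/s).
#' @param Cr_Gf,Cr_If Growth/inhibitory factor rates (cm^3/h).
#' @param rate_scale Conversion from Mol/cell/s to mMol per site per
#'   iteration.
#' @param h_scale Additional buffering factor applied to the H+ increment.
#' @param gf_scale Per-iteration fractional rate scale for the Gf/If fields.
#' @param modulation_normal Metabolic modulation of living normal cells
#'   relative to a proliferating tumor cell (oxygen and glucose only).
#' @param quiescent_factor Metabolic modulation of quiescent tumor cells.
#' @param k_gl_anaerobic,k_H_anaerobic,k_o2_anaerobic Multipliers applied to
#'   glucose uptake, H+ production and oxygen uptake when a tumor cell's
#'   local oxygen falls below `O2_thre` (anaerobic glycolysis).
#' @param p0 Base division probability of a mutant proliferating cell.
#' @param phi0 Base division probability of a nonmutant proliferating cell.
#' @param a,b Geometry constants of the multicellular-layer relation
#'   `Wp = b * Rt^(2/3)`, `Rn = Rt - (a + Wp)`.
#' @param Rmax Maximum tumor radius (lattice units); division probability is
#'   zero at and beyond this radius.
#' @param Nmm Probability that the daughter of a mutant proliferating cell is
#'   nonmutant.
#' @param stall_limit Number of consecutive failed mitosis attempts after
#'   which a proliferating cell falls quiescent.
#' @param c0,g0 Background oxygen / glucose concentrations (mMol).
#' @param pH0 Background medium pH.
#' @param Gf0,If0 Background growth/inhibitory factor levels.
#' @param medium_floor_frac Medium sites are replenished so that oxygen and
#'   glucose never drop below this fraction of background and H+ never rises
#'   above background divided by it.
#' @param replenish_mode `"all"` replenishes every normal/empty site (the
#'   vasculature perfuses the whole host tissue); `"boundary"` only the
#'   outermost lattice ring.
#' @param normal_death `"empty"`: normal cells under lethal conditions leave
#'   empty space (apoptosis); `"necrotic"`: they join the necrotic count.
#' @param init_jitter Half-width of a uniform multiplicative perturbation
#'   applied to the initial concentration lattices (0 = exactly uniform
#'   backgrounds).
#' @param n_iter Default number of iterations for [run_simulation()].
#' @param seed Default RNG seed.
#' @param dt_days Real time represented by one iteration (days).
#'
#' @return A validated object of class `tumor_params` (a named list with the
#'   derived fields `O2_thre2`, `gl_thre2` and `alpha` filled in).
#' @seealso [validate_params()], [read_params()], [write_params()],
#'   [run_simulation()]
#' @examples
#' p <- tumor_params(ncell = 33, n_iter = 10)
#' p$O2_thre2   # half the quiescence threshold
#' p$alpha[["gl"]]
#' @export
tumor_params <- function(ncell = 101,
                         center = NULL,
                         pH_thre_q = 6.4,
                         pH_thre_Ne = 6.0,
                         O2_thre = 0.02,
                         gl_thre = 0.06,
                         O2_thre2 = NULL,
                         gl_thre2 = NULL,
                         D_o2 = 1.82e-5,
                         D_gl = 9.1e-5,
                         D_H = 1.1e-5,
                         D_Gf = 1e-6 / 3600,
                         D_If = 1e-6 / 3600,
                         alpha_max = 0.9,
                         alpha_gamma = 0.05,
                         alpha = NULL,
                         Cr_o2 = 2.3e-16,
                         Cr_gl = 3.8e-17,
                         Cr_H = 1.5e-18,
                         Cr_Gf = 0.5,
                         Cr_If = 1,
                         rate_scale = 1.55e14,
                         h_scale = 3e-6,
                         gf_scale = 1e-3,
                         modulation_normal = 0.5,
                         quiescent_factor = 0.2,
                         k_gl_anaerobic = 5,
                         k_H_anaerobic = 2,
                         k_o2_anaerobic = 0.1,
                         p0 = 0.7,
                         phi0 = 0.6,
                         a = 0.42,
                         b = 0.11,
                         Rmax = 37.5,
                         Nmm = 0.2,
                         stall_limit = 3,
                         c0 = 0.8,
                         g0 = 5.5,
                         pH0 = 7.4,
                         Gf0 = 1,
                         If0 = 0,
                         medium_floor_frac = 0.95,
                         replenish_mode = c("all", "boundary"),
                         normal_death = c("empty", "necrotic"),
                         init_jitter = 0,
                         n_iter = 200,
                         seed = 1L,
                         dt_days = 0.1) {
  replenish_mode <- match.arg(replenish_mode)
  normal_death <- match.arg(normal_death)
  if (is.null(center)) center <- rep((ncell + 1L) %/% 2L, 2L)
  p <- list(
    ncell = as.integer(ncell), center = as.integer(center),
    pH_thre_q = pH_thre_q, pH_thre_Ne = pH_thre_Ne,
    O2_thre = O2_thre, gl_thre = gl_thre,
    O2_thre2 = O2_thre2, gl_thre2 = gl_thre2,
    D_o2 = D_o2, D_gl = D_gl, D_H = D_H, D_Gf = D_Gf, D_If = D_If,
    alpha_max = alpha_max, alpha_gamma = alpha_gamma, alpha = alpha,
    Cr_o2 = Cr_o2, Cr_gl = Cr_gl, Cr_H = Cr_H, Cr_Gf = Cr_Gf, Cr_If = Cr_If,
    rate_scale = rate_scale, h_scale = h_scale, gf_scale = gf_scale,
    modulation_normal = modulation_normal,
    quiescent_factor = quiescent_factor,
    k_gl_anaerobic = k_gl_anaerobic, k_H_anaerobic = k_H_anaerobic,
    k_o2_anaerobic = k_o2_anaerobic,
    p0 = p0, phi0 = phi0, a = a, b = b, Rmax = Rmax, Nmm = Nmm,
    stall_limit = as.integer(stall_limit),
    c0 = c0, g0 = g0, pH0 = pH0, Gf0 = Gf0, If0 = If0,
    medium_floor_frac = medium_floor_frac,
    replenish_mode = replenish_mode, normal_death = normal_death,
    init_jitter = init_jitter,
    n_iter = as.integer(n_iter), seed = as.integer(seed), dt_days = dt_days
  )
  class(p) <- "tumor_params"
  validate_params(p)
}

#' Validate a parameter set and fill derived fields
#'
#' Checks every invariant of the parameter container (ranges, signs, lattice
#' consistency) and fills the derived fields: the necrosis thresholds
#' `O2_thre2`/`gl_thre2` (half the quiescence thresholds unless explicitly
#' overridden) and the per-field mixing weights `alpha`.
#'
#' @param p A `tumor_params` object (possibly with `NULL` derived fields).
#' @return The completed `tumor_params` object.
#' @examples
#' p <- tumor_params(ncell = 33)
#' identical(validate_params(p), p)
#' @export
validate_params <- function(p) {
  if (!inherits(p, "tumor_params")) stop("`p` must be a 'tumor_params' object")
  if (is.null(p$O2_thre2)) p$O2_thre2 <- p$O2_thre / 2
  if (is.null(p$gl_thre2)) p$gl_thre2 <- p$gl_thre / 2
  dvec <- c(o2 = p$D_o2, gl = p$D_gl, h = p$D_H, gf = p$D_Gf, if_ = p$D_If)
  if (is.null(p$alpha)) {
    p$alpha <- p$alpha_max * (dvec / max(dvec))^p$alpha_gamma
  } else {
    p$alpha <- p$alpha[c("o2", "gl", "h", "gf", "if_")]
  }

  bad <- character(0)
  chk <- function(ok, field) if (!isTRUE(all(ok))) bad <<- c(bad, field)

  chk(p$ncell >= 3, "ncell")
  chk(length(p$center) == 2 && all(p$center >= 1) && all(p$center <= p$ncell),
      "center")
  for (f in c("pH_thre_q", "pH_thre_Ne", "O2_thre", "gl_thre", "O2_thre2",
              "gl_thre2", "Cr_o2", "Cr_gl", "Cr_H", "Cr_Gf", "Cr_If",
              "rate_scale", "h_scale", "gf_scale", "a", "b", "Rmax", "c0",
              "g0", "pH0", "Gf0", "dt_days", "k_gl_anaerobic",
              "k_H_anaerobic"))
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 && p[[f]] >= 0, f)
  for (f in c("p0", "phi0", "Nmm", "k_o2_anaerobic", "If0"))
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 &&
          p[[f]] >= 0 && p[[f]] <= 1, f)
  for (f in c("quiescent_factor", "medium_floor_frac"))
    chk(p[[f]] > 0 && p[[f]] <= 1, f)
  chk(p$k_gl_anaerobic >= 1, "k_gl_anaerobic")
  chk(p$k_H_anaerobic >= 1, "k_H_anaerobic")
  chk(all(dvec > 0), "D_o2/D_gl/D_H/D_Gf/D_If")
  chk(length(p$alpha) == 5 && !anyNA(p$alpha) &&
        all(p$alpha > 0) && all(p$alpha < 1), "alpha")
  chk(p$alpha_gamma > 0 && p$alpha_gamma <= 1, "alpha_gamma")
  chk(p$stall_limit >= 1, "stall_limit")
  chk(p$n_iter >= 0, "n_iter")
  chk(p$init_jitter >= 0 && p$init_jitter < 1, "init_jitter")
  if (length(bad))
    stop("invalid parameter value(s): ", paste(unique(bad), collapse = ", "))
  p
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("<tumor_params>\n")
  cat(sprintf("  lattice      : %d x %d, seed site (%d, %d)\n",
              x$ncell, x$ncell, x$center[1], x$center[2]))
  cat(sprintf("  thresholds   : O2 %.3g/%.3g  gl %.3g/%.3g  pH %.2f/%.2f\n",
              x$O2_thre, x$O2_thre2, x$gl_thre, x$gl_thre2,
              x$pH_thre_q, x$pH_thre_Ne))
  cat(sprintf("  mixing alpha : %s\n",
              paste(sprintf("%s=%.3g", names(x$alpha), x$alpha),
                    collapse = " ")))
  cat(sprintf("  mitosis      : p0 %.2f  phi0 %.2f  Rmax %.1f  Nmm %.2f  stall %d\n",
              x$p0, x$phi0, x$Rmax, x$Nmm, x$stall_limit))
  cat(sprintf("  medium       : O2 %.2f mMol  gl %.2f mMol  pH %.1f\n",
              x$c0, x$g0, x$pH0))
  cat(sprintf("  run          : %d iterations of %.1f days, seed %d\n",
              x$n_iter, x$dt_days, x$seed))
  invisible(x)
}

#' pH from hydrogen-ion concentration (and back)
#'
#' `ph_from_h()` converts a hydrogen-ion concentration (mol/L scale) to pH,
#' `h_from_ph()` is its exact inverse.
#'
#' @param h Positive hydrogen-ion concentration(s).
#' @param ph pH value(s).
#' @return Numeric vector of pH values / concentrations.
#' @examples
#' ph_from_h(1e-7)          # 7
#' h_from_ph(7.4)           # background medium acidity
#' ph_from_h(h_from_ph(6.4))
#' @export
ph_from_h <- function(h) {
  if (any(!is.finite(h)) || any(h <= 0))
    stop("hydrogen-ion concentration must be strictly positive")
  -log10(h)
}

#' @rdname ph_from_h
#' @export
h_from_ph <- function(ph) 10^(-ph)

#' Read / write a parameter configuration file
#'
#' Parameter sets round-trip through a plain YAML file, one key per field.
#' `read_params()` applies [tumor_params()] defaults for absent keys and
#' validates the result.
#'
#' @param path File path of the YAML configuration.
#' @param p A `tumor_params` object.
#' @return `read_params()` a validated `tumor_params`; `write_params()` the
#'   path, invisibly.
#' @examples
#' cfg <- file.path(tempdir(), "params.yaml")
#' write_params(tumor_params(ncell = 33, Nmm = 0.5), cfg)
#' read_params(cfg)$Nmm
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(tumor_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$alpha)) vals$alpha <- unlist(vals$alpha)
  do.call(tumor_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "tumor_params"))
  vals <- unclass(p)
  vals$alpha <- as.list(vals$alpha)
  yaml::write_yaml(vals, path, precision = 15L)
  invisible(path)
}
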