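#' Sinusoidal breathing waveform
#'
#' `Q(t) = Q_max * sin(2 pi t / T)`: the heavy-breathing approximation of a
#' respiratory cycle. The cycle mean of `|Q|` is `2 Q_max / pi` (about
#' 63.7 L/min at the default peak of 100 L/min).
#' @param Q_max peak flow in L/min.
#' @param T_s period in seconds.
#' @export
breathing_pattern <- function(Q_max = 100, T_s = 2) {
  if (Q_max <= 0 || T_s <= 0) stop("Q_max and T_s must be positive")
  structure(list(Q_max = Q_max, T_s = T_s), class = "breathing_pattern")
}

#' @rdname breathing_pattern
#' @param t time(s) in seconds.
#' @param bp a [breathing_pattern()].
#' @return `flow_waveform`: instantaneous flow in L/min;
#'   `mean_abs_flow`: cycle mean of `|Q|` in L/min.
#' @export
flow_waveform <- function(t, bp = breathing_pattern()) {
  bp$Q_max * sin(2 * pi * t / bp$T_s)
}

#' @rdname breathing_pattern
#' @param n_quad quadrature points for the numeric cycle mean.
#' @export
mean_abs_flow <- function(bp = breathing_pattern(), n_quad = 100000L) {
  tt <- seq(0, bp$T_s, length.out = n_quad + 1L)[-1L]
  mean(abs(flow_waveform(tt, bp)))
}

#' Inlet velocity magnitude from flow rate and area
#'
#' `||u|| = Q / A` with unit conversion (L/min to m^3/s, mm^2 to m^2).
#' @param Q_lpm flow in L/min.
#' @param A_mm2 inlet area in mm^2.
#' @return velocity in m/s.
#' @export
inlet_velocity <- function(Q_lpm, A_mm2) {
  if (any(A_mm2 <= 0)) stop("inlet area must be positive")
  (Q_lpm / 1000 / 60) / (A_mm2 * 1e-6)
}

#' Transition-model turbulence boundary conditions
#'
#' Isotropic-turbulence inlet values for the k-omega SST transition
#' (Langtry-Menter) model: `k = 1.5 I^2 u_ref^2` with turbulence intensity
#' `I` (default 4 percent), `omega = sqrt(k) / (C_mu^0.25 L)` with
#' `C_mu = 0.09` and `L` the inlet hydraulic diameter, intermittency
#' `gamma = 1`, and the transition momentum-thickness Reynolds number
#' correlation in `Tu` percent:
#' `Re_theta = 1173.51 - 589.428 Tu + 0.2196 / Tu^2` for `Tu <= 1.3`, else
#' `331.5 (Tu - 0.5658)^-0.671`. `Tu` is floored at 0.027 to guard the
#' `1/Tu^2` term.
#'
#' @param u_ref reference (peak inlet) velocity, m/s.
#' @param I turbulence intensity as a fraction (0.04 = 4 percent).
#' @param L length scale in m (inlet hydraulic diameter).
#' @param C_mu turbulence model constant.
#' @return a `turbulence_bc` list with `k`, `omega`, `gamma`, `Tu`
#'   (percent), `Re_theta`, and the inputs.
#' @export
turbulence_bcs <- function(u_ref, I = 0.04, L, C_mu = 0.09) {
  if (u_ref <= 0 || L <= 0) stop("u_ref and L must be positive")
  k <- 1.5 * I^2 * u_ref^2
  omega <- sqrt(k) / (C_mu^0.25 * L)
  Tu <- 100 * sqrt(2 / 3 * k) / u_ref
  structure(list(u_ref = u_ref, I = I, L = L, C_mu = C_mu,
                 k = k, omega = omega, gamma = 1, Tu = Tu,
                 Re_theta = re_theta(Tu)),
            class = "turbulence_bc")
}

#' @rdname turbulence_bcs
#' @param Tu turbulence intensity in percent.
#' @export
re_theta <- function(Tu) {
  Tu <- pmax(Tu, 0.027)
  ifelse(Tu <= 1.3,
         1173.51 - 589.428 * Tu + 0.2196 / Tu^2,
         331.5 * (Tu - 0.5658)^(-0.671))
}

#' Cunningham slip correction
#'
#' `C_c = 1 + Kn (1.257 + 0.4 exp(-1.1 / Kn))` with Knudsen number
#' `Kn = 2 lambda / d`; the Stokes drag of submicron particles is divided
#' by `C_c`.
#' @param d particle diameter (m).
#' @param mfp gas mean free path (m), default 68 nm (air at ambient
#'   conditions).
#' @return list with `Kn`, `C_c` and the slip-corrected Stokes drag factor
#'   `3 pi eta d / C_c` per unit viscosity (`drag_per_eta`).
#' @export
cunningham_slip <- function(d, mfp = 68e-9) {
  if (any(d <= 0) || mfp <= 0) stop("d and mfp must be positive")
  Kn <- 2 * mfp / d
  C_c <- 1 + Kn * (1.257 + 0.4 * exp(-1.1 / Kn))
  list(Kn = Kn, C_c = C_c, drag_per_eta = 3 * pi * d / C_c)
}

#' Particle force parameters
#'
#' @param d particle diameter (m).
#' @param rho_p particle density (kg/m^3).
#' @param rho_f fluid density (kg/m^3); default 1.177 (air at 300 K).
#' @param T_o fluid temperature (K).
#' @param eta dynamic viscosity (Pa s); default air.
#' @param dt time step (s).
#' @param mfp mean free path (m).
#' @param alpha_p particle volume fraction (near 0).
#' @export
particle_force_params <- function(d, rho_p = 1000, rho_f = 1.177,
                                  T_o = 300, eta = 1.846e-5, dt = 1e-4,
                                  mfp = 68e-9, alpha_p = 0) {
  vals <- c(d = d, rho_p = rho_p, rho_f = rho_f, T_o = T_o, eta = eta,
            dt = dt, mfp = mfp)
  if (any(vals <= 0)) stop("all physical parameters must be positive")
  if (alpha_p < 0 || alpha_p > 0.01) stop("alpha_p must be near zero")
  structure(as.list(c(vals, alpha_p = alpha_p)),
            class = "particle_force_params")
}

#' Brownian force sample
#'
#' `F = xi * sqrt(2 k_b T_o / (alpha dt))` per component, with standard
#' normal `xi` and the particle mobility `alpha = 1 / (3 pi eta d)` from
#' the Einstein relation `D = k_b T / (3 pi eta d)`, `alpha = D / (k_b T)`.
#' @param p a [particle_force_params()].
#' @param n number of 3-vector samples.
#' @param seed RNG seed for reproducibility (`NULL` leaves the RNG state).
#' @param xi optional fixed noise matrix (n x 3) overriding the RNG.
#' @return n x 3 matrix of forces (N).
#' @export
brownian_force <- function(p, n = 1L, seed = NULL, xi = NULL) {
  stopifnot(inherits(p, "particle_force_params"))
  if (p$dt <= 0) stop("time step must be positive")
  kb <- 1.380649e-23
  alpha <- 1 / (3 * pi * p$eta * p$d)
  amp <- sqrt(2 * kb * p$T_o / (alpha * p$dt))
  if (is.null(xi)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    xi <- matrix(rnorm(3 * n), n, 3)
  }
  xi * amp
}

#' Drag force in the slip-corrected Stokes regime
#'
#' `F_d = 0.5 C_d rho A_p ||v_s|| v_s` with `C_d = 24 / (Re_p C_c)`,
#' `Re_p = rho ||v_s|| d / eta`, `A_p = pi d^2 / 4`; algebraically equal to
#' `3 pi eta d v_s / C_c`.
#' @param p a [particle_force_params()].
#' @param v_s slip velocity 3-vector (m/s), `u - v_p`.
#' @return force 3-vector (N).
#' @export
drag_force <- function(p, v_s) {
  stopifnot(inherits(p, "particle_force_params"))
  v_s <- as.numeric(v_s)
  vmag <- sqrt(sum(v_s^2))
  if (vmag == 0) return(c(0, 0, 0))
  C_c <- cunningham_slip(p$d, p$mfp)$C_c
  Re_p <- p$rho_f * vmag * p$d / p$eta
  C_d <- 24 / (Re_p * C_c)
  A_p <- pi * p$d^2 / 4
  0.5 * C_d * p$rho_f * A_p * vmag * v_s
}

# Non-default hexahedral meshing parameters shipped as pass-through
# configuration text (not consumed by this package).
snappy_defaults <- function() {
  list(addLayers = TRUE,
       castellatedMeshControls = list(maxLoadUnbalance = 0.10,
                                      nCellsBetweenLevels = 3),
       featureRefinementLevel = 4,
       outletRefinementLevel = c(2, 5),
       volumeRefinementLevel = c(4, 10),
       refinementMode = "distance",
       refinementLevels = list(c(0.0006, 4), c(0.002, 3), c(0.01, 2)),
       resolveFeatureAngle = 10,
       allowFreeStandingZoneFaces = TRUE,
       snapControls = list(nSmoothPatch = 3, tolerance = 4.0,
                           nSolveIter = 400, nRelaxIter = 5,
                           nFeatureSnapIter = 150, explicitFeatureSnap = TRUE),
       layerControls = list(nSurfaceLayers = 6, expansionRatio = 1.3,
                            finalLayerThickness = 0.6, minThickness = 0.3,
                            featureAngle = 80, nRelaxIter = 50,
                            nSmoothSurfaceNormals = 5, nSmoothNormals = 6,
                            nLayerIter = 200))
}

#' Emit a solver-agnostic CFD case description
#'
#' Collects the boundary conditions per patch (no-slip walls, waveform
#' inlet, fixed-pressure outlets with zero-gradient turbulence), the
#' breathing waveform, turbulence inlet values, and the particle
#' specification (at least 100,000 particles, stick-on-contact walls) into
#' one JSON-serializable case bundle; optionally renders OpenFOAM-style
#' field dictionaries as text.
#'
#' @param geom a [capped_geometry()] with exactly one inlet.
#' @param bp a [breathing_pattern()].
#' @param I turbulence intensity fraction.
#' @param n_particles particle count (default 100000).
#' @param particle a [particle_force_params()] or NULL.
#' @param outlet_pressure outlet gauge pressure (Pa).
#' @param dialect `"json"` or `"openfoam"` (adds text dictionaries).
#' @return a `cfd_case` list; write with [write_case_json()].
#' @export
emit_case <- function(geom, bp = breathing_pattern(), I = 0.04,
                      n_particles = 100000L, particle = NULL,
                      outlet_pressure = 0, dialect = c("json", "openfoam")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(geom, "capped_geometry"))
  pt <- geom$patches
  if (sum(pt$inlet) != 1L) stop("case requires exactly one inlet patch")
  A_in <- pt$area_mm2[pt$inlet]
  u_ref <- inlet_velocity(bp$Q_max, A_in)
  d_h <- 2 * sqrt(A_in / pi) * 1e-3 # hydraulic diameter of the inlet, m
  turb <- turbulence_bcs(u_ref, I = I, L = d_h)
  wall_area <- sum(face_areas(geom$mesh)[geom$mesh$labels == "wall"])
  patches <- lapply(seq_len(nrow(pt)), function(i) {
    if (pt$inlet[i])
      list(name = pt$label[i], type = "inlet",
           u = "waveform Q(t)=Qmax*sin(2*pi*t/T) / A",
           p = "zeroGradient", k = turb$k, omega = turb$omega,
           gamma = 1, Re_theta = turb$Re_theta)
    else if (grepl("^outlet", pt$label[i]))
      list(name = pt$label[i], type = "outlet", u = "zeroGradient",
           p = outlet_pressure, k = "zeroGradient",
           omega = "zeroGradient", gamma = "zeroGradient",
           Re_theta = "zeroGradient")
    else
      list(name = pt$label[i], type = "wall", u = "noSlip",
           p = "zeroGradient", k = "kLowReWallFunction",
           omega = "omegaWallFunction")
  })
  patches <- c(patches, list(list(
    name = "wall", type = "wall", area_mm2 = wall_area, u = "noSlip",
    p = "zeroGradient", k = "kLowReWallFunction",
    omega = "omegaWallFunction", gamma = "zeroGradient",
    Re_theta = "zeroGradient")))
  case <- structure(list(
    patches = patches,
    waveform = list(Q_max_lpm = bp$Q_max, period_s = bp$T_s,
                    mean_abs_lpm = 2 * bp$Q_max / pi),
    turbulence = list(model = "kOmegaSSTLM", u_ref = u_ref,
                      I = I, k = turb$k, omega = turb$omega,
                      gamma = 1, Tu_pct = turb$Tu,
                      Re_theta = turb$Re_theta, C_mu = turb$C_mu,
                      L_m = d_h),
    particles = list(n = max(as.integer(n_particles), 100000L),
                     wall_mode = "stick",
                     params = if (!is.null(particle))
                       unclass(particle) else NULL),
    mesh_defaults = snappy_defaults(),
    dialect = dialect), class = "cfd_case")
  if (dialect == "openfoam") case$dictionaries <- render_openfoam(case)
  case
}

render_openfoam <- function(case) {
  fld <- function(name, internal, patch_lines) paste0(
    "FoamFile { version 2.0; format ascii; class volScalarField; object ",
    name, "; }\n",
    "internalField uniform ", internal, ";\nboundaryField {\n",
    paste(patch_lines, collapse = "\n"), "\n}\n")
  pl <- function(field) vapply(case$patches, function(p) {
    v <- p[[field]]
    spec <- if (is.character(v)) paste0("type ", v, ";")
    else paste0("type fixedValue; value uniform ", format(v), ";")
    paste0("  ", p$name, " { ", spec, " }")
  }, "")
  list(k = fld("k", case$turbulence$k, pl("k")),
       omega = fld("omega", case$turbulence$omega, pl("omega")),
       p = fld("p", 0, pl("p")),
       gammaInt = fld("gammaInt", 1, pl("gamma")),
       ReThetat = fld("ReThetat", case$turbulence$Re_theta, pl("Re_theta")))
}

#' @rdname emit_case
#' @param case a `cfd_case`.
#' @param path output path.
#' @export
write_case_json <- function(case, path) {
  jsonlite::write_json(unclass(case), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname emit_case
#' @export
read_case_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "cfd_case")
}
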