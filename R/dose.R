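#' ICRP-corrected deposition fraction
#'
#' `nDF = (nStick + nScape * ICRPcorrection) / nTotal`: particles that
#' stuck to the resolved airway walls plus the fraction of escaping
#' particles expected to deposit in the unresolved distal airways.
#' @param n_stick particles deposited on resolved walls.
#' @param n_scape particles that escaped the resolved geometry.
#' @param n_total total simulated particles.
#' @param icrp_correction correction factor in \[0, 1\].
#' @return deposition fraction in \[0, 1\].
#' @export
deposition_fraction <- function(n_stick, n_scape, n_total, icrp_correction) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_stick + n_scape > n_total) stop("n_stick + n_scape exceeds n_total")
  if (icrp_correction < 0 || icrp_correction > 1)
    stop("icrp_correction must lie in [0, 1]")
  (n_stick + n_scape * icrp_correction) / n_total
}

#' Deposition records
#'
#' Per-particle position (mm), diameter (m), volume (m^3) and fate.
#' @param position n x 3 matrix (mm).
#' @param diameter particle diameters (m); volume defaults to
#'   `pi d^3 / 6`.
#' @param fate character, `"stuck"` or `"escaped"`.
#' @param volume optional explicit volumes (m^3).
#' @export
deposition_records <- function(position, diameter = NULL, fate = "stuck",
                               volume = NULL) {
  position <- as.matrix(position)
  n <- nrow(position)
  if (any(!is.finite(position))) stop("positions must be finite")
  fate <- rep(fate, length.out = n)
  if (!all(fate %in% c("stuck", "escaped"))) stop("fate must be stuck/escaped")
  if (is.null(volume)) {
    if (is.null(diameter)) stop("either diameter or volume is required")
    volume <- pi * diameter^3 / 6
  } else if (!is.null(diameter)) {
    if (any(abs(volume - pi * diameter^3 / 6) > 1e-9 * pmax(volume, 1e-300)))
      stop("volume inconsistent with diameter (V = pi d^3 / 6)")
  }
  data.frame(id = seq_len(n), x = position[, 1], y = position[, 2],
             z = position[, 3],
             diameter = if (is.null(diameter)) (6 * volume / pi)^(1 / 3)
             else diameter,
             volume = volume, fate = fate)
}

#' @rdname deposition_records
#' @param path CSV path with columns x, y, z, diameter (m), fate.
#' @export
read_deposition_csv <- function(path) {
  df <- read.csv(path)
  deposition_records(as.matrix(df[, c("x", "y", "z")]),
                     diameter = df$diameter, fate = df$fate)
}

#' Assign per-particle activities
#'
#' `A_i = V_i * a * rho` with specific activity `a` (Bq/kg) and particle
#' density `rho` (kg/m^3); activity is proportional to particle mass.
#' @param records a [deposition_records()] data.frame.
#' @param specific_activity a, in Bq/kg (the reference value is 1e12).
#' @param density particle density in kg/m^3.
#' @return the records with an `activity_bq` column; total activity as
#'   attribute `total_bq`.
#' @export
assign_activity <- function(records, specific_activity = 1e12,
                            density = 1000) {
  if (specific_activity <= 0 || density <= 0)
    stop("specific activity and density must be positive")
  if (is.null(records$volume)) stop("records lack particle volumes")
  records$activity_bq <- records$volume * specific_activity * density
  attr(records, "total_bq") <- sum(records$activity_bq)
  records
}

#' Batch stuck particles into point-source groups
#'
#' Monte Carlo transport accepts at most `max_sources` point sources per
#' simulation. With dual decay (coupled gamma + beta emission) each
#' particle contributes two co-located sources, halving the per-batch
#' particle capacity (250 at the 500-source limit); both sources of a
#' particle always share a batch.
#'
#' @param records [deposition_records()] (only `fate == "stuck"` are used).
#' @param max_sources source limit per batch (default 500).
#' @param dual_decay two sources per particle if `TRUE`.
#' @return list of `source_batch` data.frames (columns x, y, z,
#'   activity_bq, mode, batch).
#' @export
batch_sources <- function(records, max_sources = 500L, dual_decay = FALSE) {
  spp <- if (dual_decay) 2L else 1L
  if (max_sources < spp) stop("max_sources must allow at least one particle")
  stuck <- records[records$fate == "stuck", , drop = FALSE]
  if (is.null(stuck$activity_bq)) stuck$activity_bq <- NA_real_
  n <- nrow(stuck)
  if (n == 0L) return(list())
  cap <- max_sources %/% spp
  n_batches <- ceiling(n / cap)
  batch_of <- rep(seq_len(n_batches), each = cap)[seq_len(n)]
  modes <- if (dual_decay) c("gamma", "beta") else "gamma"
  lapply(seq_len(n_batches), function(b) {
    sub <- stuck[batch_of == b, , drop = FALSE]
    out <- do.call(rbind, lapply(modes, function(m)
      data.frame(x = sub$x, y = sub$y, z = sub$z,
                 activity_bq = sub$activity_bq, mode = m, batch = b)))
    out[order(rep(seq_len(nrow(sub)), length(modes))), ]
  })
}

#' Number of batches for a particle count
#' @param n_particles stuck particle count.
#' @param max_sources per-batch source limit.
#' @param dual_decay two sources per particle if `TRUE`.
#' @export
n_source_batches <- function(n_particles, max_sources = 500L,
                             dual_decay = FALSE) {
  spp <- if (dual_decay) 2L else 1L
  as.integer(ceiling(n_particles / (max_sources %/% spp)))
}

# Rotation taking unit vector u onto unit vector v (Rodrigues; stable for
# the antiparallel case).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # rotate pi about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- cross3(u, p); a <- a / sqrt(sum(a^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  a <- cross3(u, v); a <- a / sqrt(sum(a^2))
  th <- acos(pmin(pmax(c_, -1), 1))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Rigidly align points to a reference frame
#'
#' Translates the source carina onto the target carina and rotates the
#' source tracheal axis onto the target axis (rigid transform: pairwise
#' distances preserved). Used to place deposition patterns into a
#' reference phantom frame with the tracheal carina as landmark.
#'
#' @param points n x 3 matrix (mm).
#' @param source_carina,target_carina landmark positions (mm).
#' @param source_axis,target_axis tracheal axis directions.
#' @return list with `points` (transformed) and `transform`
#'   (rotation, translation, reference).
#' @export
align_to_reference <- function(points, source_carina, target_carina,
                               source_axis, target_axis) {
  if (sqrt(sum(source_axis^2)) < 1e-12 || sqrt(sum(target_axis^2)) < 1e-12)
    stop("degenerate tracheal axis")
  R <- rotation_between(source_axis, target_axis)
  pts <- as.matrix(points)
  rel <- sweep(pts, 2, source_carina)
  out <- sweep(rel %*% t(R), 2, target_carina, "+")
  trans <- structure(list(rotation = R,
                          translation = as.numeric(target_carina),
                          reference = "tracheal_carina"),
                     class = "rigid_transform")
  list(points = out, transform = trans)
}

#' Load an ICRP correction table and interpolate
#'
#' The correction factor for unresolved distal deposition is an input (a
#' per-diameter table from external dosimetry tooling), not computed here;
#' this loads a CSV with columns `diameter_um`, `correction` and linearly
#' interpolates over aerodynamic diameter (constant extrapolation at the
#' ends).
#' @param path CSV path.
#' @return function mapping diameter (micrometers) to correction fraction.
#' @export
load_correction_table <- function(path) {
  tab <- read.csv(path)
  if (!all(c("diameter_um", "correction") %in% names(tab)))
    stop("correction table needs columns diameter_um, correction")
  function(d_um) approx(tab$diameter_um, tab$correction, xout = d_um,
                        rule = 2)$y
}

#' Write source batches as plain text
#'
#' One row per point source: `x y z activity mode batch`, plus a JSON
#' manifest of batch sizes and activities.
#' @param batches list from [batch_sources()].
#' @param path output text path (manifest written alongside as
#'   `<path>.manifest.json`).
#' @export
write_source_batches <- function(batches, path) {
  all <- do.call(rbind, batches)
  write.table(all, path, row.names = FALSE, quote = FALSE)
  manifest <- lapply(batches, function(b)
    list(batch = b$batch[1], n_sources = nrow(b),
         total_bq = sum(b$activity_bq)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
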