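#' Orient a model in the membrane frame
#'
#' Rigidly transforms the model so the centroid of the transmembrane (TM)
#' scatterers sits at the origin and the principal axis of the whole
#' assembly lies along +z with the cytoplasmic part (non-TM scatterers)
#' pointing towards positive z.
#'
#' @param model particle_model.
#' @param tm_residues Integer residues defining the TM selection; defaults
#'   to scatterers labelled "TM".
#' @return Oriented particle_model (rigid transform of the input).
#' @export
orient_membrane <- function(model, tm_residues = NULL) {
  s <- model$scatterers
  tm <- if (is.null(tm_residues)) s$segment == "TM"
        else !is.na(s$resid) & s$resid %in% tm_residues
  if (sum(tm) < 3)
    stop("TM selection ", if (is.null(tm_residues)) "segment == 'TM'"
         else deparse(range(tm_residues)), " contains fewer than 3 scatterers")
  xyz <- coords(model)
  xyz <- sweep(xyz, 2, colMeans(xyz[tm, , drop = FALSE]))
  # principal axis of the full assembly
  cc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  non_tm <- !tm
  ref <- if (any(non_tm)) colMeans(xyz[non_tm, , drop = FALSE]) - colMeans(xyz[tm, , drop = FALSE])
         else axis
  if (sum(axis * ref) < 0) axis <- -axis
  R <- rotation_to_z(axis)
  xyz <- xyz %*% t(R)
  # re-zero TM centroid (rotation is about the origin so it stays, but be exact)
  xyz <- sweep(xyz, 2, colMeans(xyz[tm, , drop = FALSE]))
  set_coords(model, xyz)
}

# rotation matrix taking unit vector v onto +z
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  cth <- sum(v * z)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) return(diag(c(1, -1, -1)))
  ax <- c(v[2] * z[3] - v[3] * z[2],
          v[3] * z[1] - v[1] * z[3],
          v[1] * z[2] - v[2] * z[1])
  ax <- ax / sqrt(sum(ax^2))
  rotation_about(ax, acos(cth))
}

# Rodrigues rotation matrix: angle in radians about unit axis
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Bend a model at a flexible hinge
#'
#' Rotates all scatterers distal to the hinge (residue index greater than
#' the pivot, i.e. towards the cytoplasmic tip) by `angle` degrees about
#' an axis through the hinge pivot. The pivot is the centroid of the
#' hinge residue's scatterers over all chains; the bend axis is
#' `z x rod-axis` of the distal block (falling back to x when the rod
#' axis is parallel to z), so a positive angle tips the distal block away
#' from +z in a reproducible plane. Belt pseudo-atoms (no residue index)
#' never move.
#'
#' @param model Oriented particle_model.
#' @param hinge Hinge name in `model$hinges`, or a residue index.
#' @param angle Bend angle, degrees, in `[-180, 180]`.
#' @return particle_model with the distal block rotated rigidly.
#' @export
bend_at_hinge <- function(model, hinge, angle) {
  if (abs(angle) > 180) stop("|angle| > 180 degrees")
  pivot_res <- if (is.character(hinge)) {
    if (is.null(model$hinges) || !hinge %in% names(model$hinges))
      stop("hinge '", hinge, "' not defined for this model")
    model$hinges[[hinge]]
  } else hinge
  s <- model$scatterers
  at_hinge <- !is.na(s$resid) & s$resid == pivot_res
  if (!any(at_hinge)) stop("hinge residue ", pivot_res, " absent from model")
  if (angle == 0) return(model)
  xyz <- coords(model)
  pivot <- colMeans(xyz[at_hinge, , drop = FALSE])
  distal <- !is.na(s$resid) & s$resid > pivot_res
  if (!any(distal)) return(model)
  dxyz <- xyz[distal, , drop = FALSE]
  # rod axis of the distal block, pointing tip-ward
  dc <- sweep(dxyz, 2, colMeans(dxyz))
  rod <- if (nrow(dxyz) >= 3) eigen(crossprod(dc) / nrow(dc), symmetric = TRUE)$vectors[, 1]
         else c(0, 0, 1)
  tipward <- colMeans(dxyz) - pivot
  if (sum(rod * tipward) < 0) rod <- -rod
  ax <- c(-rod[2], rod[1], 0)                      # z x rod
  # |z x rod| = sin(tilt); a near-parallel rod gives a numerically
  # arbitrary azimuth, so use the x fallback below ~3 degrees of tilt
  if (sqrt(sum(ax^2)) < 0.05) ax <- c(1, 0, 0)
  R <- rotation_about(ax, angle * pi / 180)
  xyz[distal, ] <- sweep(sweep(dxyz, 2, pivot) %*% t(R), 2, pivot, "+")
  set_coords(model, xyz)
}

#' Assemble a C3-symmetric trimer of dimers
#'
#' Places three copies of an oriented dimer with exact C3 symmetry about
#' the z axis. `mode = "tripod"` tilts each copy about its cytoplasmic
#' tip so the TM centroid moves out to radius `radial_offset` from the
#' axis while the tips stay converged on the axis (inter-TM distances
#' become `radial_offset * sqrt(3)`); `mode = "tm_bound"` translates each
#' copy radially by `radial_offset` without tilting, so the TM domains
#' stay adjacent near the axis.
#'
#' @param dimer Oriented particle_model (z = symmetry axis candidate).
#' @param radial_offset Radial displacement of each TM centroid, A, >= 0.
#' @param mode "tripod" or "tm_bound".
#' @return particle_model of the trimer; chains are relabelled
#'   `<chain>1`, `<chain>2`, `<chain>3` per dimer copy and a `dimer`
#'   index column is added.
#' @export
assemble_c3 <- function(dimer, radial_offset = 0, mode = c("tripod", "tm_bound")) {
  mode <- match.arg(mode)
  if (radial_offset < 0) stop("radial_offset must be >= 0")
  s <- dimer$scatterers
  xyz <- coords(dimer)
  tm <- s$segment == "TM"
  if (mode == "tripod" && radial_offset > 0) {
    prot <- !is.na(s$resid)
    tip_z <- max(xyz[prot, 3])
    tip <- c(0, 0, tip_z)
    tm_c <- colMeans(xyz[tm, , drop = FALSE])
    lever <- sqrt(sum((tm_c - tip)^2))
    if (radial_offset > lever)
      stop("radial_offset exceeds the tip-to-TM lever arm (", round(lever, 1), " A)")
    phi <- asin(radial_offset / lever)
    R <- rotation_about(c(0, 1, 0), phi)          # tilt in the xz plane
    xyz0 <- sweep(sweep(xyz, 2, tip) %*% t(R), 2, tip, "+")
    # tilt moves TM centroid to -x or +x depending on geometry; force +x
    if (colMeans(xyz0[tm, , drop = FALSE])[1] < 0)
      xyz0 <- sweep(sweep(xyz, 2, tip) %*% t(rotation_about(c(0, 1, 0), -phi)), 2, tip, "+")
  } else {
    xyz0 <- xyz
    xyz0[, 1] <- xyz0[, 1] + radial_offset
  }
  pieces <- lapply(0:2, function(k) {
    Rk <- rotation_about(c(0, 0, 1), 2 * pi * k / 3)
    sk <- s
    sk[, c("x", "y", "z")] <- xyz0 %*% t(Rk)
    sk$chain <- paste0(sk$chain, k + 1)
    sk$dimer <- k + 1L
    sk
  })
  particle_model(do.call(rbind, pieces), hinges = dimer$hinges,
                 meta = c(dimer$meta, list(c3_mode = mode, radial_offset = radial_offset)))
}

#' Radius of gyration of a particle model
#'
#' `sqrt(sum(w * |r - rbar|^2) / sum(w))`. Uniform weighting uses w = 1;
#' contrast weighting uses solvent-corrected scattering weights from
#' [contrast_weights()].
#'
#' @param model particle_model.
#' @param weighting "uniform" or "contrast".
#' @param solvent,radiation Passed to [contrast_weights()] when
#'   `weighting = "contrast"`.
#' @return Rg in A.
#' @export
radius_of_gyration <- function(model, weighting = c("uniform", "contrast"),
                               solvent = NULL, radiation = "xray") {
  weighting <- match.arg(weighting)
  xyz <- coords(model)
  w <- if (weighting == "uniform") rep(1, nrow(xyz))
       else contrast_weights(model, solvent, radiation)
  if (abs(sum(w)) < 1e-12) stop("total weight is zero; Rg undefined")
  ctr <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Minimal cross-dimer separations at selected residues
#'
#' For each residue in `residue_set`, computes the per-dimer centroid of
#' that residue's scatterers and returns the minimal distance between
#' centroids of different dimers. Requires a trimer built by
#' [assemble_c3()] (dimers distinguishable by the `dimer` column).
#'
#' @param trimer particle_model with a `dimer` index column.
#' @param residue_set Integer residue indices.
#' @return Named numeric vector of separations (A), sorted by residue.
#' @export
inter_dimer_separations <- function(trimer, residue_set) {
  s <- trimer$scatterers
  if (is.null(s$dimer)) stop("model has no dimer index; build it with assemble_c3()")
  residue_set <- sort(unique(as.integer(residue_set)))
  missing <- vapply(residue_set, function(r) {
    any(vapply(split(s, s$dimer), function(d) !any(!is.na(d$resid) & d$resid == r),
               logical(1)))
  }, logical(1))
  if (any(missing))
    stop("residue(s) missing in at least one dimer: ",
         paste(residue_set[missing], collapse = ", "))
  out <- vapply(residue_set, function(r) {
    ctrs <- t(vapply(split(s, s$dimer), function(d) {
      sel <- !is.na(d$resid) & d$resid == r
      colMeans(as.matrix(d[sel, c("x", "y", "z")]))
    }, numeric(3)))
    dd <- as.matrix(stats::dist(ctrs))
    min(dd[upper.tri(dd)])
  }, numeric(1))
  stats::setNames(out, residue_set)
}
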