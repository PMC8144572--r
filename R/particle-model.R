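#' Coarse-grained particle model for small-angle scattering
#'
#' A `particle_model` holds the point scatterers every forward computation
#' consumes: positions (A), per-scatterer X-ray electron counts, neutron
#' scattering lengths (fm, all-protium reference), excluded volumes (A^3),
#' the number of solvent-exchangeable hydrogens, the non-exchangeable
#' deuteration fraction, a segment label, a 1-based residue index (NA for
#' detergent-belt pseudo-atoms) and a chain identifier.
#'
#' @param scatterers data.frame with columns `x, y, z, xray_e, neutron_b,
#'   volume, n_exch_h, deut_frac, segment, resid, chain`.
#' @param hinges Named numeric vector of hinge pivot residues, e.g.
#'   `c(HAMP1 = 136, HAMP2 = 230, Gly = 340)`; optional.
#' @param meta Free-form metadata list (seeds, provenance).
#' @return Object of class `particle_model`.
#' @export
particle_model <- function(scatterers, hinges = NULL, meta = list()) {
  req <- c("x", "y", "z", "xray_e", "neutron_b", "volume",
           "n_exch_h", "deut_frac", "segment", "resid", "chain")
  miss <- setdiff(req, names(scatterers))
  if (length(miss)) stop("scatterers missing column(s): ", paste(miss, collapse = ", "))
  xyz <- as.matrix(scatterers[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite scatterer positions")
  if (any(scatterers$volume < 0)) stop("excluded_volume must be >= 0")
  if (any(scatterers$deut_frac < 0 | scatterers$deut_frac > 1))
    stop("deut_frac must be in [0, 1]")
  ok_seg <- c("TM", "HAMP1", "interHAMP", "HAMP2", "adaptation", "tip",
              "belt_tail", "belt_head")
  if (any(!scatterers$segment %in% ok_seg))
    stop("unknown segment label(s): ",
         paste(unique(setdiff(scatterers$segment, ok_seg)), collapse = ", "))
  structure(list(scatterers = as.data.frame(scatterers, stringsAsFactors = FALSE),
                 hinges = hinges, meta = meta),
            class = "particle_model")
}

#' @export
print.particle_model <- function(x, ...) {
  s <- x$scatterers
  cat(sprintf("particle_model: %d scatterers, %d chain(s) [%s]\n",
              nrow(s), length(unique(s$chain)),
              paste(names(table(s$segment)), table(s$segment),
                    sep = ":", collapse = " ")))
  if (!is.null(x$hinges))
    cat("hinges:", paste(names(x$hinges), x$hinges, sep = "=", collapse = " "), "\n")
  invisible(x)
}

coords <- function(model) as.matrix(model$scatterers[, c("x", "y", "z")])

set_coords <- function(model, xyz) {
  model$scatterers[, c("x", "y", "z")] <- xyz
  model
}

is_belt <- function(model) model$scatterers$segment %in% c("belt_tail", "belt_head")

#' Effective per-scatterer contrast weights
#'
#' X-ray: `electrons - rho_e * volume` (e). Neutron: `b + n_exch *
#' d2o * (b_D - b_H) - sld * volume` (fm; volumes converted via
#' 1 A = 1e5 fm). With `solvent = NULL` the weights are in-vacuo.
#'
#' @param model particle_model.
#' @param solvent `solvent_model` or NULL.
#' @param radiation "xray" or "neutron".
#' @return Numeric vector of weights (e or fm).
#' @export
contrast_weights <- function(model, solvent = NULL, radiation = c("xray", "neutron")) {
  radiation <- match.arg(radiation)
  s <- model$scatterers
  b <- scattering_elements$b
  if (radiation == "xray") {
    w <- s$xray_e
    if (!is.null(solvent)) w <- w - solvent$rho_e * s$volume
  } else {
    d2o <- if (is.null(solvent)) 0 else solvent$d2o_fraction
    w <- s$neutron_b + s$n_exch_h * d2o * (b[["D"]] - b[["H"]])
    if (!is.null(solvent)) w <- w - solvent$sld * s$volume * 1e5
  }
  w
}

# average-residue bead defaults for coarse-grained toy models:
# volume ~ mean amino-acid volume, electrons ~ mean residue electrons,
# b for an all-H residue, ~1.6 exchangeable H per residue
.bead_defaults <- list(volume = 129.0, xray_e = 54.0, neutron_b = 22.7, n_exch_h = 1.6)

bead_frame <- function(xyz, segment, resid, chain,
                       xray_e = .bead_defaults$xray_e,
                       neutron_b = .bead_defaults$neutron_b,
                       volume = .bead_defaults$volume,
                       n_exch_h = .bead_defaults$n_exch_h,
                       deut_frac = 0) {
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             xray_e = xray_e, neutron_b = neutron_b, volume = volume,
             n_exch_h = n_exch_h, deut_frac = deut_frac,
             segment = segment, resid = resid, chain = chain,
             stringsAsFactors = FALSE)
}

#' Read a particle model from a PDB file
#'
#' One bead per ATOM/HETATM record. Belt pseudo-atoms are recognized by
#' residue names DTL (tail) / DHD (head) and given the DDM pseudo-atom
#' scattering properties; everything else is treated as a protein bead
#' with average-residue properties and segment labels assigned from an
#' optional residue-range map.
#'
#' @param path PDB file path.
#' @param segment_map Optional named list of residue ranges, e.g.
#'   `list(TM = c(1, 83), HAMP1 = c(84, 136))`; residues outside all
#'   ranges are labelled "adaptation".
#' @return particle_model.
#' @export
read_model_pdb <- function(path, segment_map = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_model_pdb requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  seg <- rep("adaptation", nrow(a))
  belt_tail <- a$resid == "DTL"
  belt_head <- a$resid == "DHD"
  seg[belt_tail] <- "belt_tail"
  seg[belt_head] <- "belt_head"
  if (!is.null(segment_map)) {
    for (nm in names(segment_map)) {
      rng <- segment_map[[nm]]
      sel <- !belt_tail & !belt_head & a$resno >= rng[1] & a$resno <= rng[2]
      seg[sel] <- nm
    }
  }
  df <- bead_frame(cbind(a$x, a$y, a$z), segment = seg,
                   resid = ifelse(belt_tail | belt_head, NA_integer_, a$resno),
                   chain = ifelse(is.na(a$chain), "A", a$chain))
  tailp <- composition_scattering(c(C = 12, H = 25))
  headp <- composition_scattering(c(C = 12, H = 21, O = 11))
  df$xray_e[belt_tail] <- 9
  df$neutron_b[belt_tail] <- 9 / 97 * tailp$neutron_b
  df$n_exch_h[belt_tail] <- 0
  df$xray_e[belt_head] <- 10
  df$neutron_b[belt_head] <- 10 / 181 * headp$neutron_b
  df$n_exch_h[belt_head] <- 10 / 181 * 7
  df$volume[belt_tail] <- 350 * 9 / 97            # CH3-chunk volumes
  df$volume[belt_head] <- 350 * 10 / 181
  particle_model(df, meta = list(source = path))
}

#' Write a particle model as a PDB file
#'
#' Protein beads become CA ATOM records; belt pseudo-atoms become HETATM
#' records with residue names DTL/DHD (element C). Round-trippable by
#' [read_model_pdb()].
#'
#' @param model particle_model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("write_model_pdb requires the bio3d package")
  s <- model$scatterers
  belt <- is_belt(model)
  resid_chr <- ifelse(s$segment == "belt_tail", "DTL",
                      ifelse(s$segment == "belt_head", "DHD", "ALA"))
  resno <- ifelse(is.na(s$resid), seq_len(nrow(s)), s$resid)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(model))),
                   type = ifelse(belt, "HETATM", "ATOM"),
                   resno = resno, resid = resid_chr,
                   chain = s$chain,
                   elety = ifelse(belt, "C", "CA"),
                   eleno = seq_len(nrow(s)))
  invisible(path)
}
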