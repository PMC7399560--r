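# Data model for filament conformations and ensembles.
#
# A conformation stores one nucleotide per row: its center-of-mass position
# (nm), the oxDNA-convention base and normal versors, and the
# (duplex_id, strand_id, bp_index) indexing that locates it within the bundle.
# Duplex ids run 0..n_duplex-1, strand ids within a duplex are 1 and 2, and
# bp_index runs 0..bp_count-1 along the duplex contour.

#' Construct a filament conformation
#'
#' @param positions numeric n x 3 matrix of nucleotide center-of-mass
#'   positions in nm.
#' @param base_vectors numeric n x 3 matrix of unit base versors (oxDNA `a1`
#'   convention: base toward the paired strand).
#' @param normal_vectors numeric n x 3 matrix of unit normal versors (oxDNA
#'   `a3`, roughly along the helical axis).
#' @param strand_id integer vector; 1 or 2 within each duplex.
#' @param duplex_id integer vector in `0:(n_duplex - 1)`.
#' @param bp_index integer vector, base-pair plane index along the duplex.
#' @param n_duplex number of duplexes in the bundle (6 for a six-helix bundle).
#' @param contour_length design contour length l_c in nm.
#' @param diameter bundle diameter sigma in nm.
#' @param design_label free-text label for the origami design variant.
#' @return an object of class `filament_conformation`.
#' @export
filament_conformation <- function(positions, base_vectors, normal_vectors,
                                  strand_id, duplex_id, bp_index,
                                  n_duplex = 6L, contour_length, diameter = 6,
                                  design_label = "custom") {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3,
            nrow(base_vectors) == n, nrow(normal_vectors) == n,
            length(strand_id) == n, length(duplex_id) == n,
            length(bp_index) == n)
  if (contour_length <= 0) stop("contour_length must be positive")
  if (diameter <= 0) stop("diameter must be positive")
  obj <- structure(list(
    positions = positions,
    base_vectors = as.matrix(base_vectors),
    normal_vectors = as.matrix(normal_vectors),
    strand_id = as.integer(strand_id),
    duplex_id = as.integer(duplex_id),
    bp_index = as.integer(bp_index),
    n_duplex = as.integer(n_duplex),
    contour_length = contour_length,
    diameter = diameter,
    design_label = design_label
  ), class = "filament_conformation")
  validate_conformation(obj)
  obj
}

#' Validate a filament conformation
#'
#' Checks the type invariants: unit base/normal versors within 1e-6, unique
#' (duplex_id, strand_id, bp_index) triples, and both strands of every duplex
#' carrying equal base-pair counts.
#'
#' @param conf a `filament_conformation`.
#' @return the conformation, invisibly; errors on violation.
#' @export
validate_conformation <- function(conf) {
  nb <- sqrt(rowSums(conf$base_vectors^2))
  nn <- sqrt(rowSums(conf$normal_vectors^2))
  if (any(abs(nb - 1) > 1e-6) || any(abs(nn - 1) > 1e-6))
    stop("base/normal vectors must have unit norm within 1e-6")
  key <- paste(conf$duplex_id, conf$strand_id, conf$bp_index)
  if (anyDuplicated(key))
    stop("(duplex_id, strand_id, bp_index) triples must be unique")
  tab <- table(conf$duplex_id, conf$strand_id)
  if (any(tab == 0) || length(unique(as.vector(tab))) != 1)
    stop("every duplex must carry two strands of equal bp count")
  invisible(conf)
}

#' @export
print.filament_conformation <- function(x, ...) {
  cat("<filament_conformation> '", x$design_label, "'\n", sep = "")
  cat("  ", nrow(x$positions), " nucleotides, ", x$n_duplex, " duplexes, ",
      length(unique(x$bp_index)), " bp planes\n", sep = "")
  cat("  l_c = ", x$contour_length, " nm, sigma = ", x$diameter, " nm\n",
      sep = "")
  invisible(x)
}

n_bp_planes <- function(conf) length(unique(conf$bp_index))

#' Construct a conformation ensemble
#'
#' @param conformations list of `filament_conformation` objects sharing
#'   design label, duplex count and bp counts.
#' @param provenance list describing where the ensemble came from (generator
#'   parameters and seed, or source file paths).
#' @return an object of class `conformation_ensemble`.
#' @export
conformation_ensemble <- function(conformations, provenance = list()) {
  if (length(conformations) < 1) stop("an ensemble must contain >= 1 conformation")
  ok <- vapply(conformations, inherits, logical(1), "filament_conformation")
  if (!all(ok)) stop("all members must be filament_conformation objects")
  nd <- vapply(conformations, function(x) x$n_duplex, integer(1))
  lab <- vapply(conformations, function(x) x$design_label, character(1))
  np <- vapply(conformations, function(x) nrow(x$positions), integer(1))
  if (length(unique(nd)) != 1 || length(unique(lab)) != 1 ||
      length(unique(np)) != 1)
    stop("ensemble members must share n_duplex, design_label and site counts")
  structure(list(
    conformations = conformations,
    provenance = provenance,
    count = length(conformations)
  ), class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat("<conformation_ensemble> ", x$count, " conformations of '",
      x$conformations[[1]]$design_label, "'\n", sep = "")
  if (length(x$provenance))
    cat("  provenance: ", paste(names(x$provenance), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
length.conformation_ensemble <- function(x) x$count

#' Mirror-reflect a conformation
#'
#' Reflects all positions and versors through the yz plane (x -> -x). Every
#' chirality measure downstream (helicity, twist, writhe, chiral strength,
#' pitch) changes sign under this operation while achiral quantities are
#' unchanged; it is the canonical parity control.
#'
#' @param conf a `filament_conformation`.
#' @return the reflected conformation.
#' @export
mirror_conformation <- function(conf) {
  conf$positions[, 1] <- -conf$positions[, 1]
  conf$base_vectors[, 1] <- -conf$base_vectors[, 1]
  conf$normal_vectors[, 1] <- -conf$normal_vectors[, 1]
  conf
}

#' @rdname mirror_conformation
#' @param ensemble a `conformation_ensemble`.
#' @export
mirror_ensemble <- function(ensemble) {
  ensemble$conformations <- lapply(ensemble$conformations, mirror_conformation)
  ensemble$provenance$mirrored <- TRUE
  ensemble
}

#' End-to-end distance autocorrelation diagnostic
#'
#' For imported trajectories the statistical independence of successive
#' frames is assessed by the autocorrelation of the end-to-end separation of
#' the filament backbone; generated ensembles are i.i.d. by construction.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param max_lag largest lag to report.
#' @return data.frame with columns `lag` and `acf`.
#' @export
ensemble_autocorrelation <- function(ensemble, max_lag = 20L) {
  e2e <- vapply(ensemble$conformations, function(conf) {
    bb <- extract_backbone(conf, trim_bp = 0L)
    sqrt(sum((bb$positions[nrow(bb$positions), ] - bb$positions[1, ])^2))
  }, numeric(1))
  max_lag <- min(max_lag, length(e2e) - 1L)
  a <- stats::acf(e2e, lag.max = max_lag, plot = FALSE)
  data.frame(lag = drop(a$lag), acf = drop(a$acf))
}
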