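# Per-frame geometric descriptors of the channel gate: side-chain chi1
# dihedrals, cross-tetramer distances, gate-backbone RMSD, M3 bend
# angles at the hinge, pore cross-section areas, ligand-binding-domain
# (LBD) metrics, and the mixed angle/distance feature encoding used for
# embedding and clustering.

#' Side-chain chi1 dihedral of a residue
#'
#' Computed from atoms N, CA, CB and the first side-chain heavy atom
#' (OG1 for threonine), IUPAC sign convention.
#'
#' @param model A [structure_model()].
#' @param chain Chain id.
#' @param resno Residue number (default 617, the gate threonine).
#' @param terminal Atom name of the chi1-terminal atom.
#' @return Angle in degrees in (-180, 180].
#' @export
chi1_angle <- function(model, chain, resno = 617, terminal = "OG1") {
  pt <- function(ety) {
    i <- which(model$chain == chain & model$resno == resno &
                 model$elety == ety)
    if (length(i) != 1L)
      stop("chi1_angle: atom ", ety, " of residue ", resno,
           " chain ", chain, " not found")
    as.numeric(model[i, c("x", "y", "z")])
  }
  dihedral_angle(pt("N"), pt("CA"), pt("CB"), pt(terminal))
}

#' Cross-tetramer distance between equivalent atoms of two chains
#'
#' @param model A [structure_model()].
#' @param resno Residue number.
#' @param chains Length-2 chain pair, e.g. `c("A", "C")`.
#' @param elety Atom name (default CA).
#' @return Euclidean distance in Angstrom.
#' @export
cross_distance <- function(model, resno, chains = c("A", "C"),
                           elety = "CA") {
  stopifnot(length(chains) == 2)
  p <- lapply(chains, function(ch) {
    i <- which(model$chain == ch & model$resno == resno &
                 model$elety == elety)
    if (length(i) != 1L)
      stop("cross_distance: atom ", elety, " of residue ", resno,
           " chain ", ch, " not found")
    as.numeric(model[i, c("x", "y", "z")])
  })
  sqrt(sum((p[[1]] - p[[2]])^2))
}

#' Gate backbone RMSD after optimal superposition
#'
#' Minimum root-mean-square deviation of the gate backbone selection
#' (residues 614-625, atoms C, O, N, CA, CB by default) between a frame
#' and a reference, after optimal rigid-body superposition of that
#' selection (Kabsch).
#'
#' @param frame,reference [structure_model()]s with identical atom sets
#'   over the selection.
#' @param resno Residues of the selection.
#' @param elety Atom names of the selection.
#' @param chains Chains of the selection.
#' @return RMSD in Angstrom.
#' @export
gate_rmsd <- function(frame, reference, resno = 614:625,
                      elety = c("C", "O", "N", "CA", "CB"),
                      chains = c("A", "B", "C", "D")) {
  i1 <- select_atoms(frame, chain = chains, resno = resno, elety = elety)
  i2 <- select_atoms(reference, chain = chains, resno = resno, elety = elety)
  k1 <- paste(frame$chain[i1], frame$resno[i1], frame$elety[i1])
  k2 <- paste(reference$chain[i2], reference$resno[i2], reference$elety[i2])
  if (length(i1) != length(i2) || any(k1 != k2))
    stop("gate_rmsd: atom sets of frame and reference differ")
  superpose_rmsd(atom_coords(frame, i1), atom_coords(reference, i2))
}

#' Helix bend angle at a hinge residue
#'
#' Fits a straight axis (first principal component) through the CA run
#' below the hinge and another through the run above it, both oriented
#' by increasing residue number, and reports the angle between the two
#' oriented axes.  A straight helix gives 0 degrees; a helix kinked by
#' theta at the hinge gives theta.
#'
#' @param model A [structure_model()].
#' @param chain Chain id.
#' @param hinge Hinge residue number (default 618, the gating alanine).
#' @param flank Number of CA atoms to use on each side of the hinge.
#' @return Bend angle in degrees, >= 0.
#' @export
bend_angle <- function(model, chain, hinge = 618, flank = 4) {
  ca <- model[model$chain == chain & model$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  below <- ca[ca$resno <= hinge & ca$resno >= hinge - flank, , drop = FALSE]
  above <- ca[ca$resno >= hinge & ca$resno <= hinge + flank, , drop = FALSE]
  if (nrow(below) < 3 || nrow(above) < 3)
    stop("bend_angle: need at least 3 CA atoms on each side of the hinge")
  seg_dir <- function(seg) {
    m <- as.matrix(seg[, c("x", "y", "z")])
    mc <- sweep(m, 2, colMeans(m))
    v <- eigen(crossprod(mc), symmetric = TRUE)$vectors[, 1]
    # orient along increasing residue number
    if (sum(v * (m[nrow(m), ] - m[1, ])) < 0) v <- -v
    v
  }
  v1 <- seg_dir(below)
  v2 <- seg_dir(above)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Pore cross-section area at a marker residue
#'
#' Area of the quadrilateral through the four CA atoms of a residue,
#' projected onto the plane normal to the pore axis, with vertices
#' ordered by azimuth (so the result is invariant to the input order of
#' chains).
#'
#' @param model A [structure_model()] in the gate frame.
#' @param resno Marker residue (617, 621 or 625).
#' @param chains The four receptor chains.
#' @param axis Pore axis (default z).
#' @return Area in Angstrom^2.
#' @export
pore_area <- function(model, resno, chains = c("A", "B", "C", "D"),
                      axis = c(0, 0, 1)) {
  idx <- which(model$resno == resno & model$elety == "CA" &
                 model$chain %in% chains)
  if (length(idx) != 4)
    stop("pore_area: need exactly 4 CA atoms at residue ", resno,
         " (found ", length(idx), ")")
  xyz <- atom_coords(model, idx)
  r <- rotation_between(axis, c(0, 0, 1))
  v <- xyz %*% t(r)
  v2 <- sweep(v[, 1:2, drop = FALSE], 2, colMeans(v[, 1:2, drop = FALSE]))
  ord <- order(atan2(v2[, 2], v2[, 1]))
  shoelace_area(v2[ord, , drop = FALSE])
}

#' Ligand-binding-domain clamshell and splaying metrics
#'
#' For each subunit: `alpha`, the clamshell closure angle, measured as
#' the rigid-body rotation of the lower lobe (D2) after superposing the
#' upper lobe (D1) onto the same subunit of a declared apo (open-
#' clamshell) reference; `d635`, the CA-CA distance between residue 635
#' of the two subunits of each declared LBD dimer; `L`, the horizontal
#' (xy) distance of each D2 lobe's centre of mass from the overall
#' two-fold axis (taken as the z axis through the xy centroid of the
#' model); and `H`, the vertical position of each D2 centre of mass.
#'
#' @param model A [structure_model()] in the gate frame.
#' @param apo_reference Apo reference [structure_model()] with the same
#'   chain/residue layout.
#' @param d1_resnos,d2_resnos Residue ranges of the D1 and D2 lobes.
#' @param dimers List of chain pairs forming LBD dimers,
#'   e.g. `list(c("A","D"), c("C","B"))`.
#' @param marker_resno Residue used for the dimer separation distance
#'   (default 635).
#' @param chains Receptor chains.
#' @return List with per-subunit `alpha` (degrees), per-dimer `d635`
#'   (Angstrom), per-subunit `L` and `H` (Angstrom).
#' @export
lbd_metrics <- function(model, apo_reference, d1_resnos, d2_resnos,
                        dimers = list(c("A", "D"), c("C", "B")),
                        marker_resno = 635,
                        chains = c("A", "B", "C", "D")) {
  if (!any(model$resno == marker_resno))
    stop("lbd_metrics: marker residue ", marker_resno, " absent")
  if (missing(d1_resnos) || missing(d2_resnos))
    stop("lbd_metrics: D1/D2 residue partitions must be supplied")
  alpha <- stats::setNames(numeric(length(chains)), chains)
  L <- stats::setNames(numeric(length(chains)), chains)
  H <- stats::setNames(numeric(length(chains)), chains)
  ctr_xy <- colMeans(atom_coords(model))[1:2]
  for (ch in chains) {
    i_d1m <- select_atoms(model, chain = ch, resno = d1_resnos, elety = "CA")
    i_d1r <- select_atoms(apo_reference, chain = ch, resno = d1_resnos,
                          elety = "CA")
    i_d2m <- select_atoms(model, chain = ch, resno = d2_resnos, elety = "CA")
    i_d2r <- select_atoms(apo_reference, chain = ch, resno = d2_resnos,
                          elety = "CA")
    d1m <- atom_coords(model, i_d1m); d1r <- atom_coords(apo_reference, i_d1r)
    d2m <- atom_coords(model, i_d2m); d2r <- atom_coords(apo_reference, i_d2r)
    # superpose the model's D1 onto the reference's D1
    c_m <- colMeans(d1m); c_r <- colMeans(d1r)
    rot <- kabsch_rotation(sweep(d1m, 2, c_m), sweep(d1r, 2, c_r))
    d2m_al <- sweep(sweep(d2m, 2, c_m) %*% rot, 2, -c_r)
    # residual rigid rotation of D2 relative to the reference D2
    c2m <- colMeans(d2m_al); c2r <- colMeans(d2r)
    r2 <- kabsch_rotation(sweep(d2r, 2, c2r), sweep(d2m_al, 2, c2m))
    alpha[ch] <- acos(max(-1, min(1, (sum(diag(r2)) - 1) / 2))) * 180 / pi
    com2 <- colMeans(d2m)
    L[ch] <- sqrt(sum((com2[1:2] - ctr_xy)^2))
    H[ch] <- com2[3]
  }
  d635 <- vapply(dimers, function(pr) {
    cross_distance(model, marker_resno, chains = pr, elety = "CA")
  }, numeric(1))
  names(d635) <- vapply(dimers, paste, "", collapse = "")
  list(alpha = alpha, d635 = d635, L = L, H = H)
}

#' Gate feature vector of one frame
#'
#' The seven descriptors used for conformational embedding: the four
#' T617 chi1 dihedrals plus the cross-tetramer CA distances at T625
#' (A-C and B-D) and at T617 (A-C).
#'
#' @param model A [structure_model()] (one frame).
#' @param chi1_resno Side-chain residue (default 617).
#' @param dist_resno Distance residue at the gate entrance (default
#'   625).
#' @return Named numeric vector: chi1_A..chi1_D, d625_AC, d625_BD,
#'   d617_AC.
#' @export
gate_feature_vector <- function(model, chi1_resno = 617, dist_resno = 625) {
  chains <- c("A", "B", "C", "D")
  chi <- vapply(chains, function(ch) chi1_angle(model, ch, chi1_resno),
                numeric(1))
  c(stats::setNames(chi, paste0("chi1_", chains)),
    d625_AC = cross_distance(model, dist_resno, c("A", "C")),
    d625_BD = cross_distance(model, dist_resno, c("B", "D")),
    d617_AC = cross_distance(model, chi1_resno, c("A", "C")))
}

#' Feature table of a frame series
#'
#' @param frames A [frame_series()].
#' @param ... Passed to [gate_feature_vector()].
#' @return Numeric matrix, one row per frame.
#' @export
gate_feature_table <- function(frames, ...) {
  t(vapply(seq_len(n_frames(frames)),
           function(i) gate_feature_vector(get_frame(frames, i), ...),
           gate_feature_vector(get_frame(frames, 1), ...)))
}

#' Encode mixed angle/distance features for embedding
#'
#' Distances are standardised to unit variance.  Each angle is encoded
#' as a (sin, cos) pair jointly scaled by a single factor so the pair's
#' total variance is 1, giving angles and distances equal weight while
#' respecting periodicity: angles of 179 and -179 degrees become
#' near-neighbours in the encoded space, and atan2 of the pair recovers
#' the angle.  Zero-variance features are dropped with a warning.
#'
#' @param features Numeric matrix (frames x features) with named
#'   columns.
#' @param angular_cols Column names or indices of angular features (in
#'   degrees); defaults to names starting with "chi".
#' @return Encoded numeric matrix with attributes `scaling` (per output
#'   column factors), `mapping` (source column of each output column)
#'   and `dropped` (names of removed features).
#' @export
encode_features <- function(features,
                            angular_cols = grepl("^chi", colnames(features))) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  if (is.character(angular_cols))
    angular_cols <- colnames(features) %in% angular_cols
  if (is.numeric(angular_cols))
    angular_cols <- seq_len(ncol(features)) %in% angular_cols
  if (length(angular_cols) == 0) angular_cols <- rep(FALSE, ncol(features))
  angular_cols <- rep_len(angular_cols, ncol(features))
  out <- list(); map <- character(); dropped <- character()
  for (j in seq_len(ncol(features))) {
    nm <- colnames(features)[j]
    x <- features[, j]
    if (angular_cols[j]) {
      s <- sin(x * pi / 180); c_ <- cos(x * pi / 180)
      v <- stats::var(s) + stats::var(c_)
      if (v < 1e-12) {
        warning("encode_features: constant angle '", nm, "' dropped")
        dropped <- c(dropped, nm); next
      }
      f <- 1 / sqrt(v)
      out[[paste0(nm, ".sin")]] <- s * f
      out[[paste0(nm, ".cos")]] <- c_ * f
      map <- c(map, nm, nm)
    } else {
      v <- stats::var(x)
      if (v < 1e-12) {
        warning("encode_features: constant feature '", nm, "' dropped")
        dropped <- c(dropped, nm); next
      }
      out[[nm]] <- (x - mean(x)) / sqrt(v)
      map <- c(map, nm)
    }
  }
  enc <- do.call(cbind, out)
  attr(enc, "mapping") <- map
  attr(enc, "dropped") <- dropped
  enc
}
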