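# Structure and trajectory I/O: PDB/mmCIF reading via bio3d, atom
# selection, and placement of frames in the gate-centred coordinate
# frame (origin at the reference-residue CA centre of mass, pore axis
# along z, selectivity-filter side at negative z).

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns chain, resno, resid, elety,
#'   x, y, z (Angstrom) and optionally elesy (element symbol).
#' @return data.frame of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("structure_model: missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(atoms[, c("x", "y", "z")]))
    stop("structure_model: missing coordinates")
  if (is.null(atoms$elesy))
    atoms$elesy <- toupper(substr(gsub("[0-9'\"]", "", atoms$elety), 1, 1))
  rownames(atoms) <- NULL
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chains (%s), residues %d-%d\n",
              nrow(x), length(unique(x$chain)),
              paste(sort(unique(x$chain)), collapse = ","),
              min(x$resno), max(x$resno)))
  invisible(x)
}

#' Read a structure file (PDB or mmCIF)
#'
#' Chain, residue and atom identifiers are preserved verbatim and
#' positions are reported in Angstrom.  When a file carries alternate
#' locations, the highest-occupancy conformer of each atom is kept and
#' the number of discarded altloc records is reported via a message.
#'
#' @param path File path; format chosen by extension (.pdb/.ent vs
#'   .cif/.mmcif).
#' @param model Model number to extract from a multi-model file.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  pdb <- switch(ext,
    pdb = , ent = bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
    cif = , mmcif = bio3d::read.cif(path, verbose = FALSE),
    stop("read_structure: unknown format '.", ext,
         "' (expected .pdb/.ent/.cif)"))
  a <- pdb$atom
  if (anyNA(a$x) || anyNA(a$y) || anyNA(a$z))
    stop("read_structure: missing coordinates in ATOM records of ", path)
  if (model > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model)
      stop("read_structure: model ", model, " not present")
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  }
  # altloc resolution: keep the highest-occupancy conformer per atom
  alt <- a$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    occ <- if (!is.null(a$o)) a$o else rep(1, nrow(a))
    occ[is.na(occ)] <- 1
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(i) {
      if (length(i) == 1L) return(i)
      i[order(-occ[i], alt[i])][1]
    }), use.names = FALSE)
    n_drop <- nrow(a) - length(keep)
    if (n_drop > 0)
      message("read_structure: discarded ", n_drop,
              " alternate-location records (kept highest occupancy)")
    a <- a[sort(keep), , drop = FALSE]
  }
  structure_model(data.frame(
    chain = a$chain, resno = a$resno, resid = a$resid, elety = a$elety,
    elesy = if (!is.null(a$elesy)) a$elesy else NA_character_,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

#' Write a structure model as a PDB file
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @export
write_structure <- function(model, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
                   resno = model$resno, resid = model$resid,
                   chain = model$chain, elety = model$elety,
                   elesy = model$elesy)
  invisible(path)
}

#' Bundle frames of a trajectory with a shared topology
#'
#' @param topology A [structure_model()] giving the constant atom order.
#' @param xyz Numeric matrix, one row per frame, 3 * n_atoms columns
#'   (x1, y1, z1, x2, ...).
#' @param stride_ps Interval between stored frames in ps (> 0).
#' @param source Provenance tag: "equilibrium", "voltage" or "umbrella".
#' @return Object of class `frame_series`.
#' @export
frame_series <- function(topology, xyz, stride_ps = 250,
                         source = c("equilibrium", "voltage", "umbrella")) {
  source <- match.arg(source)
  stopifnot(inherits(topology, "structure_model"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(topology))
    stop("frame_series: xyz has ", ncol(xyz), " columns; expected ",
         3 * nrow(topology))
  if (stride_ps <= 0) stop("frame_series: stride_ps must be > 0")
  structure(list(topology = topology, xyz = xyz,
                 stride_ps = stride_ps, source = source),
            class = "frame_series")
}

#' Read a multi-model PDB as a frame series
#'
#' @param path Multi-model PDB file.
#' @inheritParams frame_series
#' @return A [frame_series()].
#' @export
read_frames <- function(path, stride_ps = 250, source = "equilibrium") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- read_structure(path, model = 1L)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frame_series(topo, unclass(xyz), stride_ps = stride_ps, source = source)
}

#' Number of frames in a frame series
#' @param frames A [frame_series()].
#' @export
n_frames <- function(frames) nrow(frames$xyz)

#' Extract one frame of a frame series as a structure model
#' @param frames A [frame_series()].
#' @param i Frame index.
#' @export
get_frame <- function(frames, i) {
  m <- frames$topology
  xyz <- matrix(frames$xyz[i, ], ncol = 3, byrow = TRUE)
  m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
  m
}

#' Select atoms by chain / residue / atom name
#'
#' Returns the indices of exactly the atoms matching the conjunction of
#' the supplied constraints, in deterministic order (chain, then residue
#' number, then atom-name rank with backbone atoms N, CA, CB, C, O
#' first).  An empty selection is an error, never a silent empty result.
#'
#' @param model A [structure_model()].
#' @param chain,resno,elety,resid Optional constraint vectors; `NULL`
#'   places no constraint.
#' @return Integer atom indices.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, elety = NULL,
                         resid = NULL) {
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (!is.null(elety)) keep <- keep & model$elety %in% elety
  if (!is.null(resid)) keep <- keep & model$resid %in% resid
  idx <- which(keep)
  if (!length(idx))
    stop("select_atoms: empty selection (chain=", paste(chain, collapse = ","),
         " resno=", paste(range(resno), collapse = ":"),
         " elety=", paste(elety, collapse = ","), ")")
  rank <- match(model$elety[idx],
                c("N", "CA", "CB", "C", "O"), nomatch = 99L)
  idx[order(model$chain[idx], model$resno[idx], rank,
            model$elety[idx])]
}

atom_coords <- function(model, idx = seq_len(nrow(model))) {
  as.matrix(model[idx, c("x", "y", "z")])
}

#' Place a structure (or every frame of a series) in the gate frame
#'
#' Translates so the centre of mass of the reference residue's CA atoms
#' (one per receptor chain) sits at the origin and rotates so the pore
#' axis -- the principal axis of the gate-residue CA atoms of all four
#' chains -- lies along z, signed so the selectivity-filter side
#' (decreasing residue number along the gate helix) is at negative z.
#' The transform is rigid: pairwise distances are preserved.
#'
#' @param x A [structure_model()] or [frame_series()].
#' @param reference_resno Residue whose CA centre of mass defines the
#'   origin (default 625).
#' @param gate_resnos Residues whose CA atoms define the pore axis.
#' @param chains Receptor chains required to carry the reference
#'   residue.
#' @return Object of the same class, aligned.
#' @export
align_to_gate_origin <- function(x, reference_resno = 625,
                                 gate_resnos = 614:625,
                                 chains = c("A", "B", "C", "D")) {
  if (inherits(x, "frame_series")) {
    out <- x
    for (i in seq_len(n_frames(x))) {
      m <- align_to_gate_origin(get_frame(x, i), reference_resno,
                                gate_resnos, chains)
      out$xyz[i, ] <- as.numeric(t(atom_coords(m)))
    }
    return(out)
  }
  stopifnot(inherits(x, "structure_model"))
  for (ch in chains) {
    if (!any(x$chain == ch & x$resno == reference_resno & x$elety == "CA"))
      stop("align_to_gate_origin: reference residue ", reference_resno,
           " CA missing in chain ", ch)
  }
  ref_idx <- select_atoms(x, chain = chains, resno = reference_resno,
                          elety = "CA")
  centre <- colMeans(atom_coords(x, ref_idx))
  xyz <- sweep(atom_coords(x), 2, centre)
  gate_idx <- select_atoms(x, chain = chains, resno = gate_resnos,
                           elety = "CA")
  g <- xyz[gate_idx, , drop = FALSE]
  gc <- sweep(g, 2, colMeans(g))
  ev <- eigen(crossprod(gc) / nrow(gc), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  # orient: deepest gate residue (toward the selectivity filter) negative
  lo <- which(x$resno[gate_idx] == min(gate_resnos))
  hi <- which(x$resno[gate_idx] == max(gate_resnos))
  dirproj <- sum((colMeans(g[lo, , drop = FALSE]) -
                  colMeans(g[hi, , drop = FALSE])) * axis)
  if (dirproj > 0) axis <- -axis
  r <- rotation_between(axis, c(0, 0, 1))
  xyz <- xyz %*% t(r)
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}
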