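# Synthetic-data generators: every downstream stage of the pipeline can
# be exercised against data with known, recorded ground truth, without
# running molecular dynamics.  Ground truth is always emitted alongside
# the data, never re-derived from it.

# Evaluate expr with a locally-seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Specification of a toy tetrameric channel gate
#'
#' Describes a pseudo-4-fold marker-atom model of an M3-helix gate:
#' one pseudo-backbone (N, CA, CB, C, O) per residue 614-625 per subunit,
#' plus the chi1-defining OG1 atom at the threonine analogue 617.
#' Subunits flagged as bent are kinked at the hinge alanine analogue 618,
#' displacing their upper-gate markers radially outward.
#'
#' @param n_subunits Must be 4 (pseudo-4-fold tetramer).
#' @param bend_flags Logical length 4: is each subunit's M3 kinked at the
#'   hinge (residue 618)?  Order corresponds to chains A, B, C, D.
#' @param chi1_targets Numeric length 4, target chi1 dihedrals (degrees,
#'   in (-180, 180]) of the 617 side chain per subunit.
#' @param ring_radii Named numeric: radial distance (Angstrom) of the CA
#'   ring at the marker residues 617, 621 and 625 for a straight subunit.
#' @param bend_offset Radial outward displacement (Angstrom) of the
#'   625-ring CA of a bent subunit; intermediate residues above the hinge
#'   ramp linearly from zero at the hinge.
#' @param noise_sd Isotropic Gaussian positional noise (Angstrom).
#' @param seed Integer RNG seed; the same seed gives identical output.
#' @return A list of class `toy_gate_spec`.
#' @export
toy_gate_spec <- function(n_subunits = 4,
                          bend_flags = rep(FALSE, 4),
                          chi1_targets = rep(-60, 4),
                          ring_radii = c(r617 = 5, r621 = 5, r625 = 5),
                          bend_offset = 1.5,
                          noise_sd = 0,
                          seed = 1L) {
  if (n_subunits != 4)
    stop("toy_gate_spec: n_subunits must be 4 (tetramer)")
  stopifnot(length(bend_flags) == 4, length(chi1_targets) == 4,
            length(ring_radii) == 3)
  if (any(ring_radii <= 0)) stop("toy_gate_spec: ring_radii must be > 0")
  if (any(chi1_targets <= -180 | chi1_targets > 180))
    stop("toy_gate_spec: chi1_targets must lie in (-180, 180]")
  if (noise_sd < 0) stop("toy_gate_spec: noise_sd must be >= 0")
  structure(list(n_subunits = 4L,
                 bend_flags = as.logical(bend_flags),
                 chi1_targets = as.numeric(chi1_targets),
                 ring_radii = stats::setNames(as.numeric(ring_radii),
                                              c("r617", "r621", "r625")),
                 bend_offset = bend_offset,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "toy_gate_spec")
}

# Helix rise per residue (Angstrom) used by the marker model.
.RISE <- 1.5
.GATE_RESNOS <- 614:625
.HINGE <- 618L

#' Generate a toy tetrameric gate structure
#'
#' Builds the marker-atom tetramer described by a [toy_gate_spec()]:
#' chains A-D at azimuths 0/90/180/270 degrees, CA atoms along each M3
#' analogue with the 625 CA ring at z = 0, five pseudo-backbone atoms
#' per residue and an OG1 at residue 617 placed so that the chi1
#' dihedral (N-CA-CB-OG1) equals the target exactly at zero noise.
#' Bent subunits have all markers above the hinge displaced radially
#' outward, reaching `bend_offset` at residue 625.
#'
#' @param spec A [toy_gate_spec()].
#' @return A `structure_model` (see [read_structure()]) with the
#'   generating [toy_gate_spec()] attached as attribute `ground_truth`.
#' @export
gen_gate_geometry <- function(spec) {
  if (!inherits(spec, "toy_gate_spec")) stop("gen_gate_geometry: need a toy_gate_spec")
  chains <- c("A", "B", "C", "D")
  azim <- c(0, 90, 180, 270) * pi / 180
  rr <- spec$ring_radii
  radius_at <- function(resno) {
    if (resno <= 617) return(rr[["r617"]])
    if (resno <= 621) return(rr[["r617"]] + (rr[["r621"]] - rr[["r617"]]) * (resno - 617) / 4)
    rr[["r621"]] + (rr[["r625"]] - rr[["r621"]]) * (resno - 621) / 4
  }
  rows <- list()
  for (s in seq_len(4)) {
    u <- c(cos(azim[s]), sin(azim[s]), 0)
    tv <- c(-sin(azim[s]), cos(azim[s]), 0)
    ez <- c(0, 0, 1)
    for (resno in .GATE_RESNOS) {
      z <- .RISE * (resno - 625L)
      r <- radius_at(resno)
      if (spec$bend_flags[s] && resno > .HINGE) {
        r <- r + spec$bend_offset * (z - .RISE * (.HINGE - 625L)) /
          (0 - .RISE * (.HINGE - 625L))
      }
      ca <- r * u + z * ez
      loc <- function(a, b, c_) ca + a * u + b * tv + c_ * ez
      resid <- if (resno %in% c(614L)) "SER" else if (resno %in% c(617L, 625L)) "THR"
        else "ALA"
      at <- rbind(
        N  = loc(0.3, -0.8, -1.0),
        CA = ca,
        CB = loc(-1.4, 0.2, 0.2),
        C  = loc(0.3, 0.8, 1.0),
        O  = loc(0.9, 0.8, 1.7))
      for (nm in rownames(at)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chains[s], resno = resno, resid = resid, elety = nm,
          elesy = substr(nm, 1, 1),
          x = at[nm, 1], y = at[nm, 2], z = at[nm, 3],
          stringsAsFactors = FALSE)
      }
      if (resno == 617L) {
        og <- place_atom(at["N", ], at["CA", ], at["CB", ],
                         1.43, 110.5, spec$chi1_targets[s])
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chains[s], resno = resno, resid = resid, elety = "OG1",
          elesy = "O", x = og[1], y = og[2], z = og[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  if (spec$noise_sd > 0) {
    atoms[, c("x", "y", "z")] <- with_seed(spec$seed,
      atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(atoms), sd = spec$noise_sd), ncol = 3))
  }
  m <- structure_model(atoms)
  attr(m, "ground_truth") <- spec
  m
}

#' Generate 1-D particle z-traces with planted crossing events
#'
#' Emulates per-particle axial positions of solvent/ion particles in a
#' channel, with a known (recorded) number of complete downward and
#' upward plane-to-plane passages plus distractor excursions that cross
#' the entry plane but turn back before the exit plane.  Particles rest
#' above the entry plane or below the exit plane between events.
#'
#' @param n_particles Number of particles.
#' @param rate_down,rate_up Aggregate event rates (events per ns) for
#'   complete downward / upward passages over the whole trace set.
#' @param duration Trace length in ns.
#' @param stride Sampling interval in ps; must divide `duration`.
#' @param seed Integer RNG seed.
#' @param entry_z,exit_z Crossing planes in Angstrom (entry above exit).
#' @param distractor_rate Aggregate rate (per ns) of partial excursions;
#'   defaults to the total crossing rate.
#' @return Object of class `particle_traces`: z matrix
#'   (particles x samples), time vector (ps), planted counts and the
#'   event schedule.
#' @export
gen_particle_traces <- function(n_particles, rate_down, rate_up, duration,
                                stride = 10, seed = 1L,
                                entry_z = -6, exit_z = -16,
                                distractor_rate = rate_down + rate_up) {
  if (rate_down < 0 || rate_up < 0 || distractor_rate < 0)
    stop("gen_particle_traces: rates must be >= 0")
  dur_ps <- duration * 1000
  if (abs(dur_ps / stride - round(dur_ps / stride)) > 1e-9)
    stop("gen_particle_traces: stride must divide duration")
  if (entry_z <= exit_z) stop("gen_particle_traces: entry_z must be above exit_z")
  tm <- seq(0, dur_ps, by = stride)
  nt <- length(tm)
  top_rest <- entry_z + 8
  bot_rest <- exit_z - 6
  mid <- (entry_z + exit_z) / 2
  transit <- max(2 * stride, 20)

  with_seed(seed, {
    side <- rep("top", n_particles)
    if (rate_up > 0) {
      nb <- if (rate_down > 0) floor(n_particles / 2) else n_particles
      side[seq_len(nb)] <- "bottom"
    }
    n_dn <- stats::rpois(1, rate_down * duration)
    n_up <- stats::rpois(1, rate_up * duration)
    n_dx <- stats::rpois(1, distractor_rate * duration)
    sched <- data.frame(
      time = stats::runif(n_dn + n_up + n_dx, 0, max(dur_ps - transit, 0)),
      type = rep(c("down", "up", "distractor"), c(n_dn, n_up, n_dx)),
      stringsAsFactors = FALSE)
    sched <- sched[order(sched$time), , drop = FALSE]
    busy_until <- rep(-Inf, n_particles)
    sched$particle <- rep(NA_integer_, nrow(sched))
    for (i in seq_len(nrow(sched))) {
      need <- switch(sched$type[i],
                     down = "top", up = "bottom",
                     distractor = NA_character_)
      free <- busy_until < sched$time[i]
      cand <- if (is.na(need)) which(free) else which(free & side == need)
      if (!length(cand)) next
      p <- cand[sample.int(length(cand), 1)]
      sched$particle[i] <- p
      busy_until[p] <- sched$time[i] + transit
      if (sched$type[i] == "down") side[p] <- "bottom"
      if (sched$type[i] == "up") side[p] <- "top"
    }
    sched <- sched[!is.na(sched$particle), , drop = FALSE]

    # baseline: rest level with clamped jitter that never reaches a plane
    z <- matrix(stats::rnorm(n_particles * nt, sd = 0.5), n_particles, nt)
    side0 <- rep("top", n_particles)
    if (rate_up > 0) {
      nb <- if (rate_down > 0) floor(n_particles / 2) else n_particles
      side0[seq_len(nb)] <- "bottom"
    }
    # fill baselines (recycled column-wise over the matrix)
    base_of <- function(s) if (s == "top") top_rest else bot_rest
    z <- z + ifelse(side0 == "top", top_rest, bot_rest)
    ev_by_p <- split(seq_len(nrow(sched)), sched$particle)
    for (ps in names(ev_by_p)) {
      p <- as.integer(ps)
      s <- side0[p]
      for (i in ev_by_p[[ps]]) {
        t0 <- sched$time[i]; t1 <- t0 + transit
        inwin <- tm >= t0 & tm <= t1
        after <- tm > t1
        ty <- sched$type[i]
        if (ty == "distractor") {
          frac <- (tm[inwin] - t0) / transit
          peak <- 1 - abs(2 * frac - 1)          # 0 -> 1 -> 0
          z[p, inwin] <- base_of(s) + peak * (mid - base_of(s)) +
            stats::rnorm(sum(inwin), sd = 0.3)
        } else {
          dest <- if (ty == "down") bot_rest else top_rest
          frac <- (tm[inwin] - t0) / transit
          z[p, inwin] <- base_of(s) + frac * (dest - base_of(s)) +
            stats::rnorm(sum(inwin), sd = 0.3)
          s <- if (ty == "down") "bottom" else "top"
          if (any(after))
            z[p, after] <- base_of(s) + stats::rnorm(sum(after), sd = 0.5)
        }
      }
    }
    # clamp jitter so baselines and event endpoints never touch a plane,
    # and distractor peaks stay strictly between the planes
    hi_guard <- entry_z + 1.0
    lo_guard <- exit_z - 1.0
    z[z > mid & z < hi_guard] <- ifelse(
      abs(z[z > mid & z < hi_guard] - mid) < abs(z[z > mid & z < hi_guard] - hi_guard),
      mid + 0.5, hi_guard)
    z[z <= mid & z > lo_guard] <- ifelse(
      abs(z[z <= mid & z > lo_guard] - mid) < abs(z[z <= mid & z > lo_guard] - lo_guard),
      mid - 0.5, lo_guard)

    structure(list(
      z = z, time_ps = tm, stride = stride, duration = duration,
      planes = c(entry = entry_z, exit = exit_z),
      planted_downward = sum(sched$type == "down"),
      planted_upward = sum(sched$type == "up"),
      schedule = sched), class = "particle_traces")
  })
}

#' Synthetic stand-in channel with a prescribed minimum gate radius
#'
#' Builds a dense-ring pore model -- stacked rings of carbon
#' pseudo-atoms along z, labelled with the gate residue numbers
#' 614-625 -- whose inscribed-sphere radius profile is analytic: at
#' each ring, radius = ring radius - vdW radius (1.70 for carbon).
#' The narrowest ring sits at the 617 level and is sized to give
#' exactly `rmin_gate` over the gate window.  This is a synthetic
#' stand-in for a deposited channel structure, used to exercise the
#' profiling + classification machinery with known ground truth; it is
#' not a model of any real protein.
#'
#' @param rmin_gate Target minimum gate radius (Angstrom).
#' @param mouth_radius Pore radius at the wide 625 end (Angstrom).
#' @param atoms_per_ring Ring density (default 16; dense enough that
#'   the inscribed sphere cannot leak between atoms).
#' @return A [structure_model()] with attribute `true_rmin_gate`.
#' @export
gen_pore_standin <- function(rmin_gate, mouth_radius = rmin_gate + 2,
                             atoms_per_ring = 16) {
  stopifnot(rmin_gate > 0, mouth_radius >= rmin_gate)
  vdw <- 1.70
  rows <- list()
  for (resno in .GATE_RESNOS) {
    z <- .RISE * (resno - 625L)
    # narrowest at 617, widening linearly toward both ends
    frac <- abs(resno - 617L) / 8
    pore_r <- rmin_gate + (mouth_radius - rmin_gate) * min(frac, 1)
    ring_r <- pore_r + vdw
    th <- 2 * pi * seq_len(atoms_per_ring) / atoms_per_ring
    rows[[length(rows) + 1L]] <- data.frame(
      chain = rep(c("A", "B", "C", "D"), length.out = atoms_per_ring),
      resno = resno, resid = "ALA",
      elety = ifelse(seq_len(atoms_per_ring) <= 4, "CA", "CB"),
      elesy = "C",
      x = ring_r * cos(th), y = ring_r * sin(th), z = z,
      stringsAsFactors = FALSE)
    # backing wall one shell out, as the protein bulk that stops the
    # inscribed sphere escaping sideways out of the tube
    wall_r <- ring_r + 2 * vdw
    rows[[length(rows) + 1L]] <- data.frame(
      chain = rep(c("A", "B", "C", "D"), length.out = atoms_per_ring),
      resno = resno, resid = "ALA", elety = "CG", elesy = "C",
      x = wall_r * cos(th + pi / atoms_per_ring),
      y = wall_r * sin(th + pi / atoms_per_ring), z = z,
      stringsAsFactors = FALSE)
  }
  m <- structure_model(do.call(rbind, rows))
  attr(m, "true_rmin_gate") <- rmin_gate
  m
}

#' Analytic 1-D potential for umbrella-sampling oracles
#'
#' @param form One of `"flat"`, `"harmonic"`, `"double_well"`.
#' @param a Harmonic force constant (kcal/mol/A^2), `U = a z^2 / 2`.
#' @param barrier Double-well barrier height (kcal/mol):
#'   `U = barrier ((z/well)^2 - 1)^2`, wells at +/- `well`, barrier at 0.
#' @param well Double-well minimum position (Angstrom).
#' @return Object of class `analytic_potential` with elements `U` and
#'   `dU` (functions of z) and the parameters.
#' @export
analytic_potential <- function(form = c("flat", "harmonic", "double_well"),
                               a = 1, barrier = 3, well = 1) {
  form <- match.arg(form)
  obj <- switch(form,
    flat = list(U = function(z) rep(0, length(z)),
                dU = function(z) rep(0, length(z))),
    harmonic = list(U = function(z) a * z^2 / 2,
                    dU = function(z) a * z),
    double_well = list(
      U = function(z) barrier * ((z / well)^2 - 1)^2,
      dU = function(z) 4 * barrier * z * (z^2 - well^2) / well^4))
  obj$form <- form
  obj$params <- switch(form, flat = list(), harmonic = list(a = a),
                       double_well = list(barrier = barrier, well = well))
  class(obj) <- "analytic_potential"
  obj
}

#' Overdamped Langevin sampling of a biased 1-D potential
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics with unit
#' mobility on `U(z) + bias_k/2 (z - bias_center)^2`.  The long-run
#' sample law converges to the Boltzmann distribution of the biased
#' potential in the small-step limit.  Stability requires
#' `dt * max|U''| < 2` (for the defaults, dt = 0.01 is safe).
#'
#' @param potential An [analytic_potential()].
#' @param bias_center,bias_k Harmonic umbrella bias (Angstrom,
#'   kcal/mol/A^2); `bias_k = 0` disables the bias.
#' @param n_steps Integration steps.
#' @param dt Time step (reduced units).
#' @param seed Integer RNG seed.
#' @param x0 Initial position; defaults to the bias centre.
#' @param kT Thermal energy (kcal/mol); 0.596 at 300 K.
#' @param sample_stride Record every `sample_stride`-th step.
#' @return Numeric vector of sampled positions.
#' @export
simulate_langevin_1d <- function(potential, bias_center = 0, bias_k = 0,
                                 n_steps = 1e5, dt = 0.01, seed = 1L,
                                 x0 = bias_center, kT = 0.596,
                                 sample_stride = 1L) {
  stopifnot(inherits(potential, "analytic_potential"))
  if (!is.finite(potential$U(x0)))
    stop("simulate_langevin_1d: potential not finite at the start point")
  with_seed(seed, {
    x <- x0
    keep <- seq(sample_stride, n_steps, by = sample_stride)
    out <- numeric(length(keep))
    noise <- sqrt(2 * kT * dt)
    j <- 1L
    xi <- stats::rnorm(n_steps)
    for (i in seq_len(n_steps)) {
      f <- -potential$dU(x) - bias_k * (x - bias_center)
      x <- x + dt * f + noise * xi[i]
      if (!is.finite(x)) stop("simulate_langevin_1d: trajectory diverged (non-finite position)")
      if (j <= length(keep) && i == keep[j]) { out[j] <- x; j <- j + 1L }
    }
    out
  })
}

#' Markov-switching synthetic gate-feature trajectory
#'
#' Emits per-frame feature vectors from a discrete-state Markov chain:
#' each frame's features are its state centroid plus noise, applied on
#' the circle (wrapped) for angular features and additively otherwise.
#' True state labels are recorded per frame.
#'
#' @param centroids Numeric matrix, one row per state, named columns.
#' @param transition Row-stochastic transition matrix (rows sum to 1
#'   within 1e-9).
#' @param n_frames Number of frames.
#' @param noise Per-feature noise SD (recycled); degrees for angular
#'   features, Angstrom for distances.
#' @param seed Integer RNG seed.
#' @param angular_cols Names (or logical mask) of angular columns;
#'   defaults to columns whose name starts with "chi".
#' @return List: `features` (n_frames x p), `labels` (true state ids),
#'   `centroids`, `angular_cols`.
#' @export
gen_state_trajectory <- function(centroids, transition, n_frames,
                                 noise = 0, seed = 1L,
                                 angular_cols = grepl("^chi", colnames(centroids))) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids); p <- ncol(centroids)
  transition <- as.matrix(transition)
  if (nrow(transition) != k || ncol(transition) != k ||
      any(abs(rowSums(transition) - 1) > 1e-9) || any(transition < 0))
    stop("gen_state_trajectory: transition matrix must be row-stochastic")
  if (is.character(angular_cols)) angular_cols <- colnames(centroids) %in% angular_cols
  if (any(wrap_angle(centroids[, angular_cols, drop = FALSE]) !=
          centroids[, angular_cols, drop = FALSE]))
    stop("gen_state_trajectory: centroid angles must lie in (-180, 180]")
  noise <- rep_len(noise, p)
  with_seed(seed, {
    labels <- integer(n_frames)
    labels[1] <- sample.int(k, 1)
    if (n_frames > 1) {
      u <- stats::runif(n_frames - 1)
      cum <- t(apply(transition, 1, cumsum))
      for (i in 2:n_frames)
        labels[i] <- 1L + sum(u[i - 1] > cum[labels[i - 1], ])
    }
    eps <- matrix(stats::rnorm(n_frames * p), n_frames, p) %*% diag(noise, p)
    feats <- centroids[labels, , drop = FALSE] + eps
    feats[, angular_cols] <- wrap_angle(feats[, angular_cols, drop = FALSE])
    colnames(feats) <- colnames(centroids)
    list(features = feats, labels = labels, centroids = centroids,
         angular_cols = which(angular_cols))
  })
}
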