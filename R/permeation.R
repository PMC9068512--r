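# Directional permeation analysis: two-plane hysteresis crossing
# counter, permeation rates with block averaging, frame-interval
# recalibration, z/time occupancy maps, continuously-open intervals,
# and conversion of ion counts to conductance.

#' Count complete plane-to-plane passages in particle z-traces
#'
#' A particle scores one downward event per completed passage: after
#' crossing the entry plane downward it reaches the exit plane before
#' re-crossing the entry plane backward (two-plane hysteresis), so
#' partial excursions between the planes score nothing and re-entries
#' after a completed passage can score again.  Upward events are the
#' mirror image.  Crossings are detected from the sequence of
#' plane-relative regions, so a passage that jumps both planes within a
#' single stride still scores.
#'
#' @param traces A [gen_particle_traces()] result, or a numeric matrix
#'   of z positions (particles x samples), or a single trace vector.
#' @param entry_z,exit_z Crossing planes in Angstrom; `entry_z` must be
#'   above `exit_z` for the downward convention.
#' @param time_ps Optional sample times (ps); taken from the trace set
#'   when available.  Must be strictly increasing.
#' @return Object of class `crossing_ledger`: `events` data.frame
#'   (particle, direction, entry_time_ps, exit_time_ps), `n_down`,
#'   `n_up`, `total_time` (ns) and the planes.
#' @export
count_crossings <- function(traces, entry_z = -6, exit_z = -16,
                            time_ps = NULL) {
  if (inherits(traces, "particle_traces")) {
    if (is.null(time_ps)) time_ps <- traces$time_ps
    z <- traces$z
  } else if (is.matrix(traces)) {
    z <- traces
  } else {
    z <- matrix(as.numeric(traces), nrow = 1)
  }
  if (entry_z <= exit_z)
    stop("count_crossings: entry_z must be above exit_z")
  if (is.null(time_ps)) time_ps <- seq_len(ncol(z)) - 1
  if (length(time_ps) != ncol(z) || any(diff(time_ps) <= 0))
    stop("count_crossings: sample times must be strictly increasing")
  S <- (z > entry_z) - (z < exit_z)       # region per sample: A=1, M=0, B=-1
  p_acc <- integer(); dir_acc <- integer()
  t_in <- numeric(); t_out <- numeric()
  for (p in seq_len(nrow(z))) {
    row <- S[p, ]
    keep <- which(row != 0L)
    if (length(keep) < 2) next
    v <- row[keep]
    tr <- which(v[-1] != v[-length(v)])
    if (!length(tr)) next
    p_acc <- c(p_acc, rep.int(p, length(tr)))
    dir_acc <- c(dir_acc, v[tr])
    t_in <- c(t_in, time_ps[keep[tr]])
    t_out <- c(t_out, time_ps[keep[tr + 1L]])
  }
  events <- data.frame(particle = p_acc,
                       direction = as.character(ifelse(dir_acc == 1L,
                                                       "down", "up")),
                       entry_time_ps = t_in, exit_time_ps = t_out,
                       stringsAsFactors = FALSE)
  structure(list(events = events,
                 n_down = sum(events$direction == "down"),
                 n_up = sum(events$direction == "up"),
                 total_time = (max(time_ps) - min(time_ps)) / 1000,
                 planes = c(entry = entry_z, exit = exit_z)),
            class = "crossing_ledger")
}

#' @export
print.crossing_ledger <- function(x, ...) {
  cat(sprintf("crossing_ledger: %d down, %d up over %.1f ns (planes %g / %g A)\n",
              x$n_down, x$n_up, x$total_time, x$planes[1], x$planes[2]))
  invisible(x)
}

#' Permeation rate from a crossing ledger
#'
#' Whole-trace rate is the downward event count divided by the total
#' time.  In block mode, events are counted in fixed-length blocks
#' placed at a fixed spacing (defaults: 40-ns blocks every 200 ns) and
#' one rate per block is returned alongside their mean.
#'
#' @param ledger A [count_crossings()] ledger.
#' @param direction "down" (default) or "up".
#' @param blocks `NULL` for the whole-trace rate, or
#'   `c(length_ns, spacing_ns)`.
#' @return List: `rate` (events per ns), and in block mode
#'   `block_rates` and `block_starts_ns`.
#' @export
permeation_rate <- function(ledger, direction = "down", blocks = NULL) {
  stopifnot(inherits(ledger, "crossing_ledger"))
  if (ledger$total_time <= 0) stop("permeation_rate: zero-duration ledger")
  tns <- ledger$events$exit_time_ps[ledger$events$direction == direction] / 1000
  if (is.null(blocks))
    return(list(rate = length(tns) / ledger$total_time))
  stopifnot(length(blocks) == 2, all(blocks > 0))
  starts <- seq(0, ledger$total_time - blocks[1], by = blocks[2])
  if (!length(starts)) stop("permeation_rate: trace shorter than one block")
  br <- vapply(starts, function(s)
    sum(tns >= s & tns < s + blocks[1]) / blocks[1], numeric(1))
  list(rate = mean(br), block_rates = br, block_starts_ns = starts)
}

#' Recalibration of coarse-stride counts against fine-stride counts
#'
#' Ordinary least squares of per-segment event counts observed at a
#' fine snapshot interval on matched counts at a coarse interval.  Both
#' the intercept fit and the through-origin fit are reported; the
#' recalibration factor is the slope.
#'
#' @param fine_counts,coarse_counts Matched per-segment counts (>= 3
#'   segments).
#' @return List: `slope`, `intercept`, `r_squared` (intercept fit) and
#'   `slope_origin`, `r_squared_origin` (through-origin fit).
#' @export
interval_recalibration <- function(fine_counts, coarse_counts) {
  if (length(fine_counts) != length(coarse_counts) || length(fine_counts) < 3)
    stop("interval_recalibration: need >= 3 matched segments")
  if (stats::var(coarse_counts) < 1e-12)
    stop("interval_recalibration: coarse counts have zero variance")
  fit <- stats::lm(fine_counts ~ coarse_counts)
  fit0 <- stats::lm(fine_counts ~ coarse_counts + 0)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       slope_origin = unname(stats::coef(fit0)[1]),
       r_squared_origin = summary(fit0)$r.squared)
}

#' z/time occupancy map of particles in the pore region
#'
#' Counts particles per (z-bin, time-bin) cell within a lateral
#' cylinder around the pore axis.  Column sums per time bin equal the
#' number of in-cylinder particle observations in that bin, so totals
#' are conserved.
#'
#' @param z Matrix of particle z positions (particles x samples),
#'   Angstrom.
#' @param time_ps Sample times (ps).
#' @param r_xy Optional matrix of lateral distances from the axis; rows
#'   outside `cylinder_radius` are excluded per sample.
#' @param z_range Axial range (default -45..10 Angstrom).
#' @param z_bin z bin width (Angstrom).
#' @param time_bin Time bin width (ns).
#' @param cylinder_radius Lateral cutoff (Angstrom, default 5).
#' @return Object of class `occupancy_map`: `counts` (z-bins x
#'   time-bins), bin edges.
#' @export
occupancy_map <- function(z, time_ps, r_xy = NULL,
                          z_range = c(-45, 10), z_bin = 1, time_bin = 1,
                          cylinder_radius = 5) {
  z <- as.matrix(z)
  if (!ncol(z)) stop("occupancy_map: empty frame range")
  stopifnot(length(time_ps) == ncol(z))
  z_edges <- seq(z_range[1], z_range[2], by = z_bin)
  t_edges <- seq(min(time_ps), max(time_ps) + 1e-9, by = time_bin * 1000)
  if (t_edges[length(t_edges)] < max(time_ps))
    t_edges <- c(t_edges, t_edges[length(t_edges)] + time_bin * 1000)
  counts <- matrix(0L, length(z_edges) - 1, length(t_edges) - 1)
  tb <- findInterval(time_ps, t_edges, rightmost.closed = TRUE)
  for (jt in seq_len(ncol(z))) {
    zi <- z[, jt]
    if (!is.null(r_xy)) zi <- zi[r_xy[, jt] <= cylinder_radius]
    zi <- zi[zi >= z_range[1] & zi <= z_range[2]]
    if (!length(zi)) next
    zb <- findInterval(zi, z_edges, rightmost.closed = TRUE)
    for (b in zb) counts[b, tb[jt]] <- counts[b, tb[jt]] + 1L
  }
  structure(list(counts = counts, z_edges = z_edges, t_edges_ps = t_edges),
            class = "occupancy_map")
}

#' Continuously-open intervals of the gate window
#'
#' A time bin is "open" when every z-cell inside the gate window holds
#' at least one particle.  Returns the maximal runs of open time bins
#' and the total open time.
#'
#' @param map An [occupancy_map()].
#' @param gate_window Length-2 z-interval (Angstrom) inside the map
#'   range.
#' @return List: `intervals` data.frame (start_ns, end_ns),
#'   `total_open_ns`, `open` logical per time bin.
#' @export
open_intervals <- function(map, gate_window) {
  stopifnot(inherits(map, "occupancy_map"))
  zc <- (map$z_edges[-1] + map$z_edges[-length(map$z_edges)]) / 2
  sel <- zc >= gate_window[1] & zc <= gate_window[2]
  if (!any(sel))
    stop("open_intervals: gate window outside the occupancy map range")
  open <- apply(map$counts[sel, , drop = FALSE] >= 1, 2, all)
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- data.frame(
    start_ns = map$t_edges_ps[starts[r$values]] / 1000,
    end_ns = map$t_edges_ps[ends[r$values] + 1] / 1000)
  list(intervals = iv,
       total_open_ns = sum(iv$end_ns - iv$start_ns),
       open = open)
}

#' Conductance from ion permeation counts
#'
#' `G = n q e / (t V)` expressed in picosiemens, for `n` permeation
#' events of ions carrying `charge` elementary charges over
#' `total_time_ns` nanoseconds under `voltage_mV` millivolts.
#'
#' @param n_events Number of complete ion passages.
#' @param total_time_ns Simulated time (ns, > 0).
#' @param voltage_mV Applied voltage (mV, nonzero).
#' @param charge Elementary charges per ion (default 1).
#' @return Conductance in pS.
#' @examples
#' conductance_from_counts(15, 360, 600)  # ~11.1 pS
#' @export
conductance_from_counts <- function(n_events, total_time_ns, voltage_mV,
                                    charge = 1) {
  if (total_time_ns <= 0) stop("conductance_from_counts: zero-duration input")
  if (voltage_mV == 0) stop("conductance_from_counts: zero voltage")
  e <- 1.602176634e-19                      # C
  g_S <- n_events * charge * e / (total_time_ns * 1e-9 * voltage_mV * 1e-3)
  g_S * 1e12
}
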