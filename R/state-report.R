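# Conductance-state assignment: group conformational clusters into
# discrete states by water permittivity (exact 1-D minimum-variance
# partition), corroborated by ion conductance and PMF barriers, and an
# end-to-end pipeline over synthetic ground-truth data.

# Exact 1-D partition of sorted values into g contiguous groups
# minimising within-group sum of squares (dynamic programme).  Returns
# group id per value (in input order).
.optimal_1d_partition <- function(x, g) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ssq <- function(i, j) {           # within-SS of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, g, n)
  B <- matrix(0L, g, n)
  for (j in 1:n) { D[1, j] <- ssq(1, j); B[1, j] <- 1L }
  if (g > 1) for (gi in 2:g) for (j in gi:n) {
    for (i in gi:j) {
      v <- D[gi - 1, i - 1] + ssq(i, j)
      if (v < D[gi, j]) { D[gi, j] <- v; B[gi, j] <- i }
    }
  }
  grp_sorted <- integer(n)
  j <- n
  for (gi in g:1) {
    i <- B[gi, j]
    grp_sorted[i:j] <- gi
    j <- i - 1L
    if (j < 1) break
  }
  grp <- integer(n)
  grp[ord] <- grp_sorted
  grp
}

#' Assign conformational clusters to discrete conductance states
#'
#' Groups clusters into `n_states` tiers by their mean water
#' permittivity using an exact 1-D minimum-within-variance partition
#' (the optimum that 1-D k-means / Jenks breaks seek), labels the tiers
#' C, O1, O2, O3 in order of increasing permittivity, and reports the
#' corroborating ion-conductance and PMF-barrier columns per tier.  A
#' higher PMF barrier co-occurring with a higher state is flagged as an
#' inconsistency (warning plus flag), never silently reordered.  O4 is
#' a reserved label that is never assigned automatically.
#'
#' @param metrics data.frame with columns `cluster`, `permittivity`
#'   (events/ns) and optionally `permittivity_sd`, `conductance` (pS),
#'   `conductance_sd`, `barrier` (kcal/mol).
#' @param n_states Number of states to form (default 4; reduced with a
#'   warning when there are fewer clusters, or when clusters are
#'   indistinguishable).
#' @return Object of class `state_assignment`: the metrics table with a
#'   `state` column, a per-state summary, and `inconsistent` flag.
#' @export
assign_states <- function(metrics, n_states = 4) {
  stopifnot(is.data.frame(metrics),
            all(c("cluster", "permittivity") %in% names(metrics)))
  if (n_states > 4) stop("assign_states: at most 4 states (O4 is reserved)")
  k <- nrow(metrics)
  if (k < 1) stop("assign_states: no clusters")
  g <- n_states
  if (k < g) {
    warning("assign_states: fewer clusters (", k, ") than states (", g,
            "); reducing to ", k, " states")
    g <- k
  }
  if (length(unique(metrics$permittivity)) == 1L && g > 1) {
    warning("assign_states: all permittivities equal; single state assigned")
    g <- 1L
  }
  grp <- .optimal_1d_partition(metrics$permittivity, g)
  means <- tapply(metrics$permittivity, grp, mean)
  ord <- order(means)                       # increasing permittivity
  state_names <- c("C", "O1", "O2", "O3")[seq_len(g)]
  lab <- stats::setNames(state_names, names(means)[ord])
  metrics$state <- unname(lab[as.character(grp)])
  agg <- function(col, f = mean) {
    if (!col %in% names(metrics)) return(rep(NA_real_, g))
    as.numeric(tapply(metrics[[col]], metrics$state, f)[state_names])
  }
  summary <- data.frame(
    state = state_names,
    n_clusters = as.integer(table(metrics$state)[state_names]),
    permittivity = agg("permittivity"),
    conductance = agg("conductance"),
    barrier = agg("barrier"),
    stringsAsFactors = FALSE)
  inconsistent <- FALSE
  b <- summary$barrier[!is.na(summary$barrier)]
  if (length(b) >= 2 && any(diff(b) > 1e-9)) {
    inconsistent <- TRUE
    warning("assign_states: PMF barrier increases with state level; ",
            "flagged as inconsistent")
  }
  structure(list(clusters = metrics, summary = summary,
                 inconsistent = inconsistent),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat("state_assignment:\n")
  print(x$summary, row.names = FALSE)
  if (x$inconsistent) cat("  [!] barrier/state ordering inconsistent\n")
  invisible(x)
}

.validate_pipeline_config <- function(config) {
  need <- c("centroids", "transition", "n_frames", "noise", "water_rates",
            "seed", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("run_pipeline: config missing field(s): ",
         paste(miss, collapse = ", "))
  config$centroids <- as.matrix(config$centroids)
  config$transition <- as.matrix(config$transition)
  k <- nrow(config$centroids)
  if (length(config$water_rates) != k)
    stop("run_pipeline: water_rates must have one rate per planted state")
  if (is.null(config$stride_ps)) config$stride_ps <- 250
  if (is.null(config$n_states)) config$n_states <- min(4, k)
  if (is.null(config$perplexity)) config$perplexity <- 30
  if (is.null(config$n_iter)) config$n_iter <- 400
  if (is.null(config$bandwidth_frac)) config$bandwidth_frac <- 0.02
  if (is.null(config$voltage_mV)) config$voltage_mV <- 600
  config
}

#' End-to-end synthetic conductance-state pipeline
#'
#' Runs the whole analysis on generated data with known ground truth:
#' a Markov-switching gate-feature trajectory is emitted, water
#' permeation events are planted at each hidden state's rate along the
#' same timeline, the features are embedded and clustered
#' ([identify_clusters()]), permeation events are counted with the
#' two-plane hysteresis counter and attributed to the cluster active at
#' their completion time, per-cluster permittivities are grouped into
#' conductance states ([assign_states()]), and all tables plus a JSON
#' summary are written to the run directory.  Fully reproducible under
#' a fixed seed.
#'
#' @param config Named list (or path to a YAML file): `centroids`
#'   (states x features, angular columns named chi*), `transition`
#'   (row-stochastic), `n_frames`, `noise` (per-feature SD),
#'   `water_rates` (events/ns per hidden state), `seed`, `out_dir`,
#'   and optional `stride_ps` (250), `n_states`, `perplexity`,
#'   `n_iter`, `bandwidth_frac`, `voltage_mV`.
#' @return Object of class `pipeline_report` (invisibly written to
#'   `out_dir`): cluster set, metrics table, state assignment, summary
#'   list, output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("run_pipeline: reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  config <- .validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # 1. synthetic feature trajectory with hidden state labels
  traj <- gen_state_trajectory(config$centroids, config$transition,
                               config$n_frames, config$noise,
                               seed = config$seed)
  stride_ns <- config$stride_ps / 1000
  duration_ns <- config$n_frames * stride_ns

  # 2. water permeation events planted at each hidden state's rate
  events <- with_seed(config$seed + 1L, {
    counts <- stats::rpois(config$n_frames,
                           config$water_rates[traj$labels] * stride_ns)
    frame <- rep(seq_len(config$n_frames), counts)
    data.frame(frame = frame,
               time_ps = (frame - 1 + stats::runif(length(frame))) *
                 config$stride_ps)
  })
  traces <- .traces_from_schedule(events$time_ps, duration_ns,
                                  stride = min(config$stride_ps, 10))
  ledger <- count_crossings(traces)

  # 3. clustering on features only (no ground-truth leakage)
  cs <- identify_clusters(traj$features,
                          perplexity = config$perplexity,
                          seed = config$seed, n_iter = config$n_iter,
                          bandwidth_frac = config$bandwidth_frac)

  # 4. per-cluster permittivity: events attributed to the cluster
  #    active at their completion time
  ev_frame <- pmin(config$n_frames,
                   floor(ledger$events$exit_time_ps[
                     ledger$events$direction == "down"] /
                       config$stride_ps) + 1L)
  ev_cluster <- cs$labels[ev_frame]
  cl_names <- names(cs$sizes)
  time_in <- vapply(cl_names, function(cl)
    sum(cs$labels == cl) * stride_ns, numeric(1))
  n_ev <- vapply(cl_names, function(cl) sum(ev_cluster == cl), numeric(1))
  metrics <- data.frame(cluster = cl_names,
                        n_frames = as.integer(cs$sizes[cl_names]),
                        time_ns = time_in,
                        n_events = as.integer(n_ev),
                        permittivity = n_ev / time_in,
                        stringsAsFactors = FALSE)

  # 5. state assignment
  sa <- assign_states(metrics[, c("cluster", "permittivity")],
                      n_states = config$n_states)
  metrics$state <- sa$clusters$state[match(metrics$cluster,
                                           sa$clusters$cluster)]

  # 6. outputs
  paths <- list(
    assignments = file.path(config$out_dir, "frame_assignments.tsv"),
    embedding = file.path(config$out_dir, "embedding.tsv"),
    stats = file.path(config$out_dir, "cluster_stats.tsv"),
    metrics = file.path(config$out_dir, "cluster_metrics.tsv"),
    summary_json = file.path(config$out_dir, "summary.json"),
    summary_md = file.path(config$out_dir, "summary.md"))
  utils::write.table(
    data.frame(frame = seq_len(config$n_frames), cluster = cs$labels,
               true_state = traj$labels),
    paths$assignments, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(frame = seq_len(config$n_frames),
               x = cs$embedding[, 1], y = cs$embedding[, 2]),
    paths$embedding, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cs$stats, paths$stats, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(metrics, paths$metrics, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summary <- list(
    n_frames = config$n_frames,
    n_clusters = length(cs$sizes),
    cluster_sizes = as.list(cs$sizes),
    n_water_events_counted = ledger$n_down,
    n_water_events_planted = nrow(events),
    states = stats::setNames(as.list(sa$summary$permittivity),
                             sa$summary$state),
    seed = config$seed)
  jsonlite::write_json(summary, paths$summary_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  md <- c("# Conductance-state pipeline summary", "",
          sprintf("- frames: %d", config$n_frames),
          sprintf("- clusters: %d (%s)", length(cs$sizes),
                  paste(sprintf("%s=%d", names(cs$sizes), cs$sizes),
                        collapse = ", ")),
          sprintf("- water events counted/planted: %d/%d",
                  ledger$n_down, nrow(events)), "",
          "| state | clusters | permittivity (1/ns) |",
          "|-------|----------|---------------------|",
          sprintf("| %s | %d | %.3f |", sa$summary$state,
                  sa$summary$n_clusters, sa$summary$permittivity))
  writeLines(md, paths$summary_md)
  structure(list(clusters = cs, metrics = metrics, assignment = sa,
                 ledger = ledger, summary = summary, paths = paths,
                 truth = list(labels = traj$labels,
                              water_rates = config$water_rates)),
            class = "pipeline_report")
}

# Build a minimal particle trace set realising a given schedule of
# downward passage times (one particle per event) plus one idle
# particle, so the counter sees realistic input.
.traces_from_schedule <- function(times_ps, duration_ns, stride = 10) {
  dur_ps <- duration_ns * 1000
  tm <- seq(0, dur_ps, by = stride)
  n <- length(times_ps) + 1L
  z <- matrix(2 + 0, n, length(tm))
  transit <- max(2 * stride, 20)
  for (i in seq_along(times_ps)) {
    t0 <- min(times_ps[i], dur_ps - transit)
    sel <- tm >= t0 & tm <= t0 + transit
    z[i, sel] <- 2 + (tm[sel] - t0) / transit * (-24)
    z[i, tm > t0 + transit] <- -22
  }
  structure(list(z = z, time_ps = tm, stride = stride,
                 duration = duration_ns,
                 planes = c(entry = -6, exit = -16),
                 planted_downward = length(times_ps), planted_upward = 0L,
                 schedule = data.frame(time = times_ps, type = "down",
                                       particle = seq_along(times_ps))),
            class = "particle_traces")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %d clusters, %d water events\n",
              length(x$clusters$sizes), x$ledger$n_down))
  print(x$assignment)
  invisible(x)
}
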