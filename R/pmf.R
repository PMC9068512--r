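# Umbrella-sampling analysis: self-consistent WHAM unbiasing of
# harmonically biased windows into a 1-D potential of mean force,
# autocorrelation-time estimation (e^-2 decay rule), Monte Carlo
# bootstrap errors with N/t subsampling, and split-half convergence.

#' Umbrella-sampling window record
#'
#' @param anchor Bias anchor position (Angstrom).
#' @param samples Recorded reaction-coordinate series (Angstrom).
#' @param spring_k Harmonic bias force constant (kcal/mol/A^2,
#'   default 25).  Zero is allowed for the unbiased one-window limit,
#'   in which WHAM reduces to `F = -kT log p`.
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(anchor, samples, spring_k = 25) {
  if (spring_k < 0) stop("umbrella_window: spring_k must be >= 0")
  samples <- as.numeric(samples)
  if (length(samples) < 100)
    warning("umbrella_window: fewer than 100 samples; estimates will be poor")
  structure(list(anchor = anchor, spring_k = spring_k, samples = samples),
            class = "umbrella_window")
}

# Core WHAM iteration on a fixed bin grid.  Returns unanchored free
# energies per bin (kcal/mol; +Inf on empty bins when allowed).
.wham_core <- function(windows, edges, kT, tol, max_iter,
                       allow_empty = FALSE) {
  nb <- length(edges) - 1
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- vapply(windows, function(w) {
    b <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    as.numeric(tabulate(b[b >= 1 & b <= nb], nb))
  }, numeric(nb))                              # nb x n_win
  M <- rowSums(counts)
  N <- vapply(windows, function(w) length(w$samples), numeric(1))
  if (!allow_empty && length(windows) > 1) {
    ord <- order(vapply(windows, `[[`, numeric(1), "anchor"))
    for (q in seq_len(length(ord) - 1)) {
      hi <- max(windows[[ord[q]]]$samples)
      lo <- min(windows[[ord[q + 1]]]$samples)
      if (lo - hi > (edges[2] - edges[1]))
        stop("wham: coverage gap between z = ", round(hi, 2), " and z = ",
             round(lo, 2), " (windows ", ord[q], " and ", ord[q + 1],
             " do not overlap)")
    }
  }
  bias <- matrix(0, nb, length(windows))
  for (i in seq_along(windows))
    bias[, i] <- windows[[i]]$spring_k / 2 *
      (centers - windows[[i]]$anchor)^2
  cmat <- exp(-bias / kT)                      # nb x n_win
  f <- rep(0, length(windows))                 # window free-energy constants
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(cmat %*% (N * exp(f / kT)))
    p <- ifelse(denom > 0, M / denom, 0)
    fn <- -kT * log(pmax(as.numeric(crossprod(cmat, p)), 1e-300))
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  denom <- as.numeric(cmat %*% (N * exp(f / kT)))
  p <- ifelse(denom > 0, M / denom, 0)
  F_ <- ifelse(p > 0, -kT * log(p), Inf)
  list(centers = centers, F = F_, f = f, M = M, iterations = it,
       converged = it < max_iter)
}

.anchor_pmf <- function(F_, anchor = c("min", "mean")) {
  anchor <- match.arg(anchor)
  fin <- is.finite(F_)
  off <- if (anchor == "min") min(F_[fin]) else mean(F_[fin])
  F_ - off
}

#' WHAM estimate of a 1-D potential of mean force
#'
#' Iterates the self-consistent weighted-histogram equations until the
#' window free-energy constants change by less than `tol`, assembles
#' the unbiased density and converts it to a free-energy profile
#' `F = -kT log p`, anchored so its minimum is zero.  Windows must
#' jointly cover the sampled range; an interior run of empty bins is a
#' coverage-gap error naming the gap.
#'
#' @param windows List of [umbrella_window()]s.
#' @param bin_width Histogram bin width (Angstrom, default 0.1).
#' @param kT Thermal energy (kcal/mol; 0.596 at 300 K).
#' @param tol Convergence tolerance on the window constants (kcal/mol).
#' @param max_iter Iteration cap.
#' @param min_count Bins holding fewer total samples than this are
#'   dropped from the reported profile (they carry only statistical
#'   noise at the sampling tails); default 5.
#' @return Object of class `pmf_profile`: data.frame `profile`
#'   (z, F, sd), window constants `f`, iteration count.
#' @export
wham <- function(windows, bin_width = 0.1, kT = 0.596, tol = 1e-8,
                 max_iter = 1e5, min_count = 5) {
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, TRUE, "umbrella_window")))
  rng <- range(unlist(lapply(windows, `[[`, "samples")))
  edges <- seq(floor(rng[1] / bin_width) * bin_width,
               ceiling(rng[2] / bin_width) * bin_width, by = bin_width)
  core <- .wham_core(windows, edges, kT, tol, max_iter)
  F_ <- core$F
  F_[core$M < min_count] <- Inf
  if (!any(is.finite(F_)))
    stop("wham: no bin holds at least ", min_count,
         " samples; windows are too thin to estimate a profile")
  F_ <- .anchor_pmf(F_)
  keep <- is.finite(F_)
  structure(list(profile = data.frame(z = core$centers[keep],
                                      F = F_[keep], sd = NA_real_),
                 edges = edges, f = core$f, kT = kT,
                 iterations = core$iterations,
                 converged = core$converged),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf(
    "pmf_profile: %d bins over [%.2f, %.2f] A, max F = %.2f kcal/mol (%d WHAM iterations)\n",
    nrow(x$profile), min(x$profile$z), max(x$profile$z),
    max(x$profile$F), x$iterations))
  invisible(x)
}

#' Barrier height of a PMF profile
#'
#' Maximum free energy between the two outermost local minima --
#' for a double-well profile, the central barrier above the deeper
#' well (the profile minimum is anchored at zero, so this is just the
#' maximum over the inter-well region).
#'
#' @param pmf A [wham()] profile.
#' @param region Optional z-interval to search for the barrier; by
#'   default the span between the two lowest local minima of the
#'   (lightly smoothed) profile, i.e. the inter-well region of a
#'   double-well.
#' @return Barrier height in kcal/mol.
#' @export
pmf_barrier <- function(pmf, region = NULL) {
  pr <- pmf$profile
  if (is.null(region)) {
    f <- stats::runmed(pr$F, 5)
    n <- length(f)
    is_min <- c(TRUE, f[2:(n - 1)] <= f[1:(n - 2)] &
                       f[2:(n - 1)] <= f[3:n], TRUE)
    mins <- which(is_min)
    # pick the pair of wells with the most prominent saddle between them
    best <- c(h = -Inf, i = 1, j = n)
    for (a in seq_along(mins)) {
      for (b in seq_along(mins)) {
        if (b <= a) next
        i <- mins[a]; j <- mins[b]
        saddle <- max(f[i:j])
        h <- saddle - max(f[i], f[j])
        if (h > best["h"]) best <- c(h = h, i = i, j = j)
      }
    }
    region <- range(pr$z[c(best["i"], best["j"])])
  }
  sel <- pr$z >= region[1] & pr$z <= region[2]
  max(pr$F[sel]) - min(pr$F[sel])
}

#' Autocorrelation time by the e^-2 decay rule
#'
#' The smallest lag at which the normalised autocorrelation of the
#' series has fallen to e^-2 (~0.1353) or below; 1 if the series is
#' already uncorrelated at lag 1.
#'
#' @param x Numeric series (length >= 10).
#' @return Integer lag in frames.
#' @export
autocorrelation_time <- function(x) {
  n <- length(x)
  if (n < 10) stop("autocorrelation_time: series too short (need >= 10)")
  if (stats::var(x) < 1e-24)
    stop("autocorrelation_time: constant series, autocorrelation undefined")
  thr <- exp(-2)
  lag <- 0L
  lag_max <- 100L
  repeat {
    lag_max <- min(lag_max, n - 1L)
    rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                                 demean = TRUE)$acf)[-1]
    hit <- which(rho <= thr)
    if (length(hit)) return(as.integer(hit[1]))
    if (lag_max >= n - 1L) return(as.integer(n - 1L))
    lag_max <- lag_max * 4L
  }
}

#' Bootstrap error bars for a WHAM PMF with N/t subsampling
#'
#' Monte Carlo bootstrap: each replicate resamples every window's
#' series with replacement at the reduced size `floor(N / t)`, where
#' `t` is that window's autocorrelation time (e^-2 rule), then re-runs
#' WHAM on the common bin grid.  The per-bin standard deviation across
#' replicates is the error estimate.
#'
#' @param windows List of [umbrella_window()]s.
#' @param n_boot Number of replicates (>= 20).
#' @param seed Integer RNG seed.
#' @param anchor Per-replicate anchoring: "min" (profile minimum at 0,
#'   default) or "mean" (profile mean at 0).
#' @inheritParams wham
#' @return A `pmf_profile` whose `sd` column holds the bootstrap SD,
#'   with the replicate matrix in `$replicates` and per-window
#'   autocorrelation times in `$autocorr_times`.
#' @export
bootstrap_pmf <- function(windows, n_boot = 50, seed = 1L,
                          bin_width = 0.1, kT = 0.596, tol = 1e-6,
                          max_iter = 1e4, anchor = "min", min_count = 5) {
  if (n_boot < 20) stop("bootstrap_pmf: n_boot must be >= 20")
  tcorr <- vapply(windows, function(w) autocorrelation_time(w$samples),
                  integer(1))
  Ns <- vapply(windows, function(w) length(w$samples), integer(1))
  if (any(tcorr >= Ns))
    stop("bootstrap_pmf: autocorrelation time >= sample count in window ",
         which(tcorr >= Ns)[1])
  base <- wham(windows, bin_width = bin_width, kT = kT, tol = tol,
               max_iter = max_iter, min_count = min_count)
  edges <- base$edges
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      wrep <- lapply(seq_along(windows), function(i) {
        m <- max(1L, Ns[i] %/% tcorr[i])
        s <- windows[[i]]$samples[sample.int(Ns[i], m, replace = TRUE)]
        umbrella_window(windows[[i]]$anchor, s, windows[[i]]$spring_k)
      })
      core <- suppressWarnings(
        .wham_core(wrep, edges, kT, tol, max_iter, allow_empty = TRUE))
      Fb <- core$F
      Fb[core$M < 1] <- Inf
      .anchor_pmf(Fb, anchor)
    }, numeric(length(edges) - 1))
  })
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  sd_bin <- apply(reps, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  })
  keep <- centers %in% base$profile$z
  out <- base
  out$profile$sd <- sd_bin[keep]
  out$replicates <- reps
  out$autocorr_times <- tcorr
  out$anchor <- anchor
  out
}

#' Split-half PMF convergence check
#'
#' Runs WHAM on the first halves and on the second halves of every
#' window's series (common bin grid) and reports the maximum absolute
#' per-bin difference after both profiles are anchored the same way.
#'
#' @param windows List of [umbrella_window()]s, each with >= 200
#'   samples.
#' @param min_count Bins with fewer total samples than this in either
#'   half are excluded from the comparison.
#' @inheritParams bootstrap_pmf
#' @return List: `max_diff` (kcal/mol), `pmf_first`, `pmf_second`.
#' @export
convergence_check <- function(windows, bin_width = 0.1, kT = 0.596,
                              tol = 1e-8, max_iter = 1e5, anchor = "min",
                              min_count = 5) {
  Ns <- vapply(windows, function(w) length(w$samples), integer(1))
  if (any(Ns < 200))
    stop("convergence_check: every window needs >= 200 samples")
  half <- function(which_half) {
    lapply(windows, function(w) {
      n <- length(w$samples)
      idx <- if (which_half == 1) seq_len(n %/% 2) else (n %/% 2 + 1):n
      umbrella_window(w$anchor, w$samples[idx], w$spring_k)
    })
  }
  rng <- range(unlist(lapply(windows, `[[`, "samples")))
  edges <- seq(floor(rng[1] / bin_width) * bin_width,
               ceiling(rng[2] / bin_width) * bin_width, by = bin_width)
  c1 <- .wham_core(half(1), edges, kT, tol, max_iter, allow_empty = TRUE)
  c2 <- .wham_core(half(2), edges, kT, tol, max_iter, allow_empty = TRUE)
  F1 <- c1$F; F1[c1$M < min_count] <- Inf
  F2 <- c2$F; F2[c2$M < min_count] <- Inf
  F1 <- .anchor_pmf(F1, anchor)
  F2 <- .anchor_pmf(F2, anchor)
  fin <- is.finite(F1) & is.finite(F2)
  list(max_diff = max(abs(F1[fin] - F2[fin])),
       z = c1$centers[fin],
       pmf_first = F1[fin], pmf_second = F2[fin])
}
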