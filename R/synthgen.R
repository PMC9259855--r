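# Synthetic cohort generator.  The generator plants the statistical
# structure the downstream analysis assumes -- band-limited carriers with
# shared slow envelope modulators, instantaneous linear leakage,
# age-dependent network topology, and injected artifacts -- with full
# ground truth, so every pipeline stage can be validated without real
# recordings.

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Configuration for a synthetic cohort
#'
#' Defaults describe the emulated study population: 131 subjects aged 7-29
#' with a roughly uniform age distribution, 448 cortical parcels, the five
#' canonical bands, 5-minute recordings.  Age effects are planted at the
#' graph level: the fraction of planted strong edges drawn from a band's
#' characteristic pool (short-range pairs for the "local" band, long-range
#' pairs for the "global" band) shifts linearly with age.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Age range in years, c(min, max); ages drawn uniformly.
#' @param n_nodes Number of parcels (>= 4).
#' @param bands Named list of \code{\link{band_definition}} objects.
#' @param duration Recording length in seconds (>= 60, i.e. two 30-s
#'   windows' worth).
#' @param fs Sampling rate in Hz; must exceed 3 x the highest band edge.
#' @param coupling_strength Planted envelope-modulator correlation for
#'   connected node pairs, in [0, 1).
#' @param leakage_strength Instantaneous mixing weight spread to ring
#'   neighbours, in [0, 1); emulates field spread.
#' @param age_effect_local Per-year slope on the short-range
#'   (clustering-building) edge fraction of \code{local_band}.
#' @param age_effect_global Per-year slope on the long-range
#'   (shortcut-building) edge fraction of \code{global_band}.
#' @param local_band,global_band Names of the bands carrying each planted
#'   effect.
#' @param age_effect_hub Per-year slope by which the hub edge share
#'   declines with age (every band): positive values make older subjects'
#'   networks depend less on the designated hubs.  Default 0.
#' @param hub_nodes Node indices designated as hubs (extra edge mass);
#'   default: 10\% of nodes, evenly spaced.
#' @param artifact_rates Named per-minute rates c(spikes=, blinks=, motion=)
#'   of residual (post-projection) artifacts.
#' @param planted_density Fraction of node pairs given strong planted
#'   weights (the "true" network cost).
#' @param char_fraction Baseline (mid-age) fraction of planted edges drawn
#'   from the band's characteristic pool.
#' @param signals If TRUE, generate parcel time series (expensive); if
#'   FALSE, only the planted connectivity matrices.
#' @param aux If TRUE, attach auxiliary channels with injected artifacts.
#' @param seed Integer seed; one global seed expands into per-subject
#'   substreams.
#' @return A validated \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 131L, age_range = c(7, 29),
                          n_nodes = 448L, bands = default_bands(),
                          duration = 300, fs = 600,
                          coupling_strength = 0.8, leakage_strength = 0.3,
                          age_effect_local = 0.01, age_effect_global = 0.01,
                          local_band = "beta", global_band = "gamma",
                          age_effect_hub = 0, hub_nodes = NULL,
                          artifact_rates = c(spikes = 1, blinks = 2,
                                             motion = 0.5),
                          planted_density = 0.15, char_fraction = 0.5,
                          signals = FALSE, aux = FALSE, seed = 1L) {
  fail <- function(field, why) stop("cohort_config: invalid '", field, "': ",
                                    why, call. = FALSE)
  if (!is.numeric(n_subjects) || n_subjects < 1) fail("n_subjects", ">= 1")
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    fail("age_range", "need (min, max) with min < max")
  if (!is.numeric(n_nodes) || n_nodes < 4) fail("n_nodes", "need >= 4 nodes")
  bands <- lapply(bands, as_band)
  if (is.null(names(bands)) || any(names(bands) == ""))
    names(bands) <- vapply(bands, `[[`, "", "name")
  if (duration * 1 < 60) fail("duration", "need >= two 30-s windows of data")
  f_hi_max <- max(vapply(bands, `[[`, 0, "f_hi"))
  if (fs <= 3 * f_hi_max)
    fail("fs", sprintf("need fs > 3 x max band edge (= %g Hz)", 3 * f_hi_max))
  if (coupling_strength < 0 || coupling_strength >= 1)
    fail("coupling_strength", "must lie in [0, 1)")
  if (leakage_strength < 0 || leakage_strength >= 1)
    fail("leakage_strength", "must lie in [0, 1)")
  if (is.null(hub_nodes))
    hub_nodes <- unique(round(seq(1, n_nodes,
                                  length.out = max(1, round(0.1 * n_nodes)))))
  if (any(hub_nodes < 1 | hub_nodes > n_nodes))
    fail("hub_nodes", "indices outside 1..n_nodes")
  if (!all(c("spikes", "blinks", "motion") %in% names(artifact_rates)))
    fail("artifact_rates", "need named rates spikes/blinks/motion")
  if (any(artifact_rates < 0)) fail("artifact_rates", "rates must be >= 0")
  if (planted_density <= 0 || planted_density > 0.5)
    fail("planted_density", "must lie in (0, 0.5]")
  # default effect carriers that are absent from a reduced band list are
  # dropped silently; explicitly named ones must exist
  local_explicit <- !missing(local_band)
  global_explicit <- !missing(global_band)
  if (!local_band %in% names(bands)) {
    if (local_explicit) fail("local_band", "not in bands")
    local_band <- NA_character_
  }
  if (!global_band %in% names(bands)) {
    if (global_explicit) fail("global_band", "not in bands")
    global_band <- NA_character_
  }
  if (!is.numeric(seed) || is.na(seed)) fail("seed", "integer required")
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 n_nodes = as.integer(n_nodes), bands = bands,
                 duration = duration, fs = fs,
                 coupling_strength = coupling_strength,
                 leakage_strength = leakage_strength,
                 age_effect_local = age_effect_local,
                 age_effect_global = age_effect_global,
                 local_band = local_band, global_band = global_band,
                 age_effect_hub = age_effect_hub,
                 hub_nodes = as.integer(hub_nodes),
                 artifact_rates = artifact_rates,
                 planted_density = planted_density,
                 char_fraction = char_fraction,
                 signals = isTRUE(signals), aux = isTRUE(aux),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d subjects aged %g-%g, %d nodes, %d band(s), %g s @ %g Hz\n",
              x$n_subjects, x$age_range[1], x$age_range[2], x$n_nodes,
              length(x$bands), x$duration, x$fs))
  invisible(x)
}

# ring distance between node indices on a circle of n nodes
ring_distance <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

# Weighted planted connectivity.  Nodes sit on a ring; K = density * n_pairs
# strong edges are a lattice<->shortcut mixture: a fraction frac_char of the
# band's characteristic pool ("short" ring-range pairs build triangles and
# local efficiency, "long" pairs build shortcuts and global efficiency) and
# the complement from the opposite pool, so one parameter interpolates
# between a clustered lattice and a shortcut-rich topology.  A fixed slice
# is forced incident to hub nodes.  Strong edges get weights in (0.5, 0.9),
# the background in (0, 0.3), so proportional thresholding at cost <=
# density recovers planted edges.
planted_connectivity <- function(n_nodes, frac_char,
                                 pool = c("none", "short", "long"),
                                 hub_nodes = integer(0),
                                 density = 0.15, hub_frac = 0.15) {
  pool <- match.arg(pool)
  n <- n_nodes
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  n_pairs <- length(ii)
  dr <- ring_distance(ii, jj, n)
  K <- max(1L, round(density * n_pairs))
  short_pool <- which(dr <= max(2L, round(0.06 * n)))
  long_pool <- which(dr >= floor(n / 4))
  is_hub_pair <- (ii %in% hub_nodes) | (jj %in% hub_nodes)
  chosen <- integer(0)
  if (length(hub_nodes) > 0) {
    n_hub <- round(hub_frac * K)
    if (n_hub > 0)
      chosen <- sample(which(is_hub_pair), min(n_hub, sum(is_hub_pair)))
  }
  f <- if (pool == "none") 0.5 else clamp(frac_char, 0, 1)
  char_pool <- if (pool == "long") long_pool else short_pool
  anti_pool <- if (pool == "long") short_pool else long_pool
  K_rest <- K - length(chosen)
  n_char <- round(f * K_rest)
  cand <- setdiff(char_pool, chosen)
  chosen <- c(chosen, sample(cand, min(n_char, length(cand))))
  cand <- setdiff(anti_pool, chosen)
  chosen <- c(chosen, sample(cand, min(K - length(chosen), length(cand))))
  if (length(chosen) < K) {                    # pools exhausted: fill uniform
    cand <- setdiff(seq_len(n_pairs), chosen)
    chosen <- c(chosen, sample(cand, K - length(chosen)))
  }
  w <- runif(n_pairs, 0, 0.3)
  w[chosen] <- runif(length(chosen), 0.5, 0.9)
  W <- matrix(0, n, n)
  W[cbind(ii, jj)] <- w
  W + t(W)
}

char_fraction_for <- function(config, band_name, age) {
  mid <- mean(config$age_range)
  f <- config$char_fraction
  if (isTRUE(band_name == config$local_band))
    f <- f + config$age_effect_local * (age - mid)
  if (isTRUE(band_name == config$global_band))
    f <- f + config$age_effect_global * (age - mid)
  clamp(f, 0.05, 0.95)
}

# ideal FFT band mask filter applied to the rows of X
fft_band_filter <- function(X, fs, f_lo, f_hi) {
  n <- ncol(X)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  keep <- as.numeric(f_fold >= f_lo & f_fold <= f_hi)
  Xf <- t(stats::mvfft(t(X)))
  Re(t(stats::mvfft(t(Xf * rep(keep, each = nrow(X))), inverse = TRUE))) / n
}

#' Generate coupled band-limited parcel series
#'
#' Each node is a band-passed Gaussian carrier multiplied by a slow
#' (< 1 Hz) rectified Gaussian modulator; coupled node pairs share modulator
#' variance in proportion to the coupling entry, producing synchronous
#' envelope amplitude modulations with independent carrier phases.  The
#' returned series are the instantaneous (zero-lag) leakage mixture of the
#' unmixed node signals.
#'
#' @param n_nodes Number of nodes.
#' @param band A \code{\link{band_definition}}.
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz (> 2 x f_hi).
#' @param envelope_coupling Symmetric zero-diagonal matrix in [0, 1): target
#'   modulator correlations.  Scalar 0 means fully independent nodes.
#' @param leakage Mixing matrix with near-identity rows; default identity.
#' @param seed Integer seed.
#' @param f_mod Modulator low-pass edge in Hz (default 0.5; several cycles
#'   per 30-s window).
#' @param modulator_depth Modulation depth: the modulator is
#'   1 + depth * |z| with z a unit-variance low-pass Gaussian, i.e. a
#'   baseline oscillatory amplitude plus rectified slow fluctuations of
#'   comparable size (default 1).
#' @return Numeric n_nodes x samples matrix.
#' @export
generate_coupled_band_series <- function(n_nodes, band, duration, fs,
                                         envelope_coupling = 0,
                                         leakage = NULL, seed = 1L,
                                         f_mod = 0.5, modulator_depth = 1) {
  band <- as_band(band)
  if (fs <= 2 * band$f_hi) stop("generate_coupled_band_series: fs too low")
  if (length(envelope_coupling) == 1L)
    envelope_coupling <- matrix(envelope_coupling, n_nodes, n_nodes) -
      diag(as.numeric(envelope_coupling), n_nodes)
  if (!isTRUE(all.equal(envelope_coupling, t(envelope_coupling))) ||
      any(diag(envelope_coupling) != 0))
    stop("generate_coupled_band_series: coupling must be symmetric with zero diagonal")
  if (any(envelope_coupling < 0 | envelope_coupling >= 1))
    stop("generate_coupled_band_series: coupling entries must lie in [0, 1)")
  if (is.null(leakage)) leakage <- diag(n_nodes)
  if (!all(dim(leakage) == n_nodes))
    stop("generate_coupled_band_series: leakage dimension mismatch")
  set.seed(seed)
  n <- round(duration * fs)
  carriers <- fft_band_filter(matrix(rnorm(n_nodes * n), n_nodes, n),
                              fs, band$f_lo, band$f_hi)
  carriers <- carriers / pmax(apply(carriers, 1L, sd), 1e-12)
  Z <- fft_band_filter(matrix(rnorm(n_nodes * n), n_nodes, n), fs, 0, f_mod)
  Z <- Z / pmax(apply(Z, 1L, sd), 1e-12)
  Sigma <- envelope_coupling
  diag(Sigma) <- 1
  ev <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-6)
  Sigma <- ev$vectors %*% (vals * t(ev$vectors))
  Sigma <- stats::cov2cor(Sigma)
  M <- t(chol(Sigma)) %*% Z
  modulators <- 1 + modulator_depth * abs(M)   # baseline + rectified slow drive
  leakage %*% (carriers * modulators)
}

# ring-neighbour leakage mixing matrix with rows summing to 1
leakage_matrix <- function(n_nodes, strength) {
  L <- diag(n_nodes)
  if (strength > 0 && n_nodes > 1) {
    for (i in seq_len(n_nodes)) {
      nb <- c(if (i > 1) i - 1 else n_nodes, if (i < n_nodes) i + 1 else 1)
      nb <- unique(nb[nb != i])
      L[i, nb] <- L[i, nb] + strength / length(nb)
    }
    L <- L / rowSums(L)
  }
  L
}

make_subject <- function(config, idx, age, seed) {
  set.seed(seed)
  n <- config$n_nodes
  planted <- list()
  for (b in names(config$bands)) {
    role <- if (isTRUE(b == config$local_band)) "short" else
      if (isTRUE(b == config$global_band)) "long" else "none"
    hub_frac <- clamp(0.15 - config$age_effect_hub *
                        (age - mean(config$age_range)), 0.02, 0.5)
    planted[[b]] <- planted_connectivity(
      n, char_fraction_for(config, b, age), pool = role,
      hub_nodes = config$hub_nodes, density = config$planted_density,
      hub_frac = hub_frac)
  }
  n_samp <- round(config$duration * config$fs)
  rec <- structure(list(subject_id = sprintf("S%03d", idx), age = age,
                        fs = config$fs, duration = config$duration,
                        n_samples = n_samp, planted = planted,
                        series = NULL, aux = NULL, aux_fs = config$fs,
                        sample_mask = NULL, artifact_log = NULL),
                   class = "subject_record")
  if (config$signals) {
    L <- leakage_matrix(n, config$leakage_strength)
    rec$series <- list()
    for (b in names(config$bands)) {
      coupling <- (planted[[b]] >= 0.5) * config$coupling_strength
      rec$series[[b]] <- generate_coupled_band_series(
        n, config$bands[[b]], config$duration, config$fs,
        envelope_coupling = coupling, leakage = L,
        seed = sample.int(.Machine$integer.max - 1L, 1L))
    }
    rec$sample_mask <- rep(TRUE, n_samp)
  }
  if (config$aux)
    rec <- generate_artifact_channels(rec, config$artifact_rates,
                                      seed = sample.int(.Machine$integer.max - 1L, 1L))
  rec
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s, age %.1f, %d band(s)%s%s\n",
              x$subject_id, x$age, length(x$planted),
              if (is.null(x$series)) "" else ", with series",
              if (is.null(x$aux)) "" else ", with aux"))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws ages uniformly over the configured range and builds one
#' \code{subject_record} per subject: planted per-band connectivity with the
#' configured age-dependent topology, optional parcel time series realizing
#' that connectivity through shared envelope modulators and leakage mixing,
#' and optional auxiliary channels with injected artifacts.  The global seed
#' expands into independent per-subject substreams, so the cohort is
#' bit-reproducible.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return List of \code{subject_record} objects with attributes
#'   \code{config} and class \code{synthetic_cohort}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ages <- runif(config$n_subjects, config$age_range[1], config$age_range[2])
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  cohort <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects))
    cohort[[i]] <- make_subject(config, i, ages[i], sub_seeds[i])
  names(cohort) <- vapply(cohort, `[[`, "", "subject_id")
  structure(cohort, config = config, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  ages <- vapply(x, `[[`, 0, "age")
  cat(sprintf("<synthetic_cohort> %d subjects, ages %.1f-%.1f, %d nodes\n",
              length(x), min(ages), max(ages), cfg$n_nodes))
  invisible(x)
}

#' Subject table of a cohort
#'
#' @param cohort A \code{synthetic_cohort}.
#' @return data.frame(subject_id, age).
#' @export
subject_table <- function(cohort) {
  data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
             age = vapply(cohort, `[[`, 0, "age"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Inject ground-truth artifacts into auxiliary channels
#'
#' Adds auxiliary channels to a subject record: a broadband reference trace
#' with amplitude spikes (8 sigma), HEOG/VEOG traces with 31-80 Hz bursts
#' (blink/microsaccade stand-ins) and a head-speed trace with 1-s excursions
#' above the motion threshold.  Event counts are deterministic
#' (rate x minutes, rounded); positions are seeded.  The injected indices
#' are returned as a ground-truth log for validating the cleaning rules.
#'
#' @param record A \code{subject_record} (needs fs and duration).
#' @param artifact_rates Named per-minute rates c(spikes=, blinks=, motion=).
#' @param seed Integer seed.
#' @return The record with \code{aux} (sig, heog, veog, speed) and
#'   \code{artifact_log} (spike sample indices, blink windows, motion block
#'   indices) filled in.
#' @export
generate_artifact_channels <- function(record,
                                       artifact_rates = c(spikes = 1,
                                                          blinks = 2,
                                                          motion = 0.5),
                                       seed = 1L) {
  stopifnot(inherits(record, "subject_record"))
  set.seed(seed)
  # aux channels keep their own (acquisition-style) rate so the 31-80 Hz
  # saccade band exists even when parcel series are heavily downsampled
  fs <- max(record$fs, 200)
  n <- round(record$duration * fs)
  minutes <- record$duration / 60
  counts <- vapply(c("spikes", "blinks", "motion"), function(k)
    as.integer(max(0, round(artifact_rates[[k]] * minutes))), integer(1))
  sig <- rnorm(n)
  # EOG channels are dominated by slow ocular signal; the 31-80 Hz saccade
  # band carries only weak instrument noise at baseline, so REOG bursts
  # stand far above the whole-series 3 SD threshold
  slow_trace <- function() {
    lf <- fft_band_filter(matrix(rnorm(n), 1L), fs, 0, 5)[1L, ]
    lf / max(sd(lf), 1e-12) + 0.2 * rnorm(n)
  }
  heog <- slow_trace()
  veog <- slow_trace()
  speed <- abs(rnorm(n, 0, 0.15)) + 0.4
  log <- list(spikes = integer(0),
              blinks = data.frame(start = integer(0), end = integer(0)),
              motion_blocks = integer(0))
  margin <- round(fs)                         # keep events off the edges
  if (counts["spikes"] > 0) {
    idx <- sort(sample(seq.int(margin, n - margin), counts["spikes"]))
    sig[idx] <- sig[idx] + 8 * sample(c(-1, 1), counts["spikes"],
                                      replace = TRUE)
    log$spikes <- idx
  }
  if (counts["blinks"] > 0) {
    blen <- round(0.3 * fs)
    starts <- sort(sample(seq.int(margin, n - margin - blen),
                          counts["blinks"]))
    # enforce separation of one second between bursts
    keep <- c(TRUE, diff(starts) > fs)
    starts <- starts[keep]
    burst_t <- seq_len(blen) / fs
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(blen) / (blen + 1))
    for (s in starts) {
      burst <- 8 * win * sin(2 * pi * 45 * burst_t +
                               runif(1, 0, 2 * pi))
      heog[s:(s + blen - 1L)] <- heog[s:(s + blen - 1L)] + burst
      veog[s:(s + blen - 1L)] <- veog[s:(s + blen - 1L)] + burst
    }
    log$blinks <- data.frame(start = starts, end = starts + blen - 1L)
  }
  if (counts["motion"] > 0) {
    n_blocks <- floor(n / fs)
    blocks <- sort(sample(seq_len(n_blocks - 1L), counts["motion"]))
    for (b in blocks) {
      idx <- seq.int((b - 1L) * round(fs) + 1L, b * round(fs))
      speed[idx] <- 2.5 + abs(rnorm(length(idx), 0, 0.1))
    }
    log$motion_blocks <- blocks
  }
  record$aux <- list(sig = sig, heog = heog, veog = veog, speed = speed)
  record$aux_fs <- fs          # may exceed the parcel-series rate
  record$artifact_log <- log
  record
}

#' Generate a noisy vertex-label fixture for sign alignment
#'
#' All rows are noisy copies of one template series; a stated fraction of
#' rows is sign-inverted, the ground truth the SVD alignment must undo.
#'
#' @param n_vertices Number of vertices (>= 2).
#' @param n_samples Samples per series.
#' @param flip_fraction Fraction of rows inverted (rounded to a count).
#' @param snr Amplitude signal-to-noise ratio of each vertex copy.
#' @param seed Integer seed.
#' @return List: \code{vertices} (matrix), \code{template}, \code{flipped}
#'   (logical per row).
#' @export
generate_vertex_label <- function(n_vertices, n_samples, flip_fraction = 0,
                                  snr = 10, seed = 1L) {
  if (n_vertices < 2) stop("generate_vertex_label: need >= 2 vertices")
  set.seed(seed)
  template <- fft_band_filter(matrix(rnorm(n_samples), 1L), 1, 0.01, 0.2)[1L, ]
  template <- template / sd(template)
  V <- matrix(rep(template, each = n_vertices), n_vertices, n_samples,
              byrow = FALSE) +
    matrix(rnorm(n_vertices * n_samples, sd = 1 / snr), n_vertices)
  n_flip <- round(flip_fraction * n_vertices)
  flipped <- rep(FALSE, n_vertices)
  if (n_flip > 0) {
    flip_idx <- sample(n_vertices, n_flip)
    V[flip_idx, ] <- -V[flip_idx, ]
    flipped[flip_idx] <- TRUE
  }
  list(vertices = V, template = template, flipped = flipped)
}
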