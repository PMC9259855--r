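# Threshold-based artifact rejection: amplitude spikes, microsaccade bursts
# on the EOG channels, and head-motion blocks.  Each rule yields a per-sample
# logical mask (TRUE = rejected); rules are independent and commute.

#' Reject amplitude spikes
#'
#' Samples whose amplitude deviates from the series mean by more than
#' \code{k_sigma} standard deviations are flagged.  Mean and SD are computed
#' over the whole series, artifacts included (literal whole-time-course
#' convention; robust variants are out of scope).
#'
#' @param series Numeric vector (finite, length >= 2).
#' @param k_sigma Threshold in SD units; default 5.
#' @return Logical mask, TRUE where rejected.  A zero-variance series yields
#'   an empty mask.
#' @export
reject_spikes <- function(series, k_sigma = 5) {
  if (length(series) < 2L || !all(is.finite(series)))
    stop("reject_spikes: need a finite series of length >= 2")
  s <- sd(series)
  if (s == 0) return(rep(FALSE, length(series)))
  abs(series - mean(series)) > k_sigma * s
}

#' Composite radial EOG (REOG) trace
#'
#' Band-passes the horizontal and vertical EOG channels to 31-80 Hz (the
#' microsaccadic spike band), takes the analytic-signal envelope of each, and
#' averages the two envelopes pointwise.
#'
#' @param heog,veog Equal-length numeric EOG traces.
#' @param fs Sampling rate in Hz; must exceed 160 Hz (2 x 80).
#' @return Non-negative numeric REOG series.
#' @export
compute_reog <- function(heog, veog, fs) {
  if (length(heog) != length(veog))
    stop("compute_reog: HEOG/VEOG length mismatch")
  if (fs <= 160)
    stop("compute_reog: fs = ", fs, " Hz too low for the 31-80 Hz band")
  saccade_band <- band_definition("saccade", 31, 80)
  env1 <- filtered_envelope(heog, fs, saccade_band)
  env2 <- filtered_envelope(veog, fs, saccade_band)
  (env1 + env2) / 2
}

# band-pass (no decimation, no notch) then envelope
filtered_envelope <- function(x, fs, band) {
  n_taps <- default_n_taps(band$f_lo, fs, length(x))
  h <- fir_bandpass_taps(band$f_lo, band$f_hi, fs, n_taps)
  Mod(hilbert_analytic(filter_zerophase(x, h)))
}

#' Reject REOG peaks
#'
#' Flags samples where the REOG trace exceeds its whole-series mean by more
#' than \code{k_sd} standard deviations.  Contiguous supra-threshold runs
#' count as a single event.
#'
#' @param reog Non-negative REOG series from \code{\link{compute_reog}}.
#' @param k_sd Threshold in SD units; default 3.
#' @return Logical mask with attribute \code{n_events}.
#' @export
reject_reog_peaks <- function(reog, k_sd = 3) {
  if (any(reog < 0)) stop("reject_reog_peaks: REOG must be non-negative")
  s <- sd(reog)
  mask <- if (s == 0) rep(FALSE, length(reog)) else
    reog > mean(reog) + k_sd * s
  structure(mask, n_events = count_events(mask))
}

#' Reject high-motion blocks
#'
#' Tiles the head-speed trace into non-overlapping blocks (default 1 s) and
#' flags every block whose mean speed exceeds the threshold (default
#' 1.7 mm/s, an empirical value).  A trailing partial block is judged on its
#' own mean.
#'
#' @param speed Non-negative head-speed trace in mm/s.
#' @param fs Sampling rate in Hz.
#' @param block_s Block length in seconds; default 1.
#' @param threshold Mean-speed threshold in mm/s; default 1.7.
#' @return Logical mask with attribute \code{n_events} (number of blocks).
#' @export
reject_motion_blocks <- function(speed, fs, block_s = 1, threshold = 1.7) {
  if (any(speed < 0)) stop("reject_motion_blocks: speed must be non-negative")
  n <- length(speed)
  len <- max(1L, round(block_s * fs))
  block <- rep(seq_len(ceiling(n / len)), each = len)[seq_len(n)]
  means <- tapply(speed, block, mean)
  bad <- as.vector(means > threshold)
  structure(bad[block], n_events = sum(bad))
}

count_events <- function(mask) {
  r <- rle(as.logical(mask))
  sum(r$values)
}

#' Combine cleaning masks into a report
#'
#' @param masks Named list of equal-length logical masks, one per rule.
#' @return A \code{cleaning_report}: per-rule masks and event counts, the
#'   combined (union) mask, and \code{fraction_removed}.
#' @export
summarize_cleaning <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("summarize_cleaning: need a non-empty list of masks")
  lens <- vapply(masks, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("summarize_cleaning: mask length mismatch (",
         paste(lens, collapse = ", "), ")")
  masks <- lapply(masks, function(m) as.logical(m))
  combined <- Reduce(`|`, masks)
  structure(list(masks = masks,
                 combined = combined,
                 events = vapply(masks, count_events, integer(1)),
                 samples_removed = vapply(masks, sum, integer(1)),
                 fraction_removed = mean(combined)),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-8s %6d samples in %d event(s)\n",
                nm, x$samples_removed[[nm]], x$events[[nm]]))
  cat(sprintf("  combined fraction removed: %.3f\n", x$fraction_removed))
  invisible(x)
}

#' Apply every cleaning rule to a subject record
#'
#' Runs the spike, REOG-peak and motion-block rules on whichever auxiliary
#' channels the record carries, attaches the \code{cleaning_report}, and
#' ANDs the combined rejection mask (resampled onto the parcel-series time
#' base when the aux rate differs) into the record's sample mask.
#'
#' @param record A \code{subject_record} with aux channels.
#' @param k_sigma,k_sd,motion_threshold Rule thresholds (defaults 5, 3,
#'   1.7 mm/s).
#' @return The updated record.
#' @export
clean_subject <- function(record, k_sigma = 5, k_sd = 3,
                          motion_threshold = 1.7) {
  aux <- record$aux
  if (is.null(aux)) return(record)
  masks <- list()
  if (!is.null(aux$sig)) masks$spikes <- reject_spikes(aux$sig, k_sigma)
  if (!is.null(aux$heog) && !is.null(aux$veog)) {
    reog <- compute_reog(aux$heog, aux$veog, record$aux_fs)
    masks$blinks <- as.logical(reject_reog_peaks(reog, k_sd))
  }
  if (!is.null(aux$speed))
    masks$motion <- as.logical(reject_motion_blocks(aux$speed, record$aux_fs,
                                                    threshold = motion_threshold))
  if (length(masks) == 0L) return(record)
  record$cleaning <- summarize_cleaning(masks)
  # aux channels are sampled at aux_fs; resample the combined mask onto the
  # parcel-series time base if one exists
  if (!is.null(record$sample_mask)) {
    n <- length(record$sample_mask)
    idx <- pmin(length(record$cleaning$combined),
                floor((seq_len(n) - 1) * record$aux_fs / record$fs) + 1L)
    record$sample_mask <- record$sample_mask & !record$cleaning$combined[idx]
  }
  record
}
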