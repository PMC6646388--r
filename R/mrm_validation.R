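#' Peak group: per-transition chromatogram data for one peptide in one run
#'
#' Holds either raw time/intensity traces per transition or pre-integrated
#' areas with apex retention times (as exported from peak-picking
#' software). Times are minutes and must be strictly increasing within a
#' trace; intensities are nonnegative counts.
#'
#' @param run_id Run identifier.
#' @param peptide Peptide sequence.
#' @param traces Named list (by fragment label) of data.frames with
#'   columns `time_min`, `intensity`; or `NULL` when only summaries are
#'   available.
#' @param areas,apex_rt Named numeric vectors (by fragment label) when
#'   pre-integrated summaries are supplied instead of traces.
#' @param replicate Technical-replicate index.
#' @return A `PeakGroup` object.
#' @export
peak_group <- function(run_id, peptide, traces = NULL, areas = NULL,
                       apex_rt = NULL, replicate = 1L) {
  if (is.null(traces) && is.null(areas)) {
    stop("peak group needs traces or integrated areas")
  }
  if (!is.null(traces)) {
    if (length(traces) < 2L) stop("peak group needs >= 2 transitions")
    for (lab in names(traces)) {
      tr <- traces[[lab]]
      if (any(diff(tr$time_min) <= 0)) {
        stop("times not strictly increasing in trace ", lab)
      }
      if (any(tr$intensity < 0)) stop("negative intensity in trace ", lab)
    }
  } else if (length(areas) < 2L) {
    stop("peak group needs >= 2 transitions")
  }
  structure(list(run_id = run_id, peptide = peptide, traces = traces,
                 areas = areas, apex_rt = apex_rt,
                 replicate = as.integer(replicate)),
            class = "PeakGroup")
}

moving_average <- function(x, width = 3L) {
  if (width <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}

#' Integrate the traces of a peak group
#'
#' Per transition: area by trapezoidal integration over the full trace
#' window (reported in intensity * seconds), and apex retention time as
#' the time of maximum smoothed intensity (centered moving average,
#' default width 3 points).
#'
#' @param pg A `PeakGroup` with raw traces (each >= 3 points).
#' @param smooth_points Moving-average width for apex picking.
#' @return data.frame with columns `fragment_label`, `area`,
#'   `apex_rt_min`.
#' @export
integrate_traces <- function(pg, smooth_points = 3L) {
  stopifnot(inherits(pg, "PeakGroup"))
  if (is.null(pg$traces)) stop("peak group carries no raw traces")
  rows <- lapply(names(pg$traces), function(lab) {
    tr <- pg$traces[[lab]]
    if (nrow(tr) < 3L) stop("trace ", lab, " shorter than 3 points")
    area <- pracma::trapz(tr$time_min * 60, tr$intensity)
    sm <- moving_average(tr$intensity, smooth_points)
    sm[is.na(sm)] <- -Inf  # filter edges
    data.frame(fragment_label = lab, area = area,
               apex_rt_min = tr$time_min[which.max(sm)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(fragment_label_index(out$fragment_label)), , drop = FALSE]
}

peak_group_summary <- function(pg, smooth_points = 3L) {
  if (!is.null(pg$traces)) {
    s <- integrate_traces(pg, smooth_points)
    list(areas = stats::setNames(s$area, s$fragment_label),
         apex_rt = stats::setNames(s$apex_rt_min, s$fragment_label))
  } else {
    list(areas = pg$areas, apex_rt = pg$apex_rt)
  }
}

#' Co-elution check (validation criterion A)
#'
#' All transitions of a genuine peptide derive from one eluting analyte
#' and must reach their apex together. Passes when the maximum pairwise
#' apex spread is within tolerance. A transition with no measurable signal
#' (missing or NA apex) fails the group with reason `missing_transition`.
#'
#' @param apex_rt Named numeric vector of per-transition apex times
#'   (minutes), length >= 2.
#' @param tolerance_min Maximum allowed apex spread, minutes.
#' @return List with `pass`, `spread_min`, `reason`.
#' @export
check_coelution <- function(apex_rt, tolerance_min = 0.2) {
  if (length(apex_rt) < 2L) stop("co-elution needs >= 2 transitions")
  if (anyNA(apex_rt)) {
    return(list(pass = FALSE, spread_min = NA_real_,
                reason = "missing_transition"))
  }
  spread <- max(apex_rt) - min(apex_rt)
  list(pass = spread <= tolerance_min, spread_min = spread,
       reason = if (spread <= tolerance_min) "" else "apex_spread_exceeded")
}

#' Transition-intensity dot product (dotp)
#'
#' Normalized dot product between the observed per-transition areas and a
#' reference intensity pattern: `sum(a*b) / (||a|| * ||b||)` over the same
#' ordered transition set. Equals 1 iff the observed pattern is
#' proportional to the reference, 0 for orthogonal patterns; invariant to
#' positive scaling of either vector. A square-root intensity transform
#' can be applied first (off by default).
#'
#' @param observed Named nonnegative numeric vector of observed areas.
#' @param reference Named nonnegative reference ratios (same transitions;
#'   a `ReferencePattern` is also accepted).
#' @param sqrt_transform Apply sqrt to both vectors first.
#' @return dotp in [0, 1].
#' @export
dotp <- function(observed, reference, sqrt_transform = FALSE) {
  if (inherits(reference, "ReferencePattern")) reference <- reference$ratios
  if (!is.null(names(observed)) && !is.null(names(reference))) {
    if (!setequal(names(observed), names(reference))) {
      stop("observed and reference transition sets differ")
    }
    observed <- observed[names(reference)]
  } else if (length(observed) != length(reference)) {
    stop("observed and reference lengths differ")
  }
  if (any(observed < 0) || any(reference < 0)) {
    stop("dotp requires nonnegative vectors")
  }
  if (sqrt_transform) {
    observed <- sqrt(observed); reference <- sqrt(reference)
  }
  na <- sqrt(sum(observed^2)); nb <- sqrt(sum(reference^2))
  if (na == 0) {
    warning("zero observed intensity vector; dotp defined as 0")
    return(0)
  }
  if (nb == 0) stop("zero reference vector")
  sum(observed * reference) / (na * nb)
}

signal_present <- function(tr, noise_mult = 3, smooth_points = 3L) {
  sm <- moving_average(tr$intensity, smooth_points)
  sm <- sm[!is.na(sm)]
  base <- stats::median(sm)
  s <- stats::mad(sm)
  max(sm) > base + noise_mult * s
}

#' Validate a peptide detection across technical replicates
#'
#' Applies the three detection criteria to the replicate peak groups of
#' one peptide in one sample:
#' \itemize{
#'   \item A (co-elution): all transitions co-elute within tolerance, in
#'     every replicate;
#'   \item B (pattern): the arithmetic mean across replicates of the dotp
#'     against the reference pattern is strictly greater than the
#'     threshold (default 0.80);
#'   \item C (reproducibility): every replicate shows signal on every
#'     transition (smoothed apex above baseline by `noise_mult` baseline
#'     MADs when traces are available) and passes co-elution.
#' }
#' `detected` is true only when A, B and C all pass (and the spike-in
#' check, when one is supplied).
#'
#' @param peak_groups List of `PeakGroup` replicates for one peptide.
#' @param reference A `ReferencePattern` for the peptide.
#' @param thresholds `validation` section of [default_config()].
#' @param spikein Optional result of [spikein_check()].
#' @return A `ValidationVerdict` list with per-criterion fields and
#'   `detected`.
#' @export
validate_detection <- function(peak_groups, reference,
                               thresholds = default_config()$validation,
                               spikein = NULL) {
  if (!length(peak_groups)) stop("no replicates supplied")
  if (is.null(reference)) stop("no reference pattern for peptide")
  if (inherits(peak_groups, "PeakGroup")) peak_groups <- list(peak_groups)
  peptide <- peak_groups[[1]]$peptide
  dotps <- numeric(0)
  coel <- logical(0)
  spreads <- numeric(0)
  signal_ok <- logical(0)
  for (pg in peak_groups) {
    s <- peak_group_summary(pg, thresholds$smooth_points)
    # transitions expected but absent from the group are missing signal
    expected <- names(reference$ratios)
    areas <- s$areas[expected]
    names(areas) <- expected
    areas[is.na(areas)] <- 0
    apex <- s$apex_rt[expected]
    names(apex) <- expected
    cc <- check_coelution(apex, thresholds$coelution_tolerance_min)
    coel <- c(coel, cc$pass)
    spreads <- c(spreads, cc$spread_min)
    dotps <- c(dotps, suppressWarnings(
      dotp(areas, reference, thresholds$sqrt_transform)))
    present <- if (!is.null(pg$traces)) {
      all(expected %in% names(pg$traces)) &&
        all(vapply(pg$traces[expected], signal_present, logical(1),
                   noise_mult = thresholds$noise_mult,
                   smooth_points = thresholds$smooth_points))
    } else {
      all(areas > 0)
    }
    signal_ok <- c(signal_ok, present)
  }
  coelution_pass <- all(coel)
  mean_dotp <- mean(dotps)
  dotp_pass <- mean_dotp > thresholds$dotp_threshold  # strict >
  replicate_pass <- all(signal_ok) && coelution_pass
  detected <- coelution_pass && dotp_pass && replicate_pass &&
    (is.null(spikein) || isTRUE(spikein$pass))
  structure(list(peptide = peptide,
                 run_id = peak_groups[[1]]$run_id,
                 n_replicates = length(peak_groups),
                 coelution_pass = coelution_pass,
                 max_apex_spread_min = if (all(is.na(spreads))) NA_real_
                                       else max(spreads, na.rm = TRUE),
                 dotp = mean_dotp,
                 dotp_per_replicate = dotps,
                 dotp_pass = dotp_pass,
                 replicate_pass = replicate_pass,
                 spikein = spikein,
                 detected = detected),
            class = "ValidationVerdict")
}

#' @export
print.ValidationVerdict <- function(x, ...) {
  cat(sprintf(
    "ValidationVerdict %s [%s]: %s (coelution %s, mean dotp %.3f %s, replicates %s)\n",
    x$peptide, x$run_id, if (x$detected) "DETECTED" else "not detected",
    if (x$coelution_pass) "pass" else "FAIL", x$dotp,
    if (x$dotp_pass) "pass" else "FAIL",
    if (x$replicate_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Spike-in standard agreement check
#'
#' Confirms a putative endogenous detection against a run of the same
#' sample spiked with a synthetic unlabeled standard of the peptide.
#' Passes when all three hold:
#' \itemize{
#'   \item the spiked run's total area exceeds the endogenous run's by
#'     more than `spike_fold` times the endogenous area (the spike must
#'     visibly add signal; no increase fails with reason
#'     `no_area_increase`);
#'   \item the endogenous transition pattern agrees with the standard's
#'     reference pattern (dotp strictly > 0.80);
#'   \item the endogenous and spiked apex retention times agree within
#'     3.0 min, inclusive.
#' }
#'
#' @param endogenous,spiked `PeakGroup`s of the same peptide and
#'   transition set, without and with the spiked standard.
#' @param standard_reference `ReferencePattern` of the synthetic standard.
#' @param thresholds `validation` section of [default_config()].
#' @return List with `area_ratio` (spiked/endogenous total),
#'   `area_increase_pass`, `dotp_vs_standard`, `dotp_pass`, `rt_diff_min`,
#'   `rt_pass`, `pass`, `reason`.
#' @export
spikein_check <- function(endogenous, spiked, standard_reference,
                          thresholds = default_config()$validation) {
  se <- peak_group_summary(endogenous, thresholds$smooth_points)
  ss <- peak_group_summary(spiked, thresholds$smooth_points)
  if (!setequal(names(se$areas), names(ss$areas))) {
    stop("endogenous and spiked runs measured different transitions")
  }
  tot_e <- sum(se$areas); tot_s <- sum(ss$areas)
  reason <- ""
  if (tot_s <= tot_e) {
    increase_pass <- FALSE
    reason <- "no_area_increase"
  } else {
    increase_pass <- (tot_s - tot_e) > thresholds$spike_fold * tot_e
    if (!increase_pass) reason <- "area_increase_below_fold"
  }
  d <- suppressWarnings(dotp(se$areas, standard_reference,
                             thresholds$sqrt_transform))
  dotp_pass <- d > thresholds$dotp_threshold
  rt_e <- stats::median(se$apex_rt, na.rm = TRUE)
  rt_s <- stats::median(ss$apex_rt, na.rm = TRUE)
  rt_diff <- abs(rt_e - rt_s)
  rt_pass <- rt_diff <= thresholds$spike_rt_tolerance_min  # inclusive
  list(area_ratio = tot_s / tot_e,
       area_increase_pass = increase_pass,
       dotp_vs_standard = d, dotp_pass = dotp_pass,
       rt_diff_min = rt_diff, rt_pass = rt_pass,
       pass = increase_pass && dotp_pass && rt_pass,
       reason = reason)
}
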