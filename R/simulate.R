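#' Synthetic-data generator configuration
#'
#' Controls the seeded simulator that emulates the pipeline's inputs:
#' labeled proteome registries with peptides planted at known specificity
#' tiers, and Gaussian-peak MRM chromatograms with controlled co-elution,
#' intensity-ratio fidelity, retention time, noise, and decoy corruptions.
#' With a fixed seed, outputs are identical across runs.
#'
#' @param seed Integer seed; every random draw flows from it.
#' @param n_target,n_related,n_other Number of proteomes per category
#'   (defaults mirror a three-strain target panel screened against related
#'   organohalide respirers and unrelated background organisms).
#' @param proteins_per_proteome Proteins simulated per proteome.
#' @param protein_len_mean,protein_len_sd Protein length distribution
#'   (residues; truncated at 50).
#' @param amplitude_range Peak base-amplitude range (counts).
#' @param sigma_rt_min Chromatographic peak width sigma, minutes.
#' @param rt_jitter_sd_min Per-transition apex jitter sigma, minutes.
#' @param group_rt_sd_min Whole-group retention shift sigma, minutes.
#' @param window_min Half-width of the simulated trace window, minutes.
#' @param interval_s Trace sampling interval, seconds.
#' @param noise_model `"gaussian_relative"` (additive Gaussian,
#'   sd = `noise_scale` x transition amplitude) or `"poisson"`.
#' @param noise_scale Relative noise scale.
#' @param baseline Constant baseline level, counts.
#' @param n_replicates Technical replicates per sample.
#' @param n_transitions Transitions per simulated reference pattern.
#' @param rt_shift_min Retention shift applied by the `rt_shift` decoy.
#' @param dropout_k Transitions silenced by the `dropout` decoy.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_target = 3L, n_related = 2L, n_other = 2L,
                       proteins_per_proteome = 30L,
                       protein_len_mean = 300, protein_len_sd = 80,
                       amplitude_range = c(5e4, 5e5),
                       sigma_rt_min = 0.05,
                       rt_jitter_sd_min = 0.02,
                       group_rt_sd_min = 0.02,
                       window_min = 0.5,
                       interval_s = 2,
                       noise_model = c("gaussian_relative", "poisson"),
                       noise_scale = 0.03,
                       baseline = 20,
                       n_replicates = 3L,
                       n_transitions = 5L,
                       rt_shift_min = 5,
                       dropout_k = 2L) {
  noise_model <- match.arg(noise_model)
  if (sigma_rt_min <= 0) stop("sigma_rt_min must be > 0")
  structure(as.list(environment()), class = "SimConfig")
}

sim_residues <- function() setdiff(canonical_residues(), character(0))

random_protein <- function(len) {
  paste(sample(canonical_residues(), len, replace = TRUE), collapse = "")
}

#' Generate a random tryptic candidate peptide
#'
#' Length 7-18, ends in K or R, no internal K/R, no methionine, does not
#' start with proline — so that, planted between tryptic boundaries, it is
#' guaranteed to appear in the host proteome's filtered peptidome.
#'
#' @param len Peptide length (default: random in 7..18).
#' @return Peptide sequence.
#' @export
random_candidate_peptide <- function(len = sample(7:18, 1)) {
  inner <- setdiff(canonical_residues(), c("K", "R", "M"))
  first <- sample(setdiff(inner, "P"), 1)
  body <- if (len > 2) paste(sample(inner, len - 2L, replace = TRUE),
                             collapse = "") else ""
  paste0(first, body, sample(c("K", "R"), 1))
}

plant_peptide <- function(sequence, peptide) {
  # insert between tryptic boundaries: preceding R, following non-P start
  pos <- sample(seq_len(nchar(sequence) - 1L), 1)
  follower <- substring(sequence, pos + 1L, pos + 1L)
  tail <- substring(sequence, pos + 1L, nchar(sequence))
  if (follower == "P") tail <- paste0("A", tail)
  paste0(substring(sequence, 1, pos), "R", peptide, tail)
}

#' Simulate a labeled proteome registry with planted ground truth
#'
#' Generates random proteomes per category and plants candidate peptides
#' verbatim so that every specificity tier has known-truth members:
#' `specific` peptides appear only in target proteomes, `semi_specific`
#' also in a related-organohalide-respirer proteome, `non_specific` also
#' in an `other`-category proteome. The emitted truth table is the oracle
#' for specificity-screen tests.
#'
#' @param config A `SimConfig`.
#' @param n_per_tier Named integer vector: planted peptides per tier.
#' @return List with `registry` (list of `Proteome`) and `truth`
#'   (data.frame `peptide`, `true_tier`, `planted_in`).
#' @export
simulate_proteomes <- function(config = sim_config(),
                               n_per_tier = c(specific = 3L,
                                              semi_specific = 2L,
                                              non_specific = 2L)) {
  set.seed(config$seed)
  make_set <- function(prefix, n, category) {
    lapply(seq_len(n), function(i) {
      len <- pmax(50L, round(stats::rnorm(config$proteins_per_proteome,
                                          config$protein_len_mean,
                                          config$protein_len_sd)))
      proteome(id = paste0(prefix, i),
               taxon_name = paste0(prefix, i),
               category = category,
               accessions = sprintf("%s%d_P%03d", prefix, i,
                                    seq_len(config$proteins_per_proteome)),
               sequences = vapply(len, random_protein, character(1)))
    })
  }
  registry <- c(make_set("TGT", config$n_target, "target"),
                make_set("REL", config$n_related, "related_ohrb"),
                make_set("OTH", config$n_other, "other"))
  categories <- vapply(registry, `[[`, character(1), "category")
  plant_into <- function(registry, idx, peptide) {
    for (i in idx) {
      j <- sample(nrow(registry[[i]]$proteins), 1)
      registry[[i]]$proteins$sequence[j] <-
        plant_peptide(registry[[i]]$proteins$sequence[j], peptide)
    }
    registry
  }
  truth <- list()
  for (tier in names(n_per_tier)) {
    for (k in seq_len(n_per_tier[[tier]])) {
      pep <- random_candidate_peptide()
      tgt <- sample(which(categories == "target"),
                    min(2L, config$n_target))
      idx <- tgt
      if (tier %in% c("semi_specific", "non_specific")) {
        idx <- c(idx, sample(which(categories == "related_ohrb"), 1))
      }
      if (tier == "non_specific") {
        idx <- c(idx, sample(which(categories == "other"), 1))
      }
      registry <- plant_into(registry, idx, pep)
      ids <- vapply(registry[idx], `[[`, character(1), "id")
      truth[[length(truth) + 1L]] <-
        data.frame(peptide = pep, true_tier = tier,
                   planted_in = paste(sort(ids), collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$peptide), ]
  rownames(truth) <- NULL
  list(registry = registry, truth = truth)
}

#' Simulate a skewed reference transition pattern
#'
#' Draws normalized transition intensity ratios skewed enough that the
#' rank-reversing permutation used by the `ratio_permute` decoy has a dotp
#' against the original below 0.6 — so permuted decoys sit well under the
#' 0.80 detection threshold by construction.
#'
#' @param peptide Peptide sequence.
#' @param config A `SimConfig`.
#' @param reference_rt Reference retention time, minutes.
#' @return A `ReferencePattern`.
#' @export
simulate_reference_pattern <- function(peptide, config = sim_config(),
                                       reference_rt = 30) {
  n <- nchar(peptide)
  if (n < 5L) stop("peptide too short to carry >= 2 transitions")
  m <- max(2L, min(config$n_transitions, n - 3L))  # y3..y(n-1) available
  labels <- paste0("y", seq(3L, length.out = m))
  for (try in 1:100) {
    ratios <- stats::rgamma(m, shape = 0.7, rate = 1)
    ratios <- ratios / sum(ratios)
    if (dotp(ratios, anti_rank_permute(ratios)) < 0.6) break
  }
  reference_pattern(peptide, stats::setNames(ratios, labels), reference_rt)
}

anti_rank_permute <- function(x) {
  rk <- rank(x, ties.method = "first")
  sort(x)[length(x) + 1L - rk]
}

#' Simulate the MRM peak group of one peptide
#'
#' Per transition: a Gaussian elution peak with amplitude proportional to
#' the reference ratio, a shared apex retention time (plus a whole-group
#' shift and small per-transition jitter), a constant baseline, and
#' additive noise. Decoy modes corrupt the group in controlled ways:
#' \describe{
#'   \item{none}{faithful signal.}
#'   \item{absent}{no analyte; baseline noise only.}
#'   \item{ratio_permute}{transition amplitudes follow the rank-reversed
#'     reference pattern (wrong relative intensities, fails dotp).}
#'   \item{rt_shift}{whole group shifted by `rt_shift_min` (fails
#'     retention-time agreement against a standard).}
#'   \item{dropout}{`dropout_k` transitions silenced (fails signal
#'     presence / co-elution).}
#' }
#' The ground-truth label is attached as attribute `"truth"`.
#'
#' @param reference A `ReferencePattern`.
#' @param config A `SimConfig`.
#' @param decoy_mode One of `"none"`, `"absent"`, `"ratio_permute"`,
#'   `"rt_shift"`, `"dropout"`.
#' @param seed Seed for this group (defaults to `config$seed`); the same
#'   seed yields identical traces.
#' @param replicate Technical-replicate index recorded on the group.
#' @param run_id Run identifier.
#' @param noise_scale,rt_jitter_sd_min Optional overrides of the config
#'   values (e.g. 0 for noiseless analytic checks).
#' @return A `PeakGroup` with raw traces.
#' @export
simulate_peak_group <- function(reference, config = sim_config(),
                                decoy_mode = c("none", "absent",
                                               "ratio_permute", "rt_shift",
                                               "dropout"),
                                seed = config$seed, replicate = 1L,
                                run_id = "sim",
                                noise_scale = config$noise_scale,
                                rt_jitter_sd_min = config$rt_jitter_sd_min) {
  decoy_mode <- match.arg(decoy_mode)
  stopifnot(inherits(reference, "ReferencePattern"))
  set.seed(seed)
  ratios <- reference$ratios
  if (decoy_mode == "ratio_permute") {
    ratios <- stats::setNames(anti_rank_permute(as.numeric(ratios)),
                              names(ratios))
  }
  base_amp <- stats::runif(1, config$amplitude_range[1],
                           config$amplitude_range[2])
  amps <- base_amp * as.numeric(ratios) / max(ratios)
  if (decoy_mode == "absent") amps[] <- 0
  if (decoy_mode == "dropout") {
    amps[sample(length(amps), min(config$dropout_k, length(amps)))] <- 0
  }
  rt_center <- reference$reference_rt +
    stats::rnorm(1, 0, config$group_rt_sd_min)
  if (decoy_mode == "rt_shift") rt_center <- rt_center + config$rt_shift_min
  times <- seq(rt_center - config$window_min,
               rt_center + config$window_min,
               by = config$interval_s / 60)
  traces <- lapply(seq_along(amps), function(i) {
    apex <- rt_center + stats::rnorm(1, 0, rt_jitter_sd_min)
    signal <- amps[i] * exp(-(times - apex)^2 / (2 * config$sigma_rt_min^2)) +
      config$baseline
    noisy <- switch(config$noise_model,
      gaussian_relative = {
        sd <- noise_scale * max(amps[i], config$baseline)
        signal + stats::rnorm(length(signal), 0, sd)
      },
      poisson = {
        if (noise_scale == 0) signal else
          stats::rpois(length(signal), lambda = signal)
      })
    data.frame(time_min = times, intensity = pmax(noisy, 0))
  })
  names(traces) <- names(ratios)
  pg <- peak_group(run_id = run_id, peptide = reference$peptide,
                   traces = traces, replicate = replicate)
  attr(pg, "truth") <- decoy_mode
  pg
}

#' Simulate a full detection study with known truth
#'
#' Generates `n_faithful` genuinely present peptides and `n_decoy`
#' corrupted peptides, each with a reference pattern and
#' `config$n_replicates` replicate peak groups, and returns everything a
#' detection run needs plus the truth labels.
#'
#' @param config A `SimConfig`.
#' @param n_faithful,n_decoy Peptide counts per class.
#' @param decoy_mode Corruption applied to decoy peptides.
#' @return List with `references` (named list of `ReferencePattern`),
#'   `groups` (named list: per peptide, list of replicate `PeakGroup`s),
#'   `truth` (data.frame `peptide`, `status`).
#' @export
simulate_study <- function(config = sim_config(), n_faithful = 20L,
                           n_decoy = 20L, decoy_mode = "ratio_permute") {
  set.seed(config$seed)
  n <- n_faithful + n_decoy
  peptides <- replicate(n, random_candidate_peptide())
  while (anyDuplicated(peptides)) {
    peptides[duplicated(peptides)] <-
      replicate(sum(duplicated(peptides)), random_candidate_peptide())
  }
  status <- c(rep("faithful", n_faithful), rep(decoy_mode, n_decoy))
  rts <- stats::runif(n, 10, 80)
  references <- stats::setNames(lapply(seq_len(n), function(i) {
    simulate_reference_pattern(peptides[i], config, reference_rt = rts[i])
  }), peptides)
  seeds <- sample.int(2^31 - 1000L, n * config$n_replicates)
  groups <- stats::setNames(lapply(seq_len(n), function(i) {
    lapply(seq_len(config$n_replicates), function(r) {
      mode <- if (status[i] == "faithful") "none" else status[i]
      simulate_peak_group(references[[i]], config, decoy_mode = mode,
                          seed = seeds[(i - 1) * config$n_replicates + r],
                          replicate = r, run_id = "study")
    })
  }), peptides)
  list(references = references, groups = groups,
       truth = data.frame(peptide = peptides, status = status,
                          stringsAsFactors = FALSE))
}

#' Simulate a mixed-sample targeting scenario
#'
#' Emulates monitoring a targeted panel in a complex sample where only a
#' subset of the panel's peptides is actually present: of `n_targeted`
#' peptides, `n_present` give faithful signal and the remainder are
#' split between entirely absent analytes and intensity-pattern decoys.
#'
#' @param config A `SimConfig`.
#' @param n_targeted Panel size.
#' @param n_present Number of genuinely present peptides.
#' @return As [simulate_study()], with truth statuses `faithful`,
#'   `absent`, `ratio_permute`.
#' @export
simulate_mixed_scenario <- function(config = sim_config(),
                                    n_targeted = 37L, n_present = 13L) {
  stopifnot(n_present <= n_targeted)
  set.seed(config$seed)
  n_bg <- n_targeted - n_present
  n_absent <- ceiling(n_bg / 2)
  peptides <- replicate(n_targeted, random_candidate_peptide())
  while (anyDuplicated(peptides)) {
    peptides[duplicated(peptides)] <-
      replicate(sum(duplicated(peptides)), random_candidate_peptide())
  }
  status <- c(rep("faithful", n_present), rep("absent", n_absent),
              rep("ratio_permute", n_bg - n_absent))
  rts <- stats::runif(n_targeted, 10, 80)
  references <- stats::setNames(lapply(seq_len(n_targeted), function(i) {
    simulate_reference_pattern(peptides[i], config, reference_rt = rts[i])
  }), peptides)
  seeds <- sample.int(2^31 - 1000L, n_targeted * config$n_replicates)
  groups <- stats::setNames(lapply(seq_len(n_targeted), function(i) {
    lapply(seq_len(config$n_replicates), function(r) {
      mode <- if (status[i] == "faithful") "none" else status[i]
      simulate_peak_group(references[[i]], config, decoy_mode = mode,
                          seed = seeds[(i - 1) * config$n_replicates + r],
                          replicate = r, run_id = "mixed")
    })
  }), peptides)
  list(references = references, groups = groups,
       truth = data.frame(peptide = peptides, status = status,
                          stringsAsFactors = FALSE))
}
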