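#' Default pipeline configuration
#'
#' Returns the full nested configuration used by every stage of the panel
#' design and validation pipeline. Any value can be overridden by a YAML
#' config file ([load_config()]) or by modifying the returned list.
#'
#' Sections:
#' \describe{
#'   \item{digestion}{tryptic digestion and candidate filter parameters:
#'     \code{missed_cleavages} (default 0), \code{proline_rule} (no cleavage
#'     of K/R-P bonds, default \code{TRUE}), \code{min_len}/\code{max_len}
#'     (candidate length bounds, residues, default 7/18),
#'     \code{exclude_residues} (default \code{"M"}: methionine oxidizes
#'     unpredictably and is avoided in targeted assays),
#'     \code{il_equivalence} (treat I and L as indistinguishable, as they
#'     are by mass; default \code{FALSE}).}
#'   \item{masses}{fixed modifications as Da offsets per residue letter
#'     (default carbamidomethyl on C, +57.02146 Da) and the proton mass.}
#'   \item{ce}{per-precursor-charge linear collision-energy coefficients
#'     (eV = slope * precursor m/z + intercept). Defaults are the common
#'     triple-quadrupole linear defaults (charge 2: 0.034, 3.314; charge 3:
#'     0.044, 3.314) and are placeholders meant to be replaced with the
#'     values of the instrument actually used.}
#'   \item{instrument}{quadrupole m/z transmission range; transitions whose
#'     product m/z falls outside are dropped with a logged reason.}
#'   \item{refine}{\code{k} transitions retained per peptide (default 5),
#'     multi-load linearity threshold \code{r_threshold} (Pearson r,
#'     default 0.9), \code{min_total_auc} signal floor.}
#'   \item{validation}{detection thresholds: \code{dotp_threshold} (strict
#'     \code{>}, default 0.80), \code{coelution_tolerance_min} (max apex
#'     spread, default 0.2 min), \code{noise_mult} (signal present when the
#'     smoothed apex exceeds baseline by this many baseline MADs, default
#'     3), \code{smooth_points} (moving-average width for apex picking,
#'     default 3), \code{sqrt_transform} (sqrt intensities before dotp,
#'     default \code{FALSE}), \code{spike_fold} (required fractional area
#'     increase upon spiking, default 0.5), \code{spike_rt_tolerance_min}
#'     (inclusive, default 3.0 min).}
#' }
#'
#' @return Nested list of configuration values.
#' @export
default_config <- function() {
  list(
    digestion = list(
      enzyme = "trypsin",
      missed_cleavages = 0L,
      proline_rule = TRUE,
      min_len = 7L,
      max_len = 18L,
      exclude_residues = "M",
      il_equivalence = FALSE,
      residue_policy = "strict"
    ),
    masses = list(
      fixed_mods = list(C = 57.02146),
      proton = 1.007276
    ),
    ce = list(
      `2` = list(slope = 0.034, intercept = 3.314),
      `3` = list(slope = 0.044, intercept = 3.314)
    ),
    instrument = list(mz_min = 10, mz_max = 3000),
    refine = list(k = 5L, r_threshold = 0.9, min_total_auc = 0),
    validation = list(
      dotp_threshold = 0.80,
      coelution_tolerance_min = 0.2,
      noise_mult = 3,
      smooth_points = 3L,
      sqrt_transform = FALSE,
      spike_fold = 0.5,
      spike_rt_tolerance_min = 3.0
    ),
    specificity = list(match = "peptidome", similarity = "jaccard")
  )
}

#' Load a YAML configuration file over the defaults
#'
#' Values present in the file override the defaults of [default_config()];
#' everything else keeps its default. Unknown keys are kept (forward
#' compatibility) but never read by the pipeline.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modify_list_deep(cfg, user)
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

# Deterministic polynomial hash (mod the Mersenne prime 2^31-1) of the
# serialized config; used in output provenance headers so two runs with
# equal hashes are byte-identical. Intermediate products stay < 2^53, so
# the arithmetic is exact in doubles.
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

canonical_residues <- function() {
  c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
    "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")
}

check_canonical <- function(sequence, label = "sequence") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% canonical_residues())
  if (length(bad)) {
    stop(sprintf("%s contains non-canonical residue(s) %s at position(s) %s",
                 label,
                 paste(unique(chars[bad]), collapse = ","),
                 paste(bad, collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}
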