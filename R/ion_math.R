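#' Monoisotopic mass constants
#'
#' Loads the published monoisotopic residue-mass table shipped with the
#' package and combines it with the water and proton masses and any fixed
#' modifications (default: carbamidomethylation of cysteine, +57.02146 Da,
#' matching the alkylation step of standard bottom-up sample preparation).
#'
#' @param fixed_mods Named list/vector of Da offsets per residue letter, or
#'   `NULL` for none.
#' @param proton Proton mass in Da.
#' @return A `MassConstants` list with `residue_masses`, `water`, `proton`,
#'   `fixed_mods`.
#' @export
mass_constants <- function(fixed_mods = list(C = 57.02146),
                           proton = 1.007276) {
  tab <- utils::read.csv(system.file("extdata", "monoisotopic_residues.csv",
                                     package = "mrmpanel"),
                         stringsAsFactors = FALSE)
  rm <- stats::setNames(tab$mass_da, tab$residue)
  if (length(fixed_mods)) {
    mods <- unlist(fixed_mods)
    unknown <- setdiff(names(mods), names(rm))
    if (length(unknown)) stop("fixed modification on unknown residue(s): ",
                              paste(unknown, collapse = ", "))
  } else {
    mods <- stats::setNames(numeric(0), character(0))
  }
  structure(list(residue_masses = rm, water = 18.010565, proton = proton,
                 fixed_mods = mods),
            class = "MassConstants")
}

residue_mass_vector <- function(constants) {
  rm <- constants$residue_masses
  if (length(constants$fixed_mods)) {
    rm[names(constants$fixed_mods)] <-
      rm[names(constants$fixed_mods)] + constants$fixed_mods
  }
  rm
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses (fixed modifications included) plus one water.
#'
#' @param peptide Peptide sequence, canonical residues only.
#' @param constants A `MassConstants`.
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(peptide, constants = mass_constants()) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (!length(chars)) stop("empty peptide")
  rm <- residue_mass_vector(constants)
  unknown <- setdiff(chars, names(rm))
  if (length(unknown)) stop("unknown residue letter(s): ",
                            paste(unknown, collapse = ", "))
  sum(rm[chars]) + constants$water
}

#' Precursor m/z
#'
#' `(M + z * proton) / z` for a peptide of neutral monoisotopic mass M.
#'
#' @param peptide Peptide sequence.
#' @param charge Precursor charge (>= 1; the assay monitors 2+).
#' @param constants A `MassConstants`.
#' @return m/z in Th.
#' @export
precursor_mz <- function(peptide, charge = 2L, constants = mass_constants()) {
  if (charge < 1) stop("precursor charge must be >= 1")
  (monoisotopic_mass(peptide, constants) + charge * constants$proton) / charge
}

#' Singly charged y-ion m/z
#'
#' The y_i ion is the C-terminal fragment of i residues retaining the
#' C-terminus: m/z = sum of its residue masses (with fixed mods) + water +
#' proton at charge 1.
#'
#' @param peptide Peptide sequence.
#' @param index y-ion index, `1 <= index <= nchar(peptide)`.
#' @param constants A `MassConstants`.
#' @return m/z in Th.
#' @export
y_ion_mz <- function(peptide, index, constants = mass_constants()) {
  n <- nchar(peptide)
  if (index < 1L || index > n) {
    stop(sprintf("y-index %d out of range for %d-residue peptide", index, n))
  }
  frag <- substring(peptide, n - index + 1L, n)
  monoisotopic_mass(frag, constants) + constants$proton
}

#' Collision-energy parameter set
#'
#' Linear collision-energy model per precursor charge:
#' CE (eV) = slope * precursor m/z + intercept.
#'
#' @param params Named list keyed by charge (as character), each a list
#'   with `slope` (eV/Th) and `intercept` (eV).
#' @return A `CEParams` object.
#' @export
ce_params <- function(params = default_config()$ce) {
  for (p in params) stopifnot(is.finite(p$slope), is.finite(p$intercept))
  structure(params, class = "CEParams")
}

#' Linear collision energy for a precursor
#'
#' @param mz Precursor m/z in Th.
#' @param charge Precursor charge.
#' @param params A `CEParams`.
#' @return Collision energy in eV.
#' @export
apply_ce <- function(mz, charge, params = ce_params()) {
  key <- as.character(charge)
  if (is.null(params[[key]])) {
    stop("no collision-energy coefficients for charge ", charge)
  }
  params[[key]]$slope * mz + params[[key]]$intercept
}

#' Enumerate the monitored transitions of a peptide
#'
#' Emits the assay's standard transition series: the 2+ precursor paired
#' with singly charged y3 up to the terminal y(n-1) ion (y_n is never
#' monitored: it duplicates the precursor composition). Each transition
#' carries its collision energy from the linear model. Product ions
#' falling outside the instrument m/z range are dropped with a reason,
#' recorded in the `"dropped"` attribute.
#'
#' @param peptide Peptide sequence of length >= 4 (below that no y3..y(n-1)
#'   series exists).
#' @param constants A `MassConstants`.
#' @param ce A `CEParams`.
#' @param precursor_charge Precursor charge state (default 2).
#' @param mz_range Length-2 numeric instrument transmission range in Th.
#' @return data.frame with columns `peptide`, `precursor_charge`,
#'   `precursor_mz`, `fragment_label`, `y_index`, `product_charge`,
#'   `product_mz`, `collision_energy`, ascending in y-index.
#' @export
enumerate_transitions <- function(peptide, constants = mass_constants(),
                                  ce = ce_params(), precursor_charge = 2L,
                                  mz_range = c(10, 3000)) {
  n <- nchar(peptide)
  if (n < 4L) stop("peptide shorter than 4 residues has no y3..y(n-1) series")
  check_canonical(peptide, "peptide")
  pre <- precursor_mz(peptide, precursor_charge, constants)
  idx <- 3:(n - 1L)
  prod_mz <- vapply(idx, function(i) y_ion_mz(peptide, i, constants),
                    numeric(1))
  df <- data.frame(
    peptide = peptide,
    precursor_charge = as.integer(precursor_charge),
    precursor_mz = pre,
    fragment_label = paste0("y", idx),
    y_index = idx,
    product_charge = 1L,
    product_mz = prod_mz,
    collision_energy = apply_ce(pre, precursor_charge, ce),
    stringsAsFactors = FALSE)
  inside <- df$product_mz >= mz_range[1] & df$product_mz <= mz_range[2]
  dropped <- df[!inside, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- "product_mz_out_of_instrument_range"
    message(nrow(dropped), " transition(s) of ", peptide,
            " outside instrument m/z range dropped")
  }
  df <- df[inside, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "dropped") <- dropped
  df
}
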