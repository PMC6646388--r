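#' Tryptic digestion parameters
#'
#' @param missed_cleavages Maximum internal missed cleavage sites (>= 0).
#' @param proline_rule If `TRUE` (default), K/R followed by P is not cleaved
#'   (classic trypsin specificity).
#' @param min_len,max_len Candidate length bounds in residues.
#' @param exclude_residues Residue letters that disqualify a candidate
#'   (default methionine).
#' @param il_equivalence Collapse I and L (indistinguishable by mass) to a
#'   single canonical letter when building peptidomes.
#' @return A `DigestParams` list.
#' @export
digest_params <- function(missed_cleavages = 0L, proline_rule = TRUE,
                          min_len = 7L, max_len = 18L,
                          exclude_residues = "M", il_equivalence = FALSE) {
  stopifnot(missed_cleavages >= 0L, min_len <= max_len)
  structure(list(enzyme = "trypsin",
                 missed_cleavages = as.integer(missed_cleavages),
                 proline_rule = isTRUE(proline_rule),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 exclude_residues = exclude_residues,
                 il_equivalence = isTRUE(il_equivalence)),
            class = "DigestParams")
}

as_digest_params <- function(x) {
  if (inherits(x, "DigestParams")) return(x)
  do.call(digest_params, x[intersect(names(x), names(formals(digest_params)))])
}

#' In-silico tryptic digestion of one protein
#'
#' Cleaves after K or R (not before P when the proline rule is on) and
#' enumerates all products with up to `missed_cleavages` internal cleavage
#' sites. Positions are 0-based, half-open; output is ordered by start
#' position, then product length.
#'
#' @param sequence Protein sequence (canonical residues, non-empty).
#' @param params A `DigestParams` (or list coercible to one).
#' @return data.frame with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`.
#' @export
digest <- function(sequence, params = digest_params()) {
  params <- as_digest_params(params)
  if (!nzchar(sequence)) stop("empty protein sequence")
  sequence <- toupper(sequence)
  check_canonical(sequence, "protein sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sites <- which(chars == "K" | chars == "R")          # cleave after position i
  if (params$proline_rule && length(sites)) {
    blocked <- sites < n & chars[pmin(sites + 1L, n)] == "P"
    sites <- sites[!blocked]
  }
  bounds <- unique(c(0L, sites[sites < n], n))          # 0-based cut points
  nb <- length(bounds)
  out <- list()
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + params$missed_cleavages)
    for (j in (i + 1L):jmax) {
      out[[length(out) + 1L]] <- c(bounds[i], bounds[j], j - i - 1L)
    }
  }
  m <- do.call(rbind, out)
  df <- data.frame(
    peptide = substring(sequence, m[, 1] + 1L, m[, 2]),
    start = m[, 1], end = m[, 2], missed_cleavages = m[, 3],
    stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end - df$start), ]
  rownames(df) <- NULL
  df
}

#' Apply the candidate peptide filter
#'
#' A candidate passes when `min_len <= length <= max_len` and it contains
#' none of the excluded residues (default: 7-18 residues, no methionine).
#' Failures carry reason codes among `too_short`, `too_long`,
#' `excluded_residue`.
#'
#' @param peptides Character vector of peptide sequences (non-empty).
#' @param params A `DigestParams`.
#' @return data.frame with columns `peptide`, `filter_pass`, `reasons`
#'   (comma-joined codes, empty iff pass). The filter is idempotent and
#'   order-independent.
#' @export
filter_candidates <- function(peptides, params = digest_params()) {
  params <- as_digest_params(params)
  if (!length(peptides)) stop("no peptides to filter")
  len <- nchar(peptides)
  reasons <- vapply(seq_along(peptides), function(i) {
    r <- character(0)
    if (len[i] < params$min_len) r <- c(r, "too_short")
    if (len[i] > params$max_len) r <- c(r, "too_long")
    if (length(params$exclude_residues) &&
        grepl(paste0("[", paste(params$exclude_residues, collapse = ""), "]"),
              peptides[i])) {
      r <- c(r, "excluded_residue")
    }
    paste(r, collapse = ",")
  }, character(1))
  data.frame(peptide = peptides,
             filter_pass = !nzchar(reasons),
             reasons = reasons,
             stringsAsFactors = FALSE)
}

il_canonical <- function(peptides) gsub("I", "L", peptides, fixed = TRUE)

#' Build the filtered tryptic peptidome of a proteome
#'
#' Digests every protein, applies the candidate filter, and returns the
#' union as a set (duplicates collapse). With `il_equivalence` on, I and L
#' are equated (mapped to L) before set formation, reflecting their
#' identical residue mass.
#'
#' @param proteome A `Proteome`.
#' @param params A `DigestParams`.
#' @return Sorted character vector of unique peptide sequences.
#' @export
build_peptidome <- function(proteome, params = digest_params()) {
  stopifnot(inherits(proteome, "Proteome"))
  params <- as_digest_params(params)
  peps <- unlist(lapply(proteome$proteins$sequence,
                        function(s) digest(s, params)$peptide),
                 use.names = FALSE)
  keep <- filter_candidates(peps, params)
  peps <- keep$peptide[keep$filter_pass]
  if (params$il_equivalence) peps <- il_canonical(peps)
  sort(unique(peps))
}
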