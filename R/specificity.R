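#' Classify the biological specificity of a candidate peptide
#'
#' Searches a registry of labeled proteomes and assigns one of three
#' tiers, with precedence non_specific > semi_specific > specific:
#' \itemize{
#'   \item `specific` — found in no proteome outside the `target` category
#'     (the assay organism's strains); action `keep`.
#'   \item `semi_specific` — also found in `related_ohrb` proteomes
#'     (related organohalide-respiring bacteria such as
#'     \emph{Dehalogenimonas}); action `keep_with_caveat`.
#'   \item `non_specific` — found in any `other`-category proteome; action
#'     `remove`.
#' }
#'
#' Match semantics default to membership in the background's tryptic
#' peptidome (`"peptidome"`: the peptide would actually be produced by
#' digestion of that organism), mirroring tryptic-peptide database lookups.
#' The alternative `"substring"` mode matches the peptide anywhere in an
#' undigested protein sequence, mirroring protein-level homology search.
#'
#' @param peptide Candidate peptide sequence.
#' @param registry List of `Proteome` objects, at least one with category
#'   `"target"`.
#' @param match `"peptidome"` or `"substring"`.
#' @param params `DigestParams` used for peptidome-mode matching.
#' @return A `SpecificityReport` list: `peptide`, `tier`, `action`, `hits`
#'   (data.frame `proteome_id`, `category`, `accession`).
#' @export
classify_specificity <- function(peptide, registry,
                                 match = c("peptidome", "substring"),
                                 params = digest_params()) {
  match <- match.arg(match)
  params <- as_digest_params(params)
  check_canonical(peptide, "peptide")
  cats <- vapply(registry, `[[`, character(1), "category")
  if (!any(cats == "target")) stop("registry has no target proteome")
  query <- if (params$il_equivalence) il_canonical(peptide) else peptide
  hits <- do.call(rbind, lapply(registry, function(pr) {
    hit <- vapply(pr$proteins$sequence, function(s) {
      if (match == "substring") {
        subj <- if (params$il_equivalence) il_canonical(s) else s
        grepl(query, subj, fixed = TRUE)
      } else {
        peps <- digest(s, params)$peptide
        if (params$il_equivalence) peps <- il_canonical(peps)
        query %in% peps
      }
    }, logical(1), USE.NAMES = FALSE)
    if (!any(hit)) return(NULL)
    data.frame(proteome_id = pr$id, category = pr$category,
               accession = pr$proteins$accession[hit],
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) {
    hits <- data.frame(proteome_id = character(0), category = character(0),
                       accession = character(0), stringsAsFactors = FALSE)
  }
  tier <- if (any(hits$category == "other")) {
    "non_specific"
  } else if (any(hits$category == "related_ohrb")) {
    "semi_specific"
  } else {
    "specific"
  }
  action <- c(specific = "keep", semi_specific = "keep_with_caveat",
              non_specific = "remove")[[tier]]
  structure(list(peptide = peptide, tier = tier, action = action,
                 hits = hits),
            class = "SpecificityReport")
}

#' Pairwise peptidome similarity
#'
#' Percentage similarity between two peptide sets. The default is the
#' Jaccard index, `100 * |A intersect B| / |A union B|`; the `"overlap"`
#' alternative is `100 * |A intersect B| / min(|A|, |B|)`. Both are
#' symmetric, bounded in [0, 100], and equal 100 iff the sets are
#' identical (Jaccard) or one contains the other (overlap).
#'
#' @param peptidome_a,peptidome_b Non-empty character vectors (treated as
#'   sets).
#' @param method `"jaccard"` or `"overlap"`.
#' @return Similarity percentage.
#' @export
peptidome_similarity <- function(peptidome_a, peptidome_b,
                                 method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  a <- unique(peptidome_a); b <- unique(peptidome_b)
  if (!length(a) || !length(b)) stop("empty peptidome")
  ni <- length(intersect(a, b))
  denom <- if (method == "jaccard") length(union(a, b)) else
    min(length(a), length(b))
  100 * ni / denom
}

#' All-pairs peptidome similarity matrix for a proteome registry
#'
#' Builds each proteome's filtered tryptic peptidome and computes the
#' pairwise similarity percentages (diagonal = 100).
#'
#' @param registry List of `Proteome` objects.
#' @param params `DigestParams` for peptidome construction.
#' @param method Similarity definition, see [peptidome_similarity()].
#' @return Symmetric numeric matrix with proteome ids as dimnames.
#' @export
similarity_matrix <- function(registry, params = digest_params(),
                              method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  ids <- vapply(registry, `[[`, character(1), "id")
  peptidomes <- lapply(registry, build_peptidome, params = params)
  n <- length(registry)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <-
        peptidome_similarity(peptidomes[[i]], peptidomes[[j]], method)
    }
  }
  m
}

#' Screen a candidate panel against a proteome registry
#'
#' Classifies every candidate, removes `non_specific` peptides from the
#' downstream panel, and tallies the tiers. Reports are sorted by peptide
#' sequence for reproducibility.
#'
#' @param candidates Character vector of candidate peptides.
#' @param registry List of `Proteome` objects (>= 1 target).
#' @inheritParams classify_specificity
#' @return data.frame with columns `peptide`, `tier`, `action`, `n_hits`,
#'   `hit_proteomes` (semicolon-joined ids); attributes `summary` (named
#'   tier counts) and `kept` (character vector of retained peptides).
#' @export
screen_panel <- function(candidates, registry,
                         match = c("peptidome", "substring"),
                         params = digest_params()) {
  match <- match.arg(match)
  candidates <- sort(unique(candidates))
  reports <- lapply(candidates, classify_specificity, registry = registry,
                    match = match, params = params)
  df <- data.frame(
    peptide = candidates,
    tier = vapply(reports, `[[`, character(1), "tier"),
    action = vapply(reports, `[[`, character(1), "action"),
    n_hits = vapply(reports, function(r) nrow(r$hits), integer(1)),
    hit_proteomes = vapply(reports, function(r) {
      paste(unique(r$hits$proteome_id), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  summary <- c(specific = sum(df$tier == "specific"),
               semi_specific = sum(df$tier == "semi_specific"),
               non_specific = sum(df$tier == "non_specific"))
  attr(df, "summary") <- summary
  attr(df, "kept") <- df$peptide[df$action != "remove"]
  df
}
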