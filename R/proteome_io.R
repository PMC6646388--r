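#' Read a labeled proteome from a FASTA file
#'
#' Parses a protein FASTA file into a `Proteome` object carrying a category
#' label used downstream by the specificity screen: `"target"` for the
#' organism(s) the assay is designed against, `"related_ohrb"` for related
#' organohalide-respiring bacteria, `"other"` for everything else.
#'
#' The accession is the header token before the first whitespace; the
#' description after it is ignored. Sequences are uppercased and, under the
#' default `"strict"` residue policy, must contain only the 20 canonical
#' amino-acid letters. Under the `"mask"` policy, proteins containing
#' non-canonical letters (B, Z, X, U, J, O, ...) are dropped with a message
#' instead, since they break the downstream mass arithmetic.
#'
#' @param path FASTA file path.
#' @param id Short label for the proteome (e.g. `"Dhc195"`).
#' @param taxon_name Organism name.
#' @param category One of `"target"`, `"related_ohrb"`, `"other"`.
#' @param residue_policy `"strict"` (error on non-canonical residues) or
#'   `"mask"` (drop offending proteins, logged).
#' @return A `Proteome`: list with `id`, `taxon_name`, `category`, and
#'   `proteins` (data.frame with columns `accession`, `sequence`).
#' @export
read_proteome <- function(path, id, taxon_name = id,
                          category = c("target", "related_ohrb", "other"),
                          residue_policy = c("strict", "mask")) {
  category <- match.arg(category)
  residue_policy <- match.arg(residue_policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  accession <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  sequence <- toupper(as.character(aa))
  dup <- accession[duplicated(accession)]
  if (length(dup)) {
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  proteome(id = id, taxon_name = taxon_name, category = category,
           accessions = accession, sequences = unname(sequence),
           residue_policy = residue_policy)
}

#' Construct a Proteome from in-memory sequences
#'
#' @inheritParams read_proteome
#' @param accessions,sequences Parallel character vectors.
#' @return A `Proteome` object.
#' @export
proteome <- function(id, taxon_name = id,
                     category = c("target", "related_ohrb", "other"),
                     accessions, sequences,
                     residue_policy = c("strict", "mask")) {
  category <- match.arg(category)
  residue_policy <- match.arg(residue_policy)
  stopifnot(length(accessions) == length(sequences))
  sequences <- toupper(sequences)
  ok <- !grepl("[^GASPVTCLINDQKEMHFRYW]", sequences)
  if (!all(ok)) {
    if (residue_policy == "strict") {
      i <- which(!ok)[1]
      check_canonical(sequences[i], label = paste0("protein ", accessions[i]))
    } else {
      message("masking ", sum(!ok), " protein(s) with non-canonical residues: ",
              paste(accessions[!ok], collapse = ", "))
      accessions <- accessions[ok]
      sequences <- sequences[ok]
      if (!length(sequences)) stop("all proteins masked in proteome ", id)
    }
  }
  if (anyDuplicated(accessions)) {
    stop("duplicate accession(s): ",
         paste(unique(accessions[duplicated(accessions)]), collapse = ", "))
  }
  structure(
    list(id = id, taxon_name = taxon_name, category = category,
         proteins = data.frame(accession = accessions, sequence = sequences,
                               stringsAsFactors = FALSE)),
    class = "Proteome")
}

#' @export
print.Proteome <- function(x, ...) {
  cat(sprintf("Proteome '%s' (%s, category %s): %d protein(s)\n",
              x$id, x$taxon_name, x$category, nrow(x$proteins)))
  invisible(x)
}

#' Write a proteome to FASTA
#'
#' @param x A `Proteome`.
#' @param path Output FASTA path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "Proteome"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x$proteins))) {
    writeLines(paste0(">", x$proteins$accession[i]), con)
    s <- x$proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

fragment_label_index <- function(label) {
  m <- regmatches(label, regexec("^y([0-9]+)$", label))
  idx <- vapply(m, function(g) {
    if (length(g) == 2L) as.integer(g[2]) else NA_integer_
  }, integer(1))
  idx
}

#' Read a candidate-observation table
#'
#' Reads the CSV of per-transition integrated peak areas exported from
#' discovery (data-dependent) runs, the input to AUC-based transition
#' ranking. Required columns: `peptide_sequence`, `protein_accession`,
#' `strain_id`, `fragment_label` (e.g. `"y7"`), `integrated_area`,
#' `run_id`. All invalid rows are reported together with their line
#' numbers, not just the first.
#'
#' @param path CSV path (lines starting with `#` are ignored).
#' @param sep Field delimiter.
#' @return data.frame with the typed columns above.
#' @export
read_candidate_table <- function(path, sep = ",") {
  req <- c("peptide_sequence", "protein_accession", "strain_id",
           "fragment_label", "integrated_area", "run_id")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("candidate table missing column(s): ", paste(missing, collapse = ", "))
  }
  df$integrated_area <- as.numeric(df$integrated_area)
  probs <- character(0)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_area <- which(is.na(df$integrated_area) | df$integrated_area < 0)
  if (length(bad_area)) {
    probs <- c(probs, sprintf("line %d: invalid integrated_area '%s'",
                              line[bad_area], df$integrated_area[bad_area]))
  }
  yidx <- fragment_label_index(df$fragment_label)
  bad_lab <- which(is.na(yidx))
  if (length(bad_lab)) {
    probs <- c(probs, sprintf("line %d: unparseable fragment_label '%s'",
                              line[bad_lab], df$fragment_label[bad_lab]))
  }
  # terminal-ion convention: y_n duplicates the precursor, so the highest
  # monitorable y-index is length - 1
  len <- nchar(df$peptide_sequence)
  bad_idx <- which(!is.na(yidx) & (yidx < 1L | yidx > len - 1L))
  if (length(bad_idx)) {
    probs <- c(probs, sprintf(
      "line %d: fragment_label %s impossible for %d-residue peptide %s",
      line[bad_idx], df$fragment_label[bad_idx], len[bad_idx],
      df$peptide_sequence[bad_idx]))
  }
  if (length(probs)) {
    stop("invalid candidate table rows:\n", paste(probs, collapse = "\n"))
  }
  df$y_index <- yidx
  df
}

#' Write a transition list CSV
#'
#' Materializes a transition panel in the vendor-importable transition-list
#' dialect: one row per transition with columns `protein`, `peptide`,
#' `precursor_mz`, `product_mz`, `fragment_label`, `collision_energy`,
#' `charge`. m/z values are printed with fixed 4-decimal precision and rows
#' are ordered by (protein, peptide, ascending y-index), so writing the
#' same panel twice yields byte-identical files.
#'
#' @param panel data.frame with columns `protein`, `peptide`,
#'   `precursor_mz`, `product_mz`, `fragment_label`, `collision_energy`,
#'   `precursor_charge`.
#' @param path Output CSV path.
#' @param header Optional character vector of `#`-prefixed provenance lines
#'   written above the table.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(panel, path, header = NULL) {
  if (is.null(panel) || nrow(panel) == 0L) stop("empty transition panel")
  req <- c("protein", "peptide", "precursor_mz", "product_mz",
           "fragment_label", "collision_energy", "precursor_charge")
  missing <- setdiff(req, names(panel))
  if (length(missing)) stop("panel missing column(s): ",
                            paste(missing, collapse = ", "))
  yidx <- fragment_label_index(panel$fragment_label)
  ord <- order(panel$protein, panel$peptide, yidx)
  panel <- panel[ord, , drop = FALSE]
  out <- data.frame(
    protein = panel$protein,
    peptide = panel$peptide,
    precursor_mz = sprintf("%.4f", panel$precursor_mz),
    product_mz = sprintf("%.4f", panel$product_mz),
    fragment_label = panel$fragment_label,
    collision_energy = sprintf("%.2f", panel$collision_energy),
    charge = panel$precursor_charge,
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transition list CSV written by [write_transition_list()]
#'
#' @param path CSV path.
#' @return data.frame with numeric m/z columns.
#' @export
read_transition_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          comment.char = "#", stringsAsFactors = FALSE)
  req <- c("protein", "peptide", "precursor_mz", "product_mz",
           "fragment_label", "collision_energy", "charge")
  missing <- setdiff(req, names(df))
  if (length(missing)) stop("transition list missing column(s): ",
                            paste(missing, collapse = ", "))
  for (col in c("precursor_mz", "product_mz", "collision_energy")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  names(df)[names(df) == "charge"] <- "precursor_charge"
  df
}

#' Read a reference spectral library
#'
#' One row per retained transition of each peptide: columns
#' `peptide_sequence`, `fragment_label`, `ratio` (nonnegative relative
#' intensity), `reference_rt_min`. Ratios are normalized to unit sum per
#' peptide on read.
#'
#' @param path CSV path.
#' @return Named list of `ReferencePattern` objects (see
#'   [reference_pattern()]), keyed by peptide sequence.
#' @export
read_reference_library <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          comment.char = "#", stringsAsFactors = FALSE)
  req <- c("peptide_sequence", "fragment_label", "ratio", "reference_rt_min")
  missing <- setdiff(req, names(df))
  if (length(missing)) stop("reference library missing column(s): ",
                            paste(missing, collapse = ", "))
  out <- lapply(split(df, df$peptide_sequence), function(d) {
    reference_pattern(peptide = d$peptide_sequence[1],
                      ratios = stats::setNames(d$ratio, d$fragment_label),
                      reference_rt = d$reference_rt_min[1])
  })
  out
}

#' Write a reference spectral library
#'
#' @param library Named list of `ReferencePattern` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_library <- function(library, path) {
  rows <- do.call(rbind, lapply(library, function(rp) {
    data.frame(peptide_sequence = rp$peptide,
               fragment_label = names(rp$ratios),
               ratio = sprintf("%.6f", rp$ratios),
               reference_rt_min = sprintf("%.4f", rp$reference_rt),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$peptide_sequence,
                     fragment_label_index(rows$fragment_label)), ]
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference transition-intensity pattern for one peptide
#'
#' The reference side of the dotp comparison: relative transition intensity
#' ratios observed in a pure culture (or synthetic standard) plus the
#' reference retention time.
#'
#' @param peptide Peptide sequence.
#' @param ratios Named nonnegative numeric vector, one entry per retained
#'   transition (names are fragment labels, e.g. `"y4"`). Normalized to
#'   unit sum.
#' @param reference_rt Reference retention time, minutes (> 0).
#' @return A `ReferencePattern` object.
#' @export
reference_pattern <- function(peptide, ratios, reference_rt) {
  if (length(ratios) < 2L) stop("reference pattern needs >= 2 transitions")
  if (any(ratios < 0)) stop("reference ratios must be nonnegative")
  if (sum(ratios) <= 0) stop("reference ratios sum to zero")
  if (!is.numeric(reference_rt) || reference_rt <= 0) {
    stop("reference_rt must be > 0 minutes")
  }
  structure(list(peptide = peptide,
                 ratios = ratios / sum(ratios),
                 reference_rt = reference_rt),
            class = "ReferencePattern")
}

#' Read chromatogram traces
#'
#' Long-format CSV of per-transition intensity traces: columns `run_id`,
#' `peptide`, `fragment_label`, `time_min`, `intensity`. An optional
#' `replicate` column gives the technical-replicate index (default 1).
#'
#' @param path CSV path.
#' @return List of peak groups (see [peak_group()]), one per
#'   run x replicate x peptide.
#' @export
read_traces <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          comment.char = "#", stringsAsFactors = FALSE)
  req <- c("run_id", "peptide", "fragment_label", "time_min", "intensity")
  missing <- setdiff(req, names(df))
  if (length(missing)) stop("trace table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (is.null(df$replicate)) df$replicate <- 1L
  key <- interaction(df$run_id, df$replicate, df$peptide, drop = TRUE)
  lapply(split(df, key), function(d) {
    traces <- lapply(split(d, d$fragment_label), function(tr) {
      tr <- tr[order(tr$time_min), c("time_min", "intensity")]
      rownames(tr) <- NULL
      tr
    })
    # order transitions by ascending y-index
    traces <- traces[order(fragment_label_index(names(traces)))]
    peak_group(run_id = d$run_id[1], peptide = d$peptide[1],
               traces = traces, replicate = d$replicate[1])
  })
}

#' Write chromatogram traces for a list of peak groups
#'
#' @param peak_groups List of peak groups with raw traces.
#' @param path Output CSV path.
#' @param header Optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_traces <- function(peak_groups, path, header = NULL) {
  rows <- do.call(rbind, lapply(peak_groups, function(pg) {
    do.call(rbind, lapply(names(pg$traces), function(lab) {
      tr <- pg$traces[[lab]]
      data.frame(run_id = pg$run_id, peptide = pg$peptide,
                 replicate = pg$replicate, fragment_label = lab,
                 time_min = sprintf("%.5f", tr$time_min),
                 intensity = sprintf("%.4f", tr$intensity),
                 stringsAsFactors = FALSE)
    }))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(rows, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
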