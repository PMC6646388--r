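#' Rank transitions of one peptide by AUC contribution
#'
#' Computes each transition's fractional contribution to the peptide's
#' total chromatographic area (`area_i / sum(area)`), sorts descending by
#' contribution with ties broken by ascending y-index, and retains the top
#' `k` (default 5, the assay's per-peptide transition budget). Observations
#' of the same fragment across runs are summed before ranking. The ranking
#' is scale invariant: multiplying every area by a positive constant does
#' not change it.
#'
#' @param observations data.frame with columns `fragment_label` and
#'   `integrated_area` (nonnegative) for one peptide.
#' @param k Number of transitions to retain.
#' @return data.frame with columns `fragment_label`, `y_index`, `area`,
#'   `contribution`, ordered by rank.
#' @export
rank_transitions <- function(observations, k = 5L) {
  if (is.null(observations) || nrow(observations) == 0L) {
    stop("no observations to rank")
  }
  if (any(observations$integrated_area < 0)) stop("negative area")
  area <- tapply(observations$integrated_area, observations$fragment_label,
                 sum)
  total <- sum(area)
  if (total <= 0) stop("all transition areas are zero: no rankable signal")
  yidx <- fragment_label_index(names(area))
  if (anyNA(yidx)) stop("unparseable fragment label(s): ",
                        paste(names(area)[is.na(yidx)], collapse = ", "))
  contribution <- as.numeric(area) / total
  ord <- order(-contribution, yidx)
  keep <- ord[seq_len(min(k, length(ord)))]
  data.frame(fragment_label = names(area)[keep],
             y_index = yidx[keep],
             area = as.numeric(area)[keep],
             contribution = contribution[keep],
             stringsAsFactors = FALSE)
}

#' Build a per-strain ranked panel from a candidate-observation table
#'
#' Applies [rank_transitions()] to every peptide of every strain in a
#' discovery observation table.
#'
#' @param table Candidate-observation data.frame
#'   (see [read_candidate_table()]).
#' @param k Transitions retained per peptide.
#' @return List of per-strain panels: each a data.frame with columns
#'   `peptide`, `strain_id`, `fragment_label`, `y_index`, `area`,
#'   `contribution`.
#' @export
rank_panel <- function(table, k = 5L) {
  lapply(split(table, table$strain_id), function(d) {
    rows <- lapply(split(d, d$peptide_sequence), function(p) {
      r <- rank_transitions(p[, c("fragment_label", "integrated_area")], k)
      cbind(peptide = p$peptide_sequence[1], strain_id = p$strain_id[1], r,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows[order(names(rows))])
    rownames(out) <- NULL
    out
  })
}

#' Merge per-strain panels into one cross-strain panel
#'
#' Peptides with identical sequence are merged into a single panel entry
#' whose `strain_ids` is the union of contributing strains. When strains
#' retained different transition sets for a shared peptide, the set from
#' the strain with the highest total AUC wins (`mode = "best"`, logged via
#' message); `mode = "intersection"` instead keeps only transitions
#' retained in every strain. The merge is idempotent and commutative over
#' input order.
#'
#' @param panels List of per-strain panels (see [rank_panel()]).
#' @param mode `"best"` or `"intersection"`.
#' @return A `RankedPanel`: data.frame with columns `peptide`,
#'   `strain_ids` (semicolon-joined, sorted), `fragment_label`, `y_index`,
#'   `area`, `contribution`; attributes `n_peptides_unique` and
#'   `n_transitions`.
#' @export
merge_across_strains <- function(panels, mode = c("best", "intersection")) {
  mode <- match.arg(mode)
  panels <- lapply(panels, function(p) {
    p <- as.data.frame(p)
    # accept already-merged panels (strain_ids) as well as per-strain ones
    if (is.null(p[["strain_id"]])) p$strain_id <- p[["strain_ids"]]
    p[["strain_ids"]] <- NULL
    p
  })
  common_cols <- Reduce(intersect, lapply(panels, names))
  all <- do.call(rbind, lapply(unname(panels), `[`, common_cols))
  if ("product_mz" %in% names(all)) {
    key <- paste(all$peptide, all$fragment_label)
    nmz <- tapply(all$product_mz, key, function(v) length(unique(v)))
    if (any(nmz > 1)) {
      stop("conflicting product m/z across strains for: ",
           paste(names(nmz)[nmz > 1], collapse = ", "),
           " (mass/CE config mismatch)")
    }
  }
  merged <- lapply(split(all, all$peptide), function(d) {
    strains <- sort(unique(unlist(strsplit(d$strain_id, ";", fixed = TRUE))))
    per_strain <- split(d, d$strain_id)
    if (mode == "best" || length(per_strain) == 1L) {
      totals <- vapply(per_strain, function(s) sum(s$area), numeric(1))
      best <- names(totals)[order(-totals, names(totals))[1]]
      if (length(per_strain) > 1L) {
        message("peptide ", d$peptide[1], ": retained transitions taken from ",
                "strain ", best, " (highest total AUC)")
      }
      sel <- per_strain[[best]]
    } else {
      common <- Reduce(intersect, lapply(per_strain, `[[`, "fragment_label"))
      sel <- per_strain[[1]]
      sel <- sel[sel$fragment_label %in% common, , drop = FALSE]
    }
    data.frame(peptide = sel$peptide,
               strain_ids = paste(strains, collapse = ";"),
               fragment_label = sel$fragment_label,
               y_index = sel$y_index, area = sel$area,
               contribution = sel$contribution,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged[order(names(merged))])
  rownames(out) <- NULL
  attr(out, "n_peptides_unique") <- length(unique(out$peptide))
  attr(out, "n_transitions") <- nrow(out)
  class(out) <- c("RankedPanel", "data.frame")
  out
}

#' @export
print.RankedPanel <- function(x, ...) {
  cat(sprintf("RankedPanel: %d unique peptide(s), %d transition(s)\n",
              attr(x, "n_peptides_unique"), attr(x, "n_transitions")))
  NextMethod()
}

#' Multi-load linearity check of peptide signals
#'
#' A robust peptide signal should scale with the amount of digest loaded
#' on column. For every peptide observed at two or more load amounts,
#' computes the Pearson correlation between total AUC and load and flags
#' `pass` when `r >= r_threshold` (default 0.9) and the AUC is strictly
#' increasing with load. Peptides seen at a single load are flagged
#' `not_evaluable`; no peptide is silently dropped.
#'
#' @param observations data.frame with columns `peptide_sequence`,
#'   `load_amount` (e.g. µg on column), `integrated_area`.
#' @param r_threshold Minimum Pearson r.
#' @return data.frame with columns `peptide`, `n_loads`, `r`, `increasing`,
#'   `flag` (`pass`, `fail`, or `not_evaluable`).
#' @export
multi_load_consistency <- function(observations, r_threshold = 0.9) {
  res <- lapply(split(observations, observations$peptide_sequence),
                function(d) {
    auc <- tapply(d$integrated_area, d$load_amount, sum)
    loads <- as.numeric(names(auc))
    ord <- order(loads)
    loads <- loads[ord]; auc <- as.numeric(auc)[ord]
    if (length(loads) < 2L) {
      return(data.frame(peptide = d$peptide_sequence[1],
                        n_loads = length(loads), r = NA_real_,
                        increasing = NA, flag = "not_evaluable",
                        stringsAsFactors = FALSE))
    }
    r <- if (stats::sd(auc) == 0) 0 else stats::cor(loads, auc)
    inc <- all(diff(auc) > 0)
    data.frame(peptide = d$peptide_sequence[1], n_loads = length(loads),
               r = r, increasing = inc,
               flag = if (r >= r_threshold && inc) "pass" else "fail",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[order(names(res))])
  rownames(out) <- NULL
  out
}
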