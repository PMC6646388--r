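# Programmatic fixtures shared across test files.

write_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(acc) {
    c(paste0(">", acc), records[[acc]])
  }))
  writeLines(lines, path)
  path
}

# Registry with peptides planted at known tiers: TQGPEPTLDEK only in
# targets; SEMLPEPTLDER also in a related organohalide respirer;
# NLNSPECPEPK also in an unrelated background organism.
fixture_registry <- function() {
  pad <- function(pep) paste0("GGGAAAR", pep, "AAAGGGK")
  list(
    proteome("tA", category = "target", accessions = c("tA1", "tA2"),
             sequences = c(pad("TQGPEPTLDEK"), pad("SEMLPEPTLDER"))),
    proteome("tB", category = "target", accessions = "tB1",
             sequences = pad("NLNSPECPEPK")),
    proteome("rel", category = "related_ohrb", accessions = "r1",
             sequences = pad("SEMLPEPTLDER")),
    proteome("oth", category = "other", accessions = "o1",
             sequences = pad("NLNSPECPEPK")))
}

# Peak group built from integrated summaries only.
summary_group <- function(peptide, areas, apex, run_id = "run",
                          replicate = 1L) {
  peak_group(run_id = run_id, peptide = peptide, areas = areas,
             apex_rt = apex, replicate = replicate)
}

faithful_replicates <- function(reference, config, seed0, n = 3L) {
  lapply(seq_len(n), function(r) {
    simulate_peak_group(reference, config, seed = seed0 + r, replicate = r)
  })
}
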