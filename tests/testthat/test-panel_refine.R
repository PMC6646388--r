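test_that("transitions are ranked by AUC contribution with the y-index tie-break", {
  obs <- data.frame(fragment_label = paste0("y", 3:8),
                    integrated_area = c(10, 50, 5, 30, 20, 15))
  r <- rank_transitions(obs, k = 5)
  expect_equal(r$fragment_label, c("y4", "y6", "y7", "y8", "y3"))
  expect_equal(sum(r$contribution), 1 - 5 / 130)  # y5 dropped
  expect_equal(r$contribution[1], 50 / 130)

  r4 <- rank_transitions(obs[1:4, ], k = 5)
  expect_equal(nrow(r4), 4L)  # k exceeds supply

  tie <- data.frame(fragment_label = c("y7", "y3"),
                    integrated_area = c(10, 10))
  expect_equal(rank_transitions(tie, k = 1)$fragment_label, "y3")

  zero <- data.frame(fragment_label = c("y3", "y4"),
                     integrated_area = c(0, 0))
  expect_error(rank_transitions(zero), "no rankable signal")
})

test_that("ranking is scale invariant and bounded at k", {
  set.seed(601)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    obs <- data.frame(fragment_label = paste0("y", 3:(n + 2)),
                      integrated_area = runif(n, 0.1, 100))
    r1 <- rank_transitions(obs, k = 5)
    obs2 <- obs; obs2$integrated_area <- obs2$integrated_area * 1e4
    r2 <- rank_transitions(obs2, k = 5)
    expect_equal(r1$fragment_label, r2$fragment_label)
    expect_equal(r1$contribution, r2$contribution, tolerance = 1e-12)
    expect_lte(nrow(r1), 5L)
  }
})

make_strain_panel <- function(peptides, strain, area_base = 100) {
  do.call(rbind, lapply(peptides, function(p) {
    data.frame(peptide = p, strain_id = strain,
               fragment_label = paste0("y", 3:5), y_index = 3:5,
               area = area_base * c(3, 2, 1),
               contribution = c(3, 2, 1) / 6,
               stringsAsFactors = FALSE)
  }))
}

test_that("cross-strain merge unions strains and keeps counts consistent", {
  pa <- make_strain_panel(c("AAAAAAK", "CCCCCCK"), "s195")
  pb <- make_strain_panel(c("AAAAAAK", "DDDDDDK"), "sFL2", area_base = 50)
  m <- merge_across_strains(list(pa, pb))
  expect_equal(attr(m, "n_peptides_unique"), 3L)
  shared <- m[m$peptide == "AAAAAAK", ]
  expect_equal(unique(shared$strain_ids), "s195;sFL2")
  # higher-total-AUC strain's transitions win
  expect_equal(unique(shared$area / c(3, 2, 1)), 100)

  disj <- merge_across_strains(list(
    make_strain_panel(paste0("PEP", 1:3, "AAK"), "a"),
    make_strain_panel(paste0("PEP", 4:7, "AAK"), "b")))
  expect_equal(attr(disj, "n_peptides_unique"), 7L)
  expect_equal(attr(disj, "n_transitions"), nrow(disj))

  # idempotent and commutative
  m1 <- merge_across_strains(list(pa, pb))
  m2 <- merge_across_strains(list(pb, pa))
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  expect_equal(as.data.frame(merge_across_strains(list(m1)))[
    , c("peptide", "fragment_label", "area")],
    as.data.frame(m1)[, c("peptide", "fragment_label", "area")])
})

test_that("strain-panel union size matches the set-union oracle", {
  # per-strain panel sizes mirroring a three-strain selection with overlaps
  set.seed(602)
  pool <- unique(replicate(60, random_candidate_peptide()))
  sizes <- c(29, 22, 17)
  picks <- lapply(sizes, function(n) sample(pool, n))
  panels <- Map(make_strain_panel, picks, c("s195", "sFL2", "sBAV1"))
  m <- merge_across_strains(panels)
  expect_equal(attr(m, "n_peptides_unique"),
               length(Reduce(union, picks)))
  expect_equal(attr(m, "n_transitions"), 3L * length(Reduce(union, picks)))
})

test_that("merge rejects conflicting transition m/z configs", {
  pa <- make_strain_panel("AAAAAAK", "a")
  pa$product_mz <- c(300, 400, 500)
  pb <- make_strain_panel("AAAAAAK", "b")
  pb$product_mz <- c(300, 400, 501.5)
  expect_error(merge_across_strains(list(pa, pb)), "product m/z")
})

test_that("multi-load linearity flags match an independent Pearson oracle", {
  obs <- data.frame(peptide_sequence = "AAAAAAK",
                    load_amount = c(0.5, 2, 8),
                    integrated_area = c(1, 4, 16))
  r <- multi_load_consistency(obs)
  expect_equal(r$flag, "pass")
  expect_equal(r$r, 1, tolerance = 1e-12)

  flat <- obs; flat$integrated_area <- c(5, 5, 5)
  expect_equal(multi_load_consistency(flat)$flag, "fail")

  single <- obs[1, ]
  expect_equal(multi_load_consistency(single)$flag, "not_evaluable")

  set.seed(603)
  noisy <- data.frame(peptide_sequence = "CCCCCCK",
                      load_amount = c(0.5, 2, 8),
                      integrated_area = c(0.5, 2, 8) * 10 +
                        rnorm(3, 0, 0.5))
  got <- multi_load_consistency(noisy)
  expect_equal(got$r, oracle_pearson(noisy$load_amount,
                                     noisy$integrated_area),
               tolerance = 1e-12)
})
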