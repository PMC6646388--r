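test_that("tier assignment follows the category precedence", {
  reg <- fixture_registry()
  r1 <- classify_specificity("TQGPEPTLDEK", reg)
  expect_equal(r1$tier, "specific")
  expect_equal(r1$action, "keep")
  expect_true(all(r1$hits$category == "target"))

  r2 <- classify_specificity("SEMLPEPTLDER", reg)
  expect_equal(r2$tier, "semi_specific")
  expect_equal(r2$action, "keep_with_caveat")

  r3 <- classify_specificity("NLNSPECPEPK", reg)
  expect_equal(r3$tier, "non_specific")  # other wins over related_ohrb
  expect_equal(r3$action, "remove")

  # absent everywhere: vacuously specific
  r4 <- classify_specificity("WWWWYYYK", reg)
  expect_equal(r4$tier, "specific")
  expect_equal(nrow(r4$hits), 0L)

  expect_error(classify_specificity("AAAK", reg[4]), "no target")
})

test_that("precedence is exhaustive over category combinations", {
  # brute force every presence pattern over {target, related, other}
  pad <- function(pep) paste0("GGGAAAR", pep, "AAAGGGK")
  pep <- "TESTPEPTLDEK"
  for (in_rel in c(FALSE, TRUE)) for (in_oth in c(FALSE, TRUE)) {
    reg <- list(
      proteome("t", category = "target", accessions = "t1",
               sequences = pad(pep)),
      proteome("r", category = "related_ohrb", accessions = "r1",
               sequences = if (in_rel) pad(pep) else "GGGAAAKCCCNNNK"),
      proteome("o", category = "other", accessions = "o1",
               sequences = if (in_oth) pad(pep) else "GGGAAAKCCCNNNK"))
    expected <- if (in_oth) "non_specific" else
      if (in_rel) "semi_specific" else "specific"
    expect_equal(classify_specificity(pep, reg)$tier, expected)
  }
})

test_that("peptidome and substring match semantics differ as designed", {
  # peptide embedded without tryptic boundaries: substring finds it,
  # peptidome does not
  reg <- list(
    proteome("t", category = "target", accessions = "t1",
             sequences = "GGGAAARTESTPEPTLDEKAAAGGGK"),
    proteome("o", category = "other", accessions = "o1",
             sequences = "GGGAAATESTPEPTLDEGAAAGGGK"))
  expect_equal(classify_specificity("TESTPEPTLDEK", reg,
                                    match = "peptidome")$tier, "specific")
  expect_equal(classify_specificity("TESTPEPTLDE", reg,
                                    match = "substring")$tier,
               "non_specific")
})

test_that("substring classification agrees with brute-force search", {
  set.seed(501)
  regs <- lapply(1:3, function(i) {
    proteome(paste0("p", i),
             category = c("target", "related_ohrb", "other")[i],
             accessions = paste0("p", i, "_", 1:10),
             sequences = vapply(1:10, function(j) random_protein_seq(120),
                                character(1)))
  })
  peps <- unlist(lapply(regs, build_peptidome,
                        params = digest_params(min_len = 5, max_len = 18,
                                               exclude_residues = NULL)))
  peps <- sample(unique(peps), 30)
  for (pep in peps) {
    got <- classify_specificity(pep, regs, match = "substring")
    hit_cat <- unlist(lapply(regs, function(pr) {
      if (any(grepl(pep, pr$proteins$sequence, fixed = TRUE))) pr$category
    }))
    expected <- if ("other" %in% hit_cat) "non_specific" else
      if ("related_ohrb" %in% hit_cat) "semi_specific" else "specific"
    expect_equal(got$tier, expected)
  }
})

test_that("classification is monotone under added background", {
  reg <- fixture_registry()
  tiers <- c(specific = 1, semi_specific = 2, non_specific = 3)
  extra <- proteome("bg", category = "other", accessions = "b1",
                    sequences = "GGGAAARSEMLPEPTLDERAAAGGGK")
  for (pep in c("TQGPEPTLDEK", "SEMLPEPTLDER", "NLNSPECPEPK")) {
    before <- tiers[classify_specificity(pep, reg)$tier]
    after <- tiers[classify_specificity(pep, c(reg, list(extra)))$tier]
    expect_gte(after, before)
  }
})

test_that("peptidome similarity behaves as a bounded symmetric set metric", {
  A <- c("p1", "p2", "p3"); B <- c("p2", "p3", "p4")
  expect_equal(peptidome_similarity(A, A), 100)
  expect_equal(peptidome_similarity(A, c("q1", "q2")), 0)
  expect_equal(peptidome_similarity(A, B), 50)  # 2 shared / 4 union
  expect_equal(peptidome_similarity(A, B), peptidome_similarity(B, A))
  expect_equal(peptidome_similarity(A, B, method = "overlap"), 100 * 2 / 3)
  expect_error(peptidome_similarity(A, character(0)), "empty")

  set.seed(502)
  for (i in 1:20) {
    a <- sample(letters, sample(3:10, 1))
    b <- sample(letters, sample(3:10, 1))
    s <- peptidome_similarity(a, b)
    expect_gte(s, 0); expect_lte(s, 100)
    expect_equal(s == 100, setequal(a, b))
  }
})

test_that("similarity matrix is symmetric with a 100 diagonal", {
  set.seed(503)
  regs <- lapply(1:3, function(i) {
    proteome(paste0("p", i), category = "target",
             accessions = paste0("p", i, "_", 1:4),
             sequences = vapply(1:4, function(j) random_protein_seq(200),
                                character(1)))
  })
  m <- similarity_matrix(regs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_true(all(m >= 0 & m <= 100))
})

test_that("panel screening removes exactly the non-specific candidates", {
  reg <- fixture_registry()
  pad_peps <- c("TQGPEPTLDEK", "SEMLPEPTLDER", "NLNSPECPEPK",
                "GGGAAAR", "AAAGGGK")
  rep <- screen_panel(pad_peps, reg)
  expect_equal(nrow(rep), 5L)
  expect_equal(rep$peptide, sort(pad_peps))  # deterministic ordering
  s <- attr(rep, "summary")
  expect_equal(sum(s), nrow(rep))
  # conservation: kept + removed = input
  expect_equal(length(attr(rep, "kept")) + sum(rep$action == "remove"),
               nrow(rep))

  empty <- screen_panel(character(0), reg)
  expect_equal(nrow(empty), 0L)
  expect_equal(unname(attr(empty, "summary")), c(0L, 0L, 0L))
})
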