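# Additive scoring of cores, peptides and FASTA files; decoy generation.

test_that("core scoring sums per-position coefficients, flanks only when covered", {
  zero <- toy_qm(zero_matrix())
  expect_equal(score_core(zero, "QPFPQPELP"), 0)

  # coefficient 0.1 at every residue actually present in the core
  m <- zero_matrix()
  core <- "QPFPQPELP"
  chars <- strsplit(core, "")[[1]]
  for (k in 1:9) m[paste0("p", k), chars[k]] <- 0.1
  expect_equal(score_core(toy_qm(m), core), 0.9)

  # whole-peptide matrix adds flank terms; absent flanks contribute 0
  mw <- zero_matrix("whole_peptide")
  for (k in 1:9) mw[paste0("p", k), chars[k]] <- 0.1
  mw["p0", "Q"] <- 0.05; mw["p10", "P"] <- 0.025
  qw <- toy_qm(mw, mode = "whole_peptide")
  expect_equal(score_core(qw, core, p0 = "Q", p10 = "P"), 0.975)
  expect_equal(score_core(qw, core), 0.9)
  # core-mode matrices ignore flanks entirely
  expect_equal(score_core(toy_qm(m), core, p0 = "Q", p10 = "P"), 0.9)

  expect_error(score_core(zero, "QPFPQPEL"), "9 residues")
  expect_error(score_core(zero, "QPFPQPXLP"), "'X'")
})

test_that("parent core under its own QM scores 9 times the parent coefficient", {
  lib <- build_saas_library(gliadin_parent())
  set.seed(3)
  tab <- score_table(lib$variants$peptide_id, stats::runif(210, -9, -5),
                     config = docking_config(engine_tag = "toy"))
  qm <- build_qm(lib, tab, mode = "core")
  parent_aff <- tab$affinity_kcal[tab$peptide_id == "aglia_wt"]
  expect_equal(score_core(qm, substr("QPFPQPELPYP", 2, 10)),
               9 * (parent_aff / qm$mu - 1))
})

test_that("peptide scoring enumerates registers with smallest-offset tie-break", {
  zero <- toy_qm(zero_matrix())
  r <- score_peptide(zero, "QPFPQPELPYP")
  expect_equal(nrow(r$registers), 3)
  expect_equal(r$best_register, 0)   # all tie at 0; lowest offset wins
  expect_equal(r$best_score, 0)

  r9 <- score_peptide(zero, "QPFPQPELP")
  expect_equal(nrow(r9$registers), 1)
  expect_error(score_peptide(zero, "QPFPQPEL"), "shorter")
})

test_that("best-register scores match the brute-force enumeration oracle", {
  set.seed(71)
  for (mode in c("core", "whole_peptide")) {
    m <- zero_matrix(mode)
    m[] <- round(stats::rnorm(length(m), 0, 0.3), 3)
    qm <- toy_qm(m, mode = mode)
    for (i in 1:50) {
      pep <- random_peptide(sample(9:25, 1))
      got <- score_peptide(qm, pep)
      want <- brute_force_best(qm, pep)
      expect_equal(got$best_score, want$best_score)
      expect_equal(got$best_register, want$best_register)
    }
  }
})

test_that("FASTA screening counts windows, skips non-standard residues, honours the inclusive call", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">prot20", paste(rep("QPFPQPELPY", 2), collapse = ""),
               ">withX", "QPFPQPXLPYPQPFP",
               ">short", "QPFPQ"), fa)
  zero <- toy_qm(zero_matrix())
  rep0 <- screen_fasta(zero, fa, cutoff = 0)
  p <- rep0$proteins
  expect_equal(p$n_windows[p$protein_id == "prot20"], 12)  # 20 - 9 + 1
  # X at 0-based offset 6 poisons windows with register offsets 0..6 that
  # reach it: starts max(0, 6-8)..6 intersect 0..6 -> 7 windows
  expect_equal(p$n_skipped[p$protein_id == "withX"], 7)
  expect_equal(p$n_windows[p$protein_id == "withX"], 15 - 9 + 1 - 7)
  expect_equal(p$n_windows[p$protein_id == "short"], 0)
  # zero QM at cutoff 0: every clean window called binder (score >= cutoff)
  expect_true(all(rep0$windows$call == "binder"))
  expect_equal(sum(p$n_binders), nrow(rep0$windows))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(screen_fasta(zero, empty), "empty FASTA")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_screening_report(rep0, out)
  body <- utils::read.delim(out, comment.char = "#")
  expect_equal(nrow(body), nrow(rep0$windows))
  expect_equal(body$register_offset, rep0$windows$register_offset)
})

test_that("preferred/non-preferred sets partition residues by coefficient sign", {
  m <- zero_matrix()
  m["p6", c("D", "K", "P")] <- -0.4
  m["p6", "W"] <- 0.3
  qm <- toy_qm(m)
  np <- nonpreferred_from_qm(qm)
  expect_equal(np$p6, c("D", "K", "P"))
  expect_equal(np$p1, character(0))
  expect_equal(preferred_from_qm(qm)$p6, "W")
  # threshold below the minimum leaves all sets empty
  np2 <- nonpreferred_from_qm(qm, threshold = -0.5)
  expect_true(all(lengths(np2) == 0))
})

test_that("decoys draw core residues from the non-preferred sets, reproducibly", {
  set.seed(83)
  m <- zero_matrix()
  m[] <- stats::rnorm(length(m), 0, 0.3)
  qm <- toy_qm(m)
  np <- nonpreferred_from_qm(qm)
  d <- generate_decoys(np, 300, length = 9, seed = 9)
  expect_equal(length(d), 300)
  expect_true(all(nchar(d) == 9))
  for (k in 1:9) {
    expect_true(all(substr(d, k, k) %in% np[[paste0("p", k)]]))
  }
  expect_identical(generate_decoys(np, 300, length = 9, seed = 9), d)
  expect_false(identical(generate_decoys(np, 300, length = 9, seed = 10), d))

  # singleton sets leave no randomness
  single <- lapply(setNames(nm = paste0("p", 1:9)), function(...) "A")
  expect_equal(unique(generate_decoys(single, 5, seed = 1)), "AAAAAAAAA")
  # empty set at any core position is an error naming the position
  empty <- single; empty$p4 <- character(0)
  expect_error(generate_decoys(empty, 5, seed = 1), "p4")

  # nonamer decoys from threshold-0 sets score < 0 (sum of negative terms)
  sc <- predict(qm, d)$score
  expect_true(all(sc < 0))
})
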