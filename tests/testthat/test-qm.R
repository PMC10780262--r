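# Quantitative-matrix fitting, normalization identities, comparison, IO.

# Build a score table assigning a given affinity to every library member.
constant_scores <- function(lib, value) {
  score_table(lib$variants$peptide_id, rep(value, nrow(lib$variants)),
              config = docking_config(engine_tag = "toy"))
}

test_that("all-equal affinities give an all-zero matrix; mu = 0 is rejected", {
  lib <- build_saas_library(gliadin_parent())
  for (mode in c("core", "whole_peptide")) {
    qm <- build_qm(lib, constant_scores(lib, -6.5), mode = mode)
    expect_true(all(qm$contributions == 0))
    expect_equal(qm$mu, -6.5)
  }
  expect_error(build_qm(lib, constant_scores(lib, 0), mode = "core"),
               "degenerate")
})

test_that("contribution coefficients follow s/mu - 1 on hand-built scores", {
  lib <- build_saas_library(gliadin_parent())
  tab <- constant_scores(lib, -7)
  # mu stays -7 if two symmetric perturbations cancel: put F at p4 to -8.4
  # and P... instead keep mu exact by perturbing a pair +/-1.4 within p4
  aff <- setNames(tab$affinity_kcal, tab$peptide_id)
  aff[["aglia_p4F"]] <- -8.4
  aff[["aglia_p4A"]] <- -5.6
  tab2 <- score_table(names(aff), unname(aff),
                      config = docking_config(engine_tag = "toy"))
  qm <- build_qm(lib, tab2, mode = "core")
  expect_equal(qm$mu, -7)
  expect_equal(qm$contributions["p4", "F"], 0.2)   # -8.4 / -7 - 1
  expect_equal(qm$contributions["p4", "A"], -0.2)  # -5.6 / -7 - 1
  expect_equal(qm$contributions["p1", "W"], 0)     # untouched variant
})

test_that("contributions over the normalization set average exactly zero", {
  lib <- build_saas_library(gliadin_parent())
  set.seed(17)
  tab <- score_table(lib$variants$peptide_id, stats::runif(210, -9, -5),
                     config = docking_config(engine_tag = "toy"))
  chars <- strsplit(lib$parent$sequence, "")[[1]]
  for (mode in c("core", "whole_peptide")) {
    qm <- build_qm(lib, tab, mode = mode)
    labels <- qm$labels
    # the normalization set's contributions: one per variant in covered
    # positions plus the parent (counted once)
    v <- lib$variants[lib$variants$substituted_label %in% labels, ]
    parent_contrib <- qm$contributions[labels[1],
                                       chars[offset_for_label(lib$parent, labels[1]) + 1]]
    vals <- c(parent_contrib,
              qm$contributions[cbind(v$substituted_label, v$substituted_aa)])
    expect_equal(length(vals), 1 + 19 * length(labels))
    expect_lt(abs(mean(vals)), 1e-12)
  }
})

test_that("the matrix is invariant to affinity rescaling and shifts as the formula dictates", {
  lib <- build_saas_library(gliadin_parent())
  set.seed(23)
  aff <- stats::runif(210, -9, -5)
  mk <- function(a) score_table(lib$variants$peptide_id, a,
                                config = docking_config(engine_tag = "toy"))
  qm1 <- build_qm(lib, mk(aff), mode = "core")
  qm2 <- build_qm(lib, mk(3.7 * aff), mode = "core")
  expect_equal(qm2$contributions, qm1$contributions)
  # additive shift c: contributions become (s - mu) / (mu + c)
  qm3 <- build_qm(lib, mk(aff + 1), mode = "core")
  expect_equal(qm3$contributions,
               qm1$contributions * qm1$mu / (qm1$mu + 1))
})

test_that("lower affinity means strictly higher contribution at a position", {
  lib <- build_saas_library(gliadin_parent())
  set.seed(31)
  tab <- score_table(lib$variants$peptide_id, stats::runif(210, -9, -5),
                     config = docking_config(engine_tag = "toy"))
  qm <- build_qm(lib, tab, mode = "core")
  aff <- setNames(tab$affinity_kcal, tab$peptide_id)
  v <- lib$variants[lib$variants$substituted_label == "p5", ]
  ord <- order(aff[v$peptide_id])
  expect_true(all(diff(qm$contributions["p5", v$substituted_aa[ord]]) < 0))
})

test_that("noise-free planted models are recovered with perfect rank agreement", {
  p <- gliadin_parent()
  lib <- build_saas_library(p)
  gt <- sample_ground_truth(paste0("p", 0:10), seed = 41)
  tab <- simulate_library_scores(gt, lib)
  for (mode in c("core", "whole_peptide")) {
    qm <- build_qm(lib, tab, mode = mode)
    for (lab in qm$labels) {
      expect_equal(stats::cor(gt$delta[lab, ], qm$contributions[lab, ],
                              method = "spearman"), -1)
      # within a position, contributions are affine in delta with slope 1/mu
      fit <- stats::lm(qm$contributions[lab, ] ~ gt$delta[lab, ])
      expect_equal(unname(stats::coef(fit)[2]), 1 / qm$mu, tolerance = 1e-9)
    }
  }
})

test_that("moderate score noise still recovers residue rankings", {
  p <- gliadin_parent()
  lib <- build_saas_library(p)
  gt <- sample_ground_truth(paste0("p", 0:10), seed = 41,
                            noise_sd_kcal = 0.1)
  qm <- build_qm(lib, simulate_library_scores(gt, lib), mode = "core")
  rho <- vapply(qm$labels, function(lab) {
    stats::cor(gt$delta[lab, ], qm$contributions[lab, ], method = "spearman")
  }, numeric(1))
  expect_true(all(abs(rho) >= 0.9))
})

test_that("missing library scores are reported by peptide id", {
  lib <- build_saas_library(gliadin_parent())
  tab <- constant_scores(lib, -7)
  short <- score_table(tab$peptide_id[-3], tab$affinity_kcal[-3],
                       config = attr(tab, "config"))
  expect_error(build_qm(lib, short, mode = "core"),
               tab$peptide_id[3], fixed = TRUE)
})

test_that("position-wise QM comparison matches a brute-force Pearson formula", {
  set.seed(53)
  m1 <- zero_matrix(); m2 <- zero_matrix()
  m1[] <- stats::rnorm(length(m1)); m2[] <- stats::rnorm(length(m2))
  qa <- toy_qm(m1); qb <- toy_qm(m2)
  r <- compare_qms(qa, qb)
  expect_named(r, paste0("p", 1:9))
  # independent textbook computation at p4
  x <- m1["p4", ]; y <- m2["p4", ]
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(r["p4"]), hand)
  expect_equal(unname(compare_qms(qa, qa)), rep(1, 9))
  neg <- toy_qm(-m1)
  expect_equal(unname(compare_qms(qa, neg)), rep(-1, 9))
  # zero variance gives NA with a warning, never a silent 0
  flat <- toy_qm(zero_matrix())
  expect_warning(r0 <- compare_qms(qa, flat, labels = "p1"), "undefined")
  expect_true(is.na(r0["p1"]))
})

test_that("QM files round-trip at full float precision and are validated", {
  lib <- build_saas_library(gliadin_parent())
  gt <- sample_ground_truth(paste0("p", 0:10), seed = 61,
                            noise_sd_kcal = 0.05)
  qm <- build_qm(lib, simulate_library_scores(gt, lib), mode = "core",
                 allele = "HLA-DQ2.5", cutoff = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_qm(qm, f)
  back <- read_qm(f)
  expect_identical(back$contributions, qm$contributions)
  expect_identical(back$mu, qm$mu)
  expect_equal(back[c("allele", "mode", "labels", "parent_id", "cutoff")],
               qm[c("allele", "mode", "labels", "parent_id", "cutoff")])
  expect_equal(back$config, qm$config)

  # missing residue column
  lines <- readLines(f)
  writeLines(gsub(",C,", ",c2,", lines, fixed = TRUE), f)
  expect_error(read_qm(f), "residue column.*C")
  # mode/label mismatch
  write_qm(qm, f)
  lines <- readLines(f)
  writeLines(sub("^mode: core$", "mode: whole_peptide", lines), f)
  expect_error(read_qm(f), "mode")
})
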