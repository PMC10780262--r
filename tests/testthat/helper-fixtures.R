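# Shared fixtures and independent oracles for the test suite.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

gliadin_parent <- function() {
  parent_peptide("QPFPQPELPYP", core_start = 1, id = "aglia")
}

dq8_parent <- function() {
  parent_peptide("SGEGSFQPSQENP", core_start = 2, id = "dq8",
                 fixed = c("p-1", "p11"))
}

# Assemble a "dqm" object directly from a contributions matrix, bypassing
# build_qm, so scoring can be tested against hand-built matrices.
toy_qm <- function(contributions, mode = "core", mu = -7, cutoff = NULL) {
  labels <- if (mode == "core") paste0("p", 1:9) else paste0("p", 0:10)
  stopifnot(identical(rownames(contributions), labels),
            identical(colnames(contributions), AAS))
  structure(list(allele = "toy", mode = mode, labels = labels,
                 contributions = contributions, mu = mu, parent_id = "toy",
                 config = docking_config(engine_tag = "toy"),
                 cutoff = cutoff),
            class = "dqm")
}

zero_matrix <- function(mode = "core") {
  labels <- if (mode == "core") paste0("p", 1:9) else paste0("p", 0:10)
  matrix(0, nrow = length(labels), ncol = 20,
         dimnames = list(labels, AAS))
}

# Independent brute-force oracle: best additive window score of a peptide,
# enumerating registers and summing residue coefficients one by one.
brute_force_best <- function(qm, peptide) {
  chars <- strsplit(peptide, "")[[1]]
  n <- length(chars)
  best <- -Inf; best_r <- NA
  for (r in 0:(n - 9)) {
    terms <- numeric(0)
    for (k in 1:9) {
      terms <- c(terms, qm$contributions[paste0("p", k), chars[r + k]])
    }
    if (qm$mode == "whole_peptide") {
      if (r >= 1) terms <- c(terms, qm$contributions["p0", chars[r]])
      if (r + 10 <= n) terms <- c(terms, qm$contributions["p10", chars[r + 10]])
    }
    s <- sum(terms)
    if (s > best) { best <- s; best_r <- r }
  }
  list(best_score = best, best_register = best_r)
}

random_peptide <- function(len) paste(sample(AAS, len, replace = TRUE),
                                      collapse = "")
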