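#' Fit a quantitative matrix from library docking scores
#'
#' `build_qm()` is the central estimator of the package. It converts the best
#' docking affinities of a SAAS combinatorial library into a quantitative
#' matrix (QM): a position x amino-acid table of dimensionless contribution
#' coefficients in which positive values mark residues that strengthen
#' predicted binding and negative values residues that weaken it.
#'
#' Let `N` be the normalization set: the parent peptide plus every variant
#' whose substituted position lies within the QM's coverage — the binding
#' core `p1..p9` for `mode = "core"` (parent + 171 variants of a full
#' library), or core plus flanks `p0..p10` for `mode = "whole_peptide"`
#' (parent + 209). With `mu` the mean affinity over `N` (negative for any
#' realistic docking run), the coefficient of residue `a` at position `L` is
#'
#' \deqn{c(L, a) = s(L, a) / \mu - 1}
#'
#' where `s(L, a)` is the best affinity of the variant carrying `a` at `L`,
#' and the parent's own affinity for the parent residue at every position.
#' Because `mu < 0`, stronger-than-average (more negative) affinities map to
#' positive coefficients, and the coefficients over `N` average exactly zero.
#' The matrix is invariant to rescaling all affinities by a positive factor.
#' A known artefact of SAAS designs: the parent residue's coefficient is the
#' same number at every position, since it always reuses the single parent
#' affinity.
#'
#' @param lib A [build_saas_library()] library whose mutable positions cover
#'   the requested mode's labels.
#' @param scores A [score_table()] with one best affinity per library member.
#' @param mode `"core"` (nonamer QM over `p1..p9`) or `"whole_peptide"`
#'   (endecamer QM over `p0..p10`).
#' @param allele Allele tag stored in the QM (e.g. `"HLA-DQ2.5"`).
#' @param cutoff Optional recommended score cutoff to store with the matrix.
#' @return An object of class `"dqm"`: list with `allele`, `mode`, `labels`,
#'   `contributions` (matrix, positions x 20 residues), `mu` (normalization
#'   mean, kcal/mol), `parent_id`, `config`, `cutoff`. Supported methods:
#'   [coef()], [predict.dqm()], [plot.dqm()], `print()`, `summary()`.
#' @examples
#' parent <- parent_peptide("QPFPQPELPYP", core_start = 1, id = "aglia")
#' lib <- build_saas_library(parent)
#' gt <- sample_ground_truth(paste0("p", 0:10), seed = 7, reference = parent)
#' qm <- build_qm(lib, simulate_library_scores(gt, lib), mode = "core")
#' round(coef(qm)["p4", c("F", "P")], 3)
#' @export
build_qm <- function(lib, scores, mode = c("core", "whole_peptide"),
                     allele = "HLA-DQ2.5", cutoff = NULL) {
  stopifnot(inherits(lib, "saas_library"), inherits(scores, "score_table"))
  mode <- match.arg(mode)
  labels <- if (mode == "core") CORE_LABELS else paste0("p", 0:10)

  missing_lab <- setdiff(labels, lib$parent$mutable_labels)
  if (length(missing_lab)) {
    stop(sprintf("library does not substitute position(s) %s required for mode '%s'",
                 paste(missing_lab, collapse = ", "), mode), call. = FALSE)
  }
  aff <- stats::setNames(scores$affinity_kcal, scores$peptide_id)
  missing_pep <- setdiff(lib$variants$peptide_id, names(aff))
  if (length(missing_pep)) {
    stop("missing score for library member(s): ",
         paste(missing_pep, collapse = ", "), call. = FALSE)
  }

  v <- lib$variants
  in_set <- v$substituted_label == "wt" | v$substituted_label %in% labels
  mu <- mean(aff[v$peptide_id[in_set]])
  if (mu == 0) stop("degenerate normalization: mean affinity is 0", call. = FALSE)

  parent_aff <- aff[[v$peptide_id[v$substituted_label == "wt"][1L]]]
  chars <- strsplit(lib$parent$sequence, "", fixed = TRUE)[[1L]]
  contrib <- matrix(NA_real_, nrow = length(labels), ncol = 20L,
                    dimnames = list(labels, AA_ALPHABET))
  for (lab in labels) {
    wt <- chars[offset_for_label(lib$parent, lab) + 1L]
    contrib[lab, wt] <- parent_aff / mu - 1
    rows <- v[v$substituted_label == lab, ]
    contrib[lab, rows$substituted_aa] <- aff[rows$peptide_id] / mu - 1
  }
  stopifnot(!anyNA(contrib))

  structure(list(allele = as.character(allele), mode = mode, labels = labels,
                 contributions = contrib, mu = mu,
                 parent_id = lib$parent$id,
                 config = attr(scores, "config"),
                 cutoff = if (is.null(cutoff)) NULL else as.numeric(cutoff)),
            class = "dqm")
}

#' @export
print.dqm <- function(x, digits = 3, ...) {
  cat(sprintf("Quantitative matrix for %s (%s normalization)\n",
              x$allele, sub("_", "-", x$mode)))
  cat(sprintf("  parent %s, normalization mean %.3f kcal/mol%s\n",
              x$parent_id, x$mu,
              if (is.null(x$cutoff)) "" else
                sprintf(", recommended cutoff %g", x$cutoff)))
  print(round(x$contributions, digits))
  invisible(x)
}

#' @export
summary.dqm <- function(object, n_top = 3, ...) {
  anchors <- intersect(c("p1", "p4", "p6", "p7", "p9"), object$labels)
  pref <- t(vapply(anchors, function(lab) {
    v <- sort(object$contributions[lab, ], decreasing = TRUE)
    c(preferred = paste(names(v)[seq_len(n_top)], collapse = " "),
      non_preferred = paste(rev(names(v))[seq_len(n_top)], collapse = " "))
  }, character(2)))
  out <- list(allele = object$allele, mode = object$mode, mu = object$mu,
              cutoff = object$cutoff, anchors = pref,
              range = range(object$contributions))
  class(out) <- "summary.dqm"
  out
}

#' @export
print.summary.dqm <- function(x, ...) {
  cat(sprintf("QM %s (%s): coefficients in [%.3f, %.3f]\n",
              x$allele, x$mode, x$range[1L], x$range[2L]))
  cat("Anchor-position preferences (top residues):\n")
  print(x$anchors, quote = FALSE)
  invisible(x)
}

#' @export
coef.dqm <- function(object, ...) object$contributions

#' Position-wise correlation between two quantitative matrices
#'
#' Pearson correlation of the 20 paired contribution coefficients at each
#' position shared by the two QMs — the standard way to ask whether two
#' libraries (e.g. a rigid poly-Pro gliadin backbone vs. a flexible
#' non-gliadin one) agree on residue preferences at a groove position.
#'
#' @param qm_a,qm_b Objects of class `"dqm"`.
#' @param labels Positions to compare; default all shared positions.
#' @return Named numeric vector of correlation coefficients. A position at
#'   which either QM has zero variance yields `NA` with a warning, never a
#'   silent 0.
#' @export
compare_qms <- function(qm_a, qm_b, labels = NULL) {
  stopifnot(inherits(qm_a, "dqm"), inherits(qm_b, "dqm"))
  shared <- intersect(qm_a$labels, qm_b$labels)
  if (is.null(labels)) labels <- shared
  bad <- setdiff(labels, shared)
  if (length(bad)) {
    stop("position(s) not covered by both QMs: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- vapply(labels, function(lab) {
    a <- qm_a$contributions[lab, ]
    b <- qm_b$contributions[lab, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning(sprintf("zero contribution variance at %s: correlation undefined", lab),
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(a, b)
  }, numeric(1))
  stats::setNames(out, labels)
}

#' Plot contribution coefficients at selected positions
#'
#' Bar charts of the 20 amino-acid coefficients, one panel per position —
#' positive bars are preferred residues, negative bars non-preferred.
#'
#' @param x A `"dqm"`.
#' @param labels Positions to plot; default the HLA-DQ anchor positions
#'   covered by the matrix.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.dqm <- function(x, labels = NULL, ...) {
  if (is.null(labels)) {
    labels <- intersect(c("p1", "p4", "p6", "p7", "p9"), x$labels)
  }
  old <- graphics::par(mfrow = c(length(labels), 1),
                       mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (lab in labels) {
    graphics::barplot(x$contributions[lab, ], main = lab,
                      ylab = "contribution", las = 1, cex.names = 0.8, ...)
    graphics::abline(h = 0)
  }
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a quantitative matrix
#'
#' The file is YAML front matter (allele, mode, normalization mean, parent,
#' docking config, recommended cutoff) between `---` fences, followed by a
#' CSV body: one row per position, 20 residue columns in alphabetical
#' one-letter order. Numeric fields are written at full double precision so
#' the round trip is exact.
#'
#' @param qm A `"dqm"` object.
#' @param path File path.
#' @return `read_qm()` returns the `"dqm"`; `write_qm()` returns `path`
#'   invisibly.
#' @export
write_qm <- function(qm, path) {
  stopifnot(inherits(qm, "dqm"))
  meta <- list(allele = qm$allele, mode = qm$mode, mu = fmt17(qm$mu),
               parent_id = qm$parent_id,
               cutoff = if (is.null(qm$cutoff)) NULL else fmt17(qm$cutoff),
               config = unclass(qm$config))
  body <- data.frame(label = qm$labels, stringsAsFactors = FALSE)
  for (a in AA_ALPHABET) body[[a]] <- fmt17(qm$contributions[, a])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("---", sub("\n$", "", yaml::as.yaml(meta)), "---"), con)
  utils::write.csv(body, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qm
#' @export
read_qm <- function(path) {
  lines <- readLines(path)
  fences <- which(lines == "---")
  if (length(fences) < 2L) stop("missing YAML front matter", call. = FALSE)
  meta <- yaml::yaml.load(paste(lines[(fences[1L] + 1L):(fences[2L] - 1L)],
                                collapse = "\n"))
  df <- utils::read.csv(text = lines[(fences[2L] + 1L):length(lines)],
                        stringsAsFactors = FALSE, check.names = FALSE)
  missing_col <- setdiff(AA_ALPHABET, names(df))
  if (length(missing_col)) {
    stop("QM file missing residue column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  labels <- as.character(df$label)
  label_number(labels)  # validates
  expected <- if (meta$mode == "core") CORE_LABELS else paste0("p", 0:10)
  if (!identical(sort_labels(labels), expected)) {
    stop(sprintf("mode '%s' expects positions %s..%s but file has %d rows",
                 meta$mode, expected[1L], expected[length(expected)],
                 length(labels)), call. = FALSE)
  }
  contrib <- as.matrix(df[, AA_ALPHABET])
  rownames(contrib) <- labels
  contrib <- contrib[expected, , drop = FALSE]
  cfg <- meta$config
  structure(list(
    allele = meta$allele, mode = meta$mode, labels = expected,
    contributions = contrib, mu = as.numeric(meta$mu),
    parent_id = meta$parent_id,
    config = docking_config(cfg$exhaustiveness, cfg$energy_range_kcal,
                            cfg$flexible_peptide, cfg$flexible_site,
                            cfg$site_radius_A, cfg$engine_tag),
    cutoff = if (is.null(meta$cutoff)) NULL else as.numeric(meta$cutoff)),
    class = "dqm")
}
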