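# Additive QM scoring of peptides, proteins, and decoy construction.

# Vectorized score of 9-mer windows starting at 0-based offsets `starts`
# within `chars`, under `qm`. Returns NA for windows touching a non-standard
# residue at any scored position (flank gaps at termini score 0).
#' @keywords internal
#' @noRd
score_windows <- function(qm, chars, starts) {
  n <- length(chars)
  out <- numeric(length(starts))
  for (i in seq_along(starts)) {
    r <- starts[i]
    res <- chars[(r + 1L):(r + 9L)]
    if (!all(res %in% AA_ALPHABET)) { out[i] <- NA_real_; next }
    terms <- qm$contributions[cbind(CORE_LABELS, res)]
    if (qm$mode == "whole_peptide") {
      skip <- FALSE
      for (fl in list(c("p0", r), c("p10", r + 10L))) {
        pos <- as.integer(fl[2L])
        if (pos >= 1L && pos <= n) {
          a <- chars[pos]
          if (!(a %in% AA_ALPHABET)) { skip <- TRUE; break }
          terms <- c(terms, qm$contributions[fl[1L], a])
        }
      }
      if (skip) { out[i] <- NA_real_; next }
    }
    out[i] <- sum(terms)
  }
  out
}

#' Score a 9-mer binding core against a quantitative matrix
#'
#' The predicted binding score is the sum of the QM coefficients of the core
#' residues at `p1..p9`, plus the `p0`/`p10` terms when the matrix covers the
#' flanks and flank residues are supplied (an absent flank contributes 0).
#'
#' @param qm A `"dqm"` quantitative matrix.
#' @param core9 A 9-residue string occupying `p1..p9`.
#' @param p0,p10 Optional single flank residues.
#' @return Dimensionless additive score.
#' @examples
#' \dontrun{score_core(qm, "QPFPQPELP")}
#' @export
score_core <- function(qm, core9, p0 = NULL, p10 = NULL) {
  stopifnot(inherits(qm, "dqm"))
  core9 <- check_sequence(core9, "core")
  if (nchar(core9) != 9L) stop("core must be exactly 9 residues", call. = FALSE)
  res <- strsplit(core9, "", fixed = TRUE)[[1L]]
  terms <- qm$contributions[cbind(CORE_LABELS, res)]
  if (qm$mode == "whole_peptide") {
    for (fl in list(list("p0", p0), list("p10", p10))) {
      if (!is.null(fl[[2L]])) {
        a <- check_sequence(fl[[2L]], fl[[1L]])
        if (nchar(a) != 1L) stop(fl[[1L]], " must be a single residue",
                                 call. = FALSE)
        terms <- c(terms, qm$contributions[fl[[1L]], a])
      }
    }
  }
  sum(terms)
}

#' Score a peptide over all binding-core registers
#'
#' A peptide of length `L >= 9` admits `L - 8` placements of the 9-residue
#' binding core. Each register is scored additively and the best (maximum)
#' score is reported, ties resolved in favour of the smallest register
#' offset. For a matrix covering the flanks, residues adjacent to the core
#' within the peptide are scored as `p0`/`p10`; at the termini the missing
#' flank contributes 0.
#'
#' @param qm A `"dqm"`.
#' @param peptide Peptide sequence, length >= 9.
#' @return List with `best_score`, `best_register` (0-based offset of `p1`),
#'   and `registers`, a data frame of all register scores.
#' @export
score_peptide <- function(qm, peptide) {
  stopifnot(inherits(qm, "dqm"))
  peptide <- check_sequence(peptide, "peptide")
  len <- nchar(peptide)
  if (len < 9L) stop("peptide shorter than the 9-residue binding core",
                     call. = FALSE)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  starts <- 0:(len - 9L)
  scores <- score_windows(qm, chars, starts)
  best <- which.max(scores)  # first maximum = smallest offset
  list(best_score = scores[best], best_register = starts[best],
       registers = data.frame(register_offset = starts, score = scores))
}

#' Predict binding scores for peptides under a quantitative matrix
#'
#' @param object A `"dqm"`.
#' @param newdata Character vector of peptide sequences (length >= 9 each),
#'   optionally named.
#' @param cutoff Score cutoff for the binder call (`score >= cutoff`,
#'   inclusive); default the QM's stored recommended cutoff, if any.
#' @param ... Unused.
#' @return Data frame with `peptide_id`, `sequence`, `score` (best over
#'   registers), `register_offset`, and — when a cutoff is available —
#'   `call` (`"binder"`/`"non-binder"`).
#' @export
predict.dqm <- function(object, newdata, cutoff = object$cutoff, ...) {
  newdata <- as.character(newdata)
  ids <- names(newdata)
  if (is.null(ids)) ids <- paste0("pep", seq_along(newdata))
  hits <- lapply(newdata, score_peptide, qm = object)
  out <- data.frame(
    peptide_id = ids,
    sequence = toupper(newdata),
    score = vapply(hits, `[[`, numeric(1), "best_score"),
    register_offset = vapply(hits, `[[`, numeric(1), "best_register"),
    stringsAsFactors = FALSE
  )
  if (!is.null(cutoff)) {
    out$call <- ifelse(out$score >= cutoff, "binder", "non-binder")
  }
  out
}

#' Screen a protein FASTA file for predicted binding cores
#'
#' Slides the 9-residue binding core along every protein and scores each
#' register additively under the QM — the proteome-scale use of the matrices.
#' Windows containing non-standard residues (X, B, Z, U, ...) at any scored
#' position are skipped and counted rather than imputed.
#'
#' @param qm A `"dqm"`.
#' @param fasta_path Path to a protein FASTA file.
#' @param cutoff Score cutoff; windows with `score >= cutoff` are called
#'   binders.
#' @return An object of class `"screening_report"`: list with `windows` (one
#'   row per scored register: `protein_id`, `register_offset` 0-based,
#'   `core_sequence`, `score`, `call`), `proteins` (per-protein summary with
#'   best score/register, window, skip and binder counts), and `cutoff`.
#' @export
screen_fasta <- function(qm, fasta_path, cutoff = 0.1) {
  stopifnot(inherits(qm, "dqm"), is.finite(cutoff))
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (!length(seqs)) stop("empty FASTA: nothing to screen", call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))

  win_list <- vector("list", length(seqs))
  prot_list <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(as.character(seqs[[i]]))
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    len <- length(chars)
    if (len < 9L) {
      prot_list[[i]] <- data.frame(protein_id = ids[i], length = len,
                                   n_windows = 0L, n_skipped = 0L,
                                   n_binders = 0L, best_score = NA_real_,
                                   best_register = NA_integer_)
      next
    }
    starts <- 0:(len - 9L)
    scores <- score_windows(qm, chars, starts)
    keep <- which(!is.na(scores))
    n_bind <- 0L
    if (length(keep)) {
      w <- data.frame(
        protein_id = ids[i],
        register_offset = starts[keep],
        core_sequence = substring(s, starts[keep] + 1L, starts[keep] + 9L),
        score = scores[keep],
        call = ifelse(scores[keep] >= cutoff, "binder", "non-binder"),
        stringsAsFactors = FALSE
      )
      win_list[[i]] <- w
      n_bind <- sum(w$call == "binder")
    }
    best <- if (length(keep)) which.max(scores) else NA_integer_
    prot_list[[i]] <- data.frame(
      protein_id = ids[i], length = len,
      n_windows = length(keep), n_skipped = length(starts) - length(keep),
      n_binders = n_bind,
      best_score = if (length(keep)) scores[best] else NA_real_,
      best_register = if (length(keep)) starts[best] else NA_integer_)
  }
  structure(list(windows = do.call(rbind, win_list),
                 proteins = do.call(rbind, prot_list),
                 cutoff = cutoff, allele = qm$allele),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening report (%s, cutoff %g): %d proteins, %d windows, %d binder calls\n",
              x$allele, x$cutoff, nrow(x$proteins),
              sum(x$proteins$n_windows), sum(x$proteins$n_binders)))
  print(utils::head(x$proteins, 10))
  invisible(x)
}

#' Write a screening report as TSV
#'
#' One row per scored window (`protein_id`, 0-based `register_offset`,
#' `core_sequence`, score to 6 decimals, call), preceded by `#` comment lines
#' with the cutoff and per-protein best scores.
#'
#' @param report A [screen_fasta()] result.
#' @param path Output TSV path.
#' @export
write_screening_report <- function(report, path) {
  stopifnot(inherits(report, "screening_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# allele: %s", report$allele), con)
  writeLines(sprintf("# cutoff: %g", report$cutoff), con)
  p <- report$proteins
  writeLines(sprintf("# best\t%s\t%s\t%s", p$protein_id,
                     ifelse(is.na(p$best_score), "NA",
                            sprintf("%.6f", p$best_score)),
                     p$best_register), con)
  w <- report$windows
  w$score <- sprintf("%.6f", w$score)
  utils::write.table(w, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-position non-preferred (and preferred) residue sets from a QM
#'
#' Residues whose contribution falls below (`nonpreferred_from_qm`) or above
#' (`preferred_from_qm`) the threshold at each binding-core position.
#' Non-preferred sets drive decoy construction; preferred sets describe the
#' binding motif the matrix encodes.
#'
#' @param qm A `"dqm"` covering `p1..p9`.
#' @param threshold Contribution threshold (default 0, the sign boundary).
#' @return Named list (`p1`...`p9`) of residue character vectors; sets may be
#'   empty.
#' @export
nonpreferred_from_qm <- function(qm, threshold = 0) {
  stopifnot(inherits(qm, "dqm"))
  lapply(stats::setNames(nm = CORE_LABELS), function(lab) {
    AA_ALPHABET[qm$contributions[lab, ] < threshold]
  })
}

#' @rdname nonpreferred_from_qm
#' @export
preferred_from_qm <- function(qm, threshold = 0) {
  stopifnot(inherits(qm, "dqm"))
  lapply(stats::setNames(nm = CORE_LABELS), function(lab) {
    AA_ALPHABET[qm$contributions[lab, ] > threshold]
  })
}

# Draw n peptides whose core residues come uniformly from per-position sets;
# flank residues (length > 9) are uniform over the full alphabet.
#' @keywords internal
#' @noRd
sample_core_peptides <- function(sets, n, length = 9L, seed) {
  stopifnot(identical(sort_labels(names(sets)), CORE_LABELS))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    stop("empty residue set at core position(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  length <- as.integer(length)
  if (length < 9L) stop("peptide length must be >= 9", call. = FALSE)
  n <- as.integer(n)
  left <- (length - 9L) %/% 2L
  right <- length - 9L - left
  with_seed(seed, {
    core <- vapply(CORE_LABELS, function(lab) {
      sets[[lab]][sample.int(base::length(sets[[lab]]), n, replace = TRUE)]
    }, character(n))
    if (n == 1L) core <- matrix(core, nrow = 1L)
    flank <- function(k) {
      if (k == 0L) return(rep("", n))
      m <- matrix(AA_ALPHABET[sample.int(20L, n * k, replace = TRUE)],
                  nrow = n)
      apply(m, 1L, paste, collapse = "")
    }
    paste0(flank(left), apply(core, 1L, paste, collapse = ""), flank(right))
  })
}

#' Generate non-binder decoy peptides
#'
#' Decoys are random combinations of non-preferred residues at all nine
#' binding-core positions — the standard construction of a negative class for
#' validating a binding matrix. Core residues are drawn uniformly from each
#' position's non-preferred set; for lengths above 9, flanking residues are
#' drawn uniformly from the full alphabet. With sets derived at threshold 0,
#' every decoy's core score under the source QM is a sum of strictly negative
#' terms, hence `< 0`.
#'
#' @param sets Per-position residue sets, usually [nonpreferred_from_qm()];
#'   every core position must be non-empty.
#' @param n Number of decoys.
#' @param length Peptide length (>= 9; default 9).
#' @param seed Integer seed; the draw is reproducible.
#' @return Character vector of `n` peptide sequences.
#' @export
generate_decoys <- function(sets, n, length = 9L, seed) {
  sample_core_peptides(sets, n, length, seed)
}
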