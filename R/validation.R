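# Sensitivity/specificity/accuracy of a QM on labelled binder/non-binder sets.

#' Assemble a labelled binder/non-binder peptide set
#'
#' @param binders,non_binders Character vectors of peptide sequences, each at
#'   least 9 residues.
#' @param provenance Free-text note on where the set came from.
#' @return A data frame of class `"labelled_set"` with columns `sequence` and
#'   `label` (`"binder"`/`"non_binder"`).
#' @export
labelled_set <- function(binders, non_binders, provenance = "") {
  seqs <- c(vapply(as.character(binders), check_sequence, character(1)),
            vapply(as.character(non_binders), check_sequence, character(1)))
  if (any(nchar(seqs) < 9L)) {
    stop("all peptides must be at least 9 residues", call. = FALSE)
  }
  structure(
    data.frame(sequence = unname(seqs),
               label = rep(c("binder", "non_binder"),
                           c(length(binders), length(non_binders))),
               stringsAsFactors = FALSE),
    provenance = provenance,
    class = c("labelled_set", "data.frame"))
}

#' Read a labelled set from CSV or from two plain peptide lists
#'
#' `read_labelled_set()` expects a CSV with columns `sequence,label` (labels
#' `binder`/`non_binder`); `read_peptide_lists()` builds the set from two
#' plain-text files, one sequence per line.
#'
#' @param path CSV path.
#' @return A [labelled_set()].
#' @export
read_labelled_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sequence", "label") %in% names(df))) {
    stop("labelled set CSV must have columns sequence,label", call. = FALSE)
  }
  bad <- setdiff(unique(df$label), c("binder", "non_binder"))
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  labelled_set(df$sequence[df$label == "binder"],
               df$sequence[df$label == "non_binder"],
               provenance = path)
}

#' @rdname read_labelled_set
#' @param binders_path,non_binders_path Plain-text peptide lists.
#' @export
read_peptide_lists <- function(binders_path, non_binders_path) {
  rd <- function(p) {
    x <- trimws(readLines(p))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  labelled_set(rd(binders_path), rd(non_binders_path),
               provenance = paste(binders_path, non_binders_path, sep = " + "))
}

# Confusion counts and percentage metrics at one cutoff, from precomputed
# best-register scores. Percentages at full precision; NA for a missing class.
#' @keywords internal
#' @noRd
metrics_at <- function(scores, is_binder, cutoff) {
  called <- scores >= cutoff
  TP <- sum(called & is_binder);  FN <- sum(!called & is_binder)
  FP <- sum(called & !is_binder); TN <- sum(!called & !is_binder)
  data.frame(
    cutoff = cutoff, TP = TP, FN = FN, TN = TN, FP = FP,
    sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
    accuracy = 100 * (TP + TN) / length(scores))
}

#' Evaluate a QM on a labelled set at one cutoff
#'
#' Each peptide is scored by its best binding-core register and called a
#' binder when `score >= cutoff` (inclusive). Sensitivity is the percentage
#' of binders called correctly, specificity the percentage of non-binders,
#' accuracy the percentage of all peptides; values are retained at full
#' precision and conventionally reported rounded to whole percent. If the set
#' lacks one class, that class's metric is `NA` (undefined), never 0.
#'
#' @param qm A `"dqm"`.
#' @param set A [labelled_set()].
#' @param cutoff Score cutoff.
#' @return One-row data frame: `cutoff`, `TP`, `FN`, `TN`, `FP`,
#'   `sensitivity`, `specificity`, `accuracy` (percent).
#' @export
evaluate_at_cutoff <- function(qm, set, cutoff) {
  stopifnot(inherits(qm, "dqm"), inherits(set, "labelled_set"))
  scores <- predict(qm, set$sequence, cutoff = NULL)$score
  metrics_at(scores, set$label == "binder", cutoff)
}

#' Scan cutoffs and select the operating point
#'
#' Computes the confusion matrix and percentage metrics at every cutoff of an
#' arithmetic grid — by default -0.5 to +0.5 in steps of 0.1, the standard
#' grid for QM validation — and selects the cutoff with the highest accuracy
#' (ties: lowest cutoff, then highest sensitivity). Grid values are computed
#' by integer multiples of the step to avoid floating-point drift, so the
#' default grid is exactly \{-0.5, -0.4, ..., +0.5\}.
#'
#' @param qm A `"dqm"`.
#' @param set A [labelled_set()] containing both classes.
#' @param lo,hi,step Grid bounds (inclusive) and positive step; `hi - lo`
#'   must be an integer multiple of `step`.
#' @return An object of class `"cutoff_scan"`: data frame with one row per
#'   cutoff (columns as in [evaluate_at_cutoff()]) plus attribute
#'   `selected_cutoff`.
#' @export
cutoff_scan <- function(qm, set, lo = -0.5, hi = 0.5, step = 0.1) {
  stopifnot(inherits(qm, "dqm"), inherits(set, "labelled_set"))
  if (!(lo < hi) || step <= 0) stop("need lo < hi and step > 0", call. = FALSE)
  k <- round((hi - lo) / step)
  if (abs(lo + k * step - hi) > 1e-9) {
    stop("hi - lo must be an integer multiple of step", call. = FALSE)
  }
  grid <- round(lo + step * (0:k), 10)
  if (!all(c("binder", "non_binder") %in% set$label)) {
    stop("cutoff scan needs both binders and non-binders", call. = FALSE)
  }
  scores <- predict(qm, set$sequence, cutoff = NULL)$score
  is_binder <- set$label == "binder"
  rows <- do.call(rbind, lapply(grid, metrics_at, scores = scores,
                                is_binder = is_binder))
  sel <- rows[order(-rows$accuracy, rows$cutoff, -rows$sensitivity), ][1L, ]
  structure(rows, selected_cutoff = sel$cutoff,
            class = c("cutoff_scan", "data.frame"))
}

#' @export
print.cutoff_scan <- function(x, ...) {
  df <- as.data.frame(x)
  for (col in c("sensitivity", "specificity", "accuracy")) {
    df[[col]] <- round(df[[col]])
  }
  cat("Cutoff scan (percentages rounded to whole percent):\n")
  print(df, row.names = FALSE)
  cat(sprintf("Selected cutoff (highest accuracy): %g\n",
              attr(x, "selected_cutoff")))
  invisible(x)
}

#' Write a cutoff-scan result as TSV
#'
#' Confusion counts plus sensitivity/specificity/accuracy per cutoff, with
#' the selected cutoff in a comment line. Percentages are written at full
#' precision.
#'
#' @param scan A [cutoff_scan()] result.
#' @param path Output TSV path.
#' @export
write_cutoff_scan <- function(scan, path) {
  stopifnot(inherits(scan, "cutoff_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# selected_cutoff: %g", attr(scan, "selected_cutoff")),
             con)
  utils::write.table(as.data.frame(scan), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
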