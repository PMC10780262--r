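# Internal constants and helpers shared across the package.

# The 20 standard amino acids, alphabetical one-letter order. This ordering is
# the column order of every matrix and CSV the package writes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Symbolic peptide positions, groove order. p1..p9 are the binding core;
# p0/p10 (and p-1/p11 where the peptide is long enough) are flanks.
ALL_LABELS  <- c("p-1", paste0("p", 0:11))
CORE_LABELS <- paste0("p", 1:9)

#' @keywords internal
#' @noRd
label_number <- function(label) {
  m <- regmatches(label, regexec("^p(-?[0-9]+)$", label))
  n <- vapply(m, function(x) if (length(x) == 2L) as.integer(x[2L]) else NA_integer_,
              integer(1))
  bad <- is.na(n) | n < -1L | n > 11L
  if (any(bad)) {
    stop("unknown position label(s): ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  }
  n
}

# Order labels p-1 < p0 < ... < p11
#' @keywords internal
#' @noRd
sort_labels <- function(labels) labels[order(label_number(labels))]

#' @keywords internal
#' @noRd
check_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop(what, " contains non-standard residue(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  seq
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never clobbers user RNG.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
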