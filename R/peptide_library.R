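#' Define a parent peptide with its binding-core register
#'
#' A parent peptide anchors a single-amino-acid-substitution (SAAS)
#' combinatorial library. MHC class II peptides are described by symbolic
#' positions: the nine binding-core residues `p1`...`p9` sit in the groove,
#' and `p0`/`p10` (plus `p-1`/`p11` for longer peptides) flank its open ends.
#' `core_start` ties the symbolic register to the sequence: it is the 0-based
#' offset of `p1`, so the register notation of the structural literature maps
#' directly onto the string.
#'
#' @param sequence Amino-acid sequence (standard 20-letter alphabet; forced to
#'   upper case). Length must be between 9 and 13 so all residues fall within
#'   `p-1`...`p11`.
#' @param core_start 0-based offset of position `p1` in `sequence`. For the
#'   alpha-gliadin 11-mer `QPFPQPELPYP` bound to HLA-DQ2.5 this is 1 (`p0` is
#'   the leading Q); for the 13-mer `SGEGSFQPSQENP` bound to HLA-DQ8.1 it is 2
#'   (`p-1` is the leading S).
#' @param id Identifier used as the prefix of library peptide ids.
#' @param fixed Character vector of position labels excluded from substitution
#'   (e.g. `c("p-1", "p11")` for the HLA-DQ8.1 parent, whose terminal residues
#'   are kept unchanged).
#'
#' @return An object of class `"parent_peptide"`: a list with elements `id`,
#'   `sequence`, `core_start`, `labels` (data frame mapping each position
#'   label to its 0-based offset) and `mutable_labels`.
#' @examples
#' parent_peptide("QPFPQPELPYP", core_start = 1, id = "aglia")
#' parent_peptide("SGEGSFQPSQENP", core_start = 2, id = "dq8",
#'                fixed = c("p-1", "p11"))
#' @export
parent_peptide <- function(sequence, core_start, id = "parent",
                           fixed = character()) {
  sequence <- check_sequence(sequence, "parent sequence")
  len <- nchar(sequence)
  if (len < 9L) stop("parent sequence must be at least 9 residues", call. = FALSE)
  if (!is.numeric(core_start) || length(core_start) != 1L ||
      core_start != as.integer(core_start)) {
    stop("core_start must be a single integer (0-based offset of p1)",
         call. = FALSE)
  }
  core_start <- as.integer(core_start)
  if (core_start < 0L || core_start + 9L > len) {
    stop(sprintf("core_start %d out of range: p1..p9 must fit in a %d-residue sequence",
                 core_start, len), call. = FALSE)
  }
  nums <- (0:(len - 1L)) - core_start + 1L   # p-number of each offset
  if (any(nums < -1L) || any(nums > 11L)) {
    stop("register places residues outside p-1..p11; check core_start and length",
         call. = FALSE)
  }
  labels <- paste0("p", nums)
  fixed <- unique(as.character(fixed))
  unknown <- setdiff(fixed, labels)
  if (length(unknown)) {
    stop("fixed label(s) not present in this peptide: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  obj <- list(
    id = as.character(id),
    sequence = sequence,
    core_start = core_start,
    labels = data.frame(label = labels, offset = 0:(len - 1L),
                        stringsAsFactors = FALSE),
    mutable_labels = setdiff(labels, fixed)
  )
  class(obj) <- "parent_peptide"
  obj
}

#' @export
print.parent_peptide <- function(x, ...) {
  cat("Parent peptide", sQuote(x$id), "\n")
  cat("  ", x$sequence, "\n", sep = "")
  cat("  register: ", x$labels$label[1L], "..",
      x$labels$label[nrow(x$labels)],
      "  (p1 at 0-based offset ", x$core_start, ")\n", sep = "")
  fixed <- setdiff(x$labels$label, x$mutable_labels)
  if (length(fixed)) cat("  fixed:", paste(fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Map a sequence offset to its position label (and back)
#'
#' @param parent A [parent_peptide()].
#' @param offset 0-based offset into the parent sequence.
#' @return `label_for_offset()` returns the position label at `offset`;
#'   `offset_for_label()` returns the 0-based offset carrying `label`.
#' @examples
#' p <- parent_peptide("QPFPQPELPYP", core_start = 1)
#' label_for_offset(p, 0)  # "p0"
#' offset_for_label(p, "p9")
#' @export
label_for_offset <- function(parent, offset) {
  stopifnot(inherits(parent, "parent_peptide"))
  if (!is.numeric(offset) || length(offset) != 1L || is.na(offset) ||
      offset != as.integer(offset)) {
    stop("offset must be a single integer", call. = FALSE)
  }
  i <- match(as.integer(offset), parent$labels$offset)
  if (is.na(i)) {
    stop(sprintf("offset %d out of range 0..%d", as.integer(offset),
                 nchar(parent$sequence) - 1L), call. = FALSE)
  }
  parent$labels$label[i]
}

#' @rdname label_for_offset
#' @param label A position label such as `"p4"`.
#' @export
offset_for_label <- function(parent, label) {
  stopifnot(inherits(parent, "parent_peptide"))
  i <- match(label, parent$labels$label)
  if (anyNA(i)) {
    stop("label(s) not present in this peptide: ",
         paste(label[is.na(i)], collapse = ", "), call. = FALSE)
  }
  parent$labels$offset[i]
}

#' Build a SAAS combinatorial peptide library
#'
#' Applies the rule "one peptide, one substitution": every mutable position of
#' the parent is substituted in turn by each of the 19 alternative amino acids,
#' giving `19 * m + 1` peptides for `m` mutable positions (210 for an 11-mer
#' with all eleven positions open, the standard library size for HLA-DQ work).
#' Variant order is deterministic: by position label, then alphabetical
#' residue; ids are `"<parent id>_<label><aa>"` and the parent is
#' `"<parent id>_wt"`.
#'
#' @param parent A [parent_peptide()].
#' @return An object of class `"saas_library"`: a list with the `parent` and a
#'   data frame `variants` with columns `peptide_id`, `sequence`,
#'   `substituted_label`, `substituted_aa` (the parent row carries `"wt"` in
#'   both substitution columns).
#' @examples
#' lib <- build_saas_library(parent_peptide("QPFPQPELPYP", core_start = 1))
#' nrow(lib$variants)  # 210
#' @export
build_saas_library <- function(parent) {
  stopifnot(inherits(parent, "parent_peptide"))
  labels <- sort_labels(parent$mutable_labels)
  if (!length(labels)) stop("parent has no mutable positions", call. = FALSE)
  chars <- strsplit(parent$sequence, "", fixed = TRUE)[[1L]]
  rows <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    off <- offset_for_label(parent, lab)
    wt <- chars[off + 1L]
    alt <- setdiff(AA_ALPHABET, wt)
    seqs <- vapply(alt, function(a) {
      v <- chars; v[off + 1L] <- a; paste(v, collapse = "")
    }, character(1))
    rows[[k]] <- data.frame(
      peptide_id = paste0(parent$id, "_", lab, alt),
      sequence = unname(seqs),
      substituted_label = lab,
      substituted_aa = alt,
      stringsAsFactors = FALSE
    )
  }
  variants <- rbind(
    data.frame(peptide_id = paste0(parent$id, "_wt"),
               sequence = parent$sequence,
               substituted_label = "wt", substituted_aa = "wt",
               stringsAsFactors = FALSE),
    do.call(rbind, rows)
  )
  rownames(variants) <- NULL
  stopifnot(!anyDuplicated(variants$sequence))
  structure(list(parent = parent, variants = variants),
            class = "saas_library")
}

#' @export
print.saas_library <- function(x, ...) {
  cat("SAAS combinatorial library from parent", sQuote(x$parent$id), "\n")
  cat("  ", nrow(x$variants), " peptides (",
      length(x$parent$mutable_labels), " mutable positions x 19 + parent)\n",
      sep = "")
  invisible(x)
}

#' Write / read a SAAS library as FASTA plus manifest
#'
#' The FASTA file holds the peptide sequences keyed by `peptide_id`; the CSV
#' manifest records which position and residue each variant substitutes, plus
#' the parent's register in comment lines, so the library round-trips exactly.
#'
#' @param lib A [build_saas_library()] result.
#' @param fasta_path,manifest_path File paths.
#' @return `read_library()` returns the reconstructed `"saas_library"`;
#'   `write_library()` returns its paths invisibly.
#' @export
write_library <- function(lib, fasta_path, manifest_path) {
  stopifnot(inherits(lib, "saas_library"))
  seqs <- Biostrings::AAStringSet(stats::setNames(lib$variants$sequence,
                                                  lib$variants$peptide_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  con <- file(manifest_path, "w")
  on.exit(close(con))
  fixed <- setdiff(lib$parent$labels$label, lib$parent$mutable_labels)
  writeLines(c(
    sprintf("# parent_id: %s", lib$parent$id),
    sprintf("# parent_sequence: %s", lib$parent$sequence),
    sprintf("# core_start: %d", lib$parent$core_start),
    sprintf("# fixed: %s", paste(fixed, collapse = " "))
  ), con)
  utils::write.csv(lib$variants[, c("peptide_id", "substituted_label",
                                    "substituted_aa")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(c(fasta = fasta_path, manifest = manifest_path))
}

#' @rdname write_library
#' @export
read_library <- function(fasta_path, manifest_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  header <- grep("^#", readLines(manifest_path), value = TRUE)
  field <- function(key) {
    ln <- grep(sprintf("^# %s:", key), header, value = TRUE)
    if (!length(ln)) stop("manifest missing header field ", sQuote(key),
                          call. = FALSE)
    sub(sprintf("^# %s:\\s*", key), "", ln[1L])
  }
  fixed <- field("fixed")
  fixed <- if (nzchar(fixed)) strsplit(fixed, "\\s+")[[1L]] else character()
  parent <- parent_peptide(field("parent_sequence"),
                           core_start = as.integer(field("core_start")),
                           id = field("parent_id"), fixed = fixed)
  manifest <- utils::read.csv(manifest_path, comment.char = "#",
                              stringsAsFactors = FALSE)
  missing_ids <- setdiff(manifest$peptide_id, names(seqs))
  if (length(missing_ids)) {
    stop("manifest ids absent from FASTA: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  if (!nrow(manifest)) stop("manifest has no peptides (parent row required)",
                            call. = FALSE)
  variants <- data.frame(
    peptide_id = manifest$peptide_id,
    sequence = unname(as.character(seqs[manifest$peptide_id])),
    substituted_label = manifest$substituted_label,
    substituted_aa = manifest$substituted_aa,
    stringsAsFactors = FALSE
  )
  if (!any(variants$substituted_label == "wt")) {
    stop("library must contain the parent ('wt') row", call. = FALSE)
  }
  structure(list(parent = parent, variants = variants),
            class = "saas_library")
}
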