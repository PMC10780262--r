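#' Docking run configuration
#'
#' Records the provenance of a set of docking affinities: search effort
#' (exhaustiveness), the energy window within which alternative poses are
#' retained, whether peptide and binding-site residues were flexible, and the
#' radius used to define the site around the bound peptide. Defaults mirror a
#' standard flexible-docking protocol for peptide-MHC work (exhaustiveness 8,
#' energy range 3 kcal/mol, 6 A site).
#'
#' @param exhaustiveness Positive integer search-effort parameter.
#' @param energy_range_kcal Energy window in kcal/mol (> 0); poses scoring more
#'   than this above the best pose are discarded.
#' @param flexible_peptide,flexible_site Logical flags.
#' @param site_radius_A Binding-site definition radius in Angstroms.
#' @param engine_tag Free-text tag naming the score source (e.g. `"vina"`,
#'   `"synthetic"`).
#' @return An object of class `"docking_config"`.
#' @export
docking_config <- function(exhaustiveness = 8L, energy_range_kcal = 3,
                           flexible_peptide = TRUE, flexible_site = TRUE,
                           site_radius_A = 6, engine_tag = "vina") {
  if (!is.numeric(exhaustiveness) || exhaustiveness < 1) {
    stop("exhaustiveness must be >= 1", call. = FALSE)
  }
  if (!is.numeric(energy_range_kcal) || energy_range_kcal <= 0) {
    stop("energy_range_kcal must be > 0", call. = FALSE)
  }
  structure(list(
    exhaustiveness = as.integer(exhaustiveness),
    energy_range_kcal = as.numeric(energy_range_kcal),
    flexible_peptide = isTRUE(flexible_peptide),
    flexible_site = isTRUE(flexible_site),
    site_radius_A = as.numeric(site_radius_A),
    engine_tag = as.character(engine_tag)
  ), class = "docking_config")
}

#' @export
print.docking_config <- function(x, ...) {
  cat(sprintf(
    "Docking config [%s]: exhaustiveness %d, energy range %g kcal/mol,\n  flexible peptide %s, flexible site %s, site radius %g A\n",
    x$engine_tag, x$exhaustiveness, x$energy_range_kcal,
    x$flexible_peptide, x$flexible_site, x$site_radius_A))
  invisible(x)
}

#' Parse docking output text into a pose table
#'
#' Accepts either the tabular result block printed to the docking log (columns
#' mode, affinity, rmsd l.b., rmsd u.b.) or `REMARK VINA RESULT:` lines from
#' output PDBQT files, surrounded by arbitrary log noise. Unicode minus signs
#' pasted from PDFs or terminals are normalized before numeric parsing; rmsd
#' columns are ignored.
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines.
#' @return A data frame with columns `rank` and `affinity_kcal` (kcal/mol,
#'   more negative = stronger), in printed order.
#' @examples
#' parse_docking_output(c("   1   -7.5   0.000   0.000",
#'                        "   2   -6.9   1.202   2.334"))
#' @export
parse_docking_output <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  # U+2212 minus, U+2013 en dash -> ASCII hyphen-minus
  text <- gsub("−|–", "-", text)
  num <- "[-+]?[0-9]+(\\.[0-9]+)?"

  remark <- regmatches(text, regexec(
    sprintf("REMARK VINA RESULT:\\s+(%s)", num), text))
  remark_aff <- vapply(remark,
                       function(m) if (length(m)) as.numeric(m[2L]) else NA_real_,
                       numeric(1))
  if (any(!is.na(remark_aff))) {
    aff <- remark_aff[!is.na(remark_aff)]
    return(data.frame(rank = seq_along(aff), affinity_kcal = aff))
  }

  tab <- regmatches(text, regexec(
    sprintf("^\\s*([0-9]+)\\s+(%s)\\s+(%s)\\s+(%s)\\s*$", num, num, num), text))
  hits <- lengths(tab) > 0L
  if (!any(hits)) stop("no poses found in docking output", call. = FALSE)
  rows <- tab[hits]
  data.frame(
    rank = vapply(rows, function(m) as.integer(m[2L]), integer(1)),
    affinity_kcal = vapply(rows, function(m) as.numeric(m[3L]), numeric(1))
  )
}

#' Best affinity after energy-range pose filtering
#'
#' Poses scoring more than `energy_range_kcal` above the best (most negative)
#' pose are discarded; the best affinity of the retained set is returned. The
#' filter can never remove the top pose, so the value equals the overall
#' minimum for any positive range — it is kept for fidelity to the docking
#' protocol and for provenance (the number of retained poses is attached as
#' attribute `n_retained`).
#'
#' @param poses A data frame as returned by [parse_docking_output()], or a
#'   numeric vector of affinities.
#' @param energy_range_kcal Positive energy window in kcal/mol.
#' @return Best affinity in kcal/mol, with attribute `n_retained`.
#' @examples
#' best_score(c(-7.5, -6.9, -4.0), energy_range_kcal = 3)  # -7.5, 2 retained
#' @export
best_score <- function(poses, energy_range_kcal = 3) {
  aff <- if (is.data.frame(poses)) poses$affinity_kcal else as.numeric(poses)
  if (!length(aff)) stop("empty pose list", call. = FALSE)
  if (anyNA(aff) || any(!is.finite(aff))) {
    stop("non-finite affinity in pose list", call. = FALSE)
  }
  if (!is.numeric(energy_range_kcal) || energy_range_kcal <= 0) {
    stop("energy_range_kcal must be > 0", call. = FALSE)
  }
  keep <- aff <= min(aff) + energy_range_kcal
  structure(min(aff[keep]), n_retained = sum(keep))
}

#' Assemble a score table of best affinities per peptide
#'
#' @param peptide_id Character vector of unique peptide ids.
#' @param affinity_kcal Numeric vector of best affinities (kcal/mol).
#' @param config A [docking_config()] describing how the scores were produced.
#' @return An object of class `"score_table"`: a data frame with columns
#'   `peptide_id` and `affinity_kcal` and a `config` attribute.
#' @export
score_table <- function(peptide_id, affinity_kcal, config = docking_config()) {
  peptide_id <- as.character(peptide_id)
  affinity_kcal <- as.numeric(affinity_kcal)
  if (length(peptide_id) != length(affinity_kcal)) {
    stop("peptide_id and affinity_kcal lengths differ", call. = FALSE)
  }
  dup <- unique(peptide_id[duplicated(peptide_id)])
  if (length(dup)) {
    stop("duplicate peptide_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyNA(affinity_kcal) || any(!is.finite(affinity_kcal))) {
    stop("affinities must be finite", call. = FALSE)
  }
  stopifnot(inherits(config, "docking_config"))
  structure(
    data.frame(peptide_id = peptide_id, affinity_kcal = affinity_kcal,
               stringsAsFactors = FALSE),
    config = config, class = c("score_table", "data.frame"))
}

#' Read / write a score table as CSV
#'
#' The CSV body has header `peptide_id,affinity_kcal`; the docking
#' configuration travels in `# key: value` comment lines above it, so one file
#' round-trips the table together with its provenance.
#'
#' @param table A [score_table()].
#' @param path CSV file path.
#' @return `read_score_table()` returns a `"score_table"`;
#'   `write_score_table()` returns `path` invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  cfg <- attr(table, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(unclass(cfg)),
                     vapply(unclass(cfg), as.character, character(1))), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  kv <- regmatches(header, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", header))
  meta <- stats::setNames(
    vapply(kv, function(m) m[3L], character(1)),
    vapply(kv, function(m) m[2L], character(1)))
  cfg <- docking_config(
    exhaustiveness = as.integer(meta[["exhaustiveness"]]),
    energy_range_kcal = as.numeric(meta[["energy_range_kcal"]]),
    flexible_peptide = as.logical(meta[["flexible_peptide"]]),
    flexible_site = as.logical(meta[["flexible_site"]]),
    site_radius_A = as.numeric(meta[["site_radius_A"]]),
    engine_tag = meta[["engine_tag"]])
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE,
                        colClasses = c(peptide_id = "character"))
  if (!all(c("peptide_id", "affinity_kcal") %in% names(df))) {
    stop("score table must have columns peptide_id, affinity_kcal",
         call. = FALSE)
  }
  suppressWarnings(aff <- as.numeric(df$affinity_kcal))
  bad <- which(is.na(aff) | !is.finite(aff))
  if (length(bad)) {
    stop("non-numeric affinity at data row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  score_table(df$peptide_id, aff, config = cfg)
}
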