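#' Sample a planted additive docking-energy model
#'
#' The synthetic simulator stands in for a docking engine: each covered
#' position carries an energy increment `delta(label, residue)` in kcal/mol
#' (negative = stabilizing) and a peptide's affinity is the base affinity plus
#' the sum of increments over covered positions, plus Gaussian noise. Planting
#' a model, simulating a library, and rebuilding the quantitative matrix lets
#' the whole pipeline be validated against known ground truth.
#'
#' Increments are drawn i.i.d. uniform on `[-delta_spread_kcal,
#' +delta_spread_kcal]`. When a `reference` peptide is supplied, the increment
#' of its residue at each covered position is set to 0, i.e. the deltas are
#' substitution energies relative to the reference composition (the usual
#' convention of mutational scans) and `base_affinity_kcal` is then exactly
#' the reference peptide's noise-free affinity.
#'
#' @param labels Position labels the model covers (e.g. `paste0("p", 1:9)`).
#' @param seed Integer seed; the draw is reproducible and does not disturb the
#'   caller's RNG stream.
#' @param delta_spread_kcal Half-width of the uniform increment distribution
#'   (kcal/mol, > 0). Default 1.0, a typical per-residue docking-score scale.
#' @param base_affinity_kcal Affinity of the reference composition (kcal/mol).
#'   Default -7.0, a typical peptide-MHC docking affinity.
#' @param noise_sd_kcal Standard deviation of the Gaussian score noise
#'   (kcal/mol, >= 0).
#' @param reference Optional reference peptide: either a [parent_peptide()] or
#'   `NULL` for fully i.i.d. deltas.
#' @return An object of class `"ground_truth"`: list with `base_affinity_kcal`,
#'   `delta` (matrix labels x 20 residues), `noise_sd_kcal`, `seed`.
#' @export
sample_ground_truth <- function(labels, seed, delta_spread_kcal = 1,
                                base_affinity_kcal = -7,
                                noise_sd_kcal = 0, reference = NULL) {
  if (!length(labels)) stop("empty label set", call. = FALSE)
  labels <- sort_labels(unique(as.character(labels)))
  if (!is.numeric(delta_spread_kcal) || delta_spread_kcal <= 0) {
    stop("delta_spread_kcal must be > 0", call. = FALSE)
  }
  if (!is.numeric(noise_sd_kcal) || noise_sd_kcal < 0) {
    stop("noise_sd_kcal must be >= 0", call. = FALSE)
  }
  delta <- with_seed(seed, matrix(
    stats::runif(length(labels) * 20L, -delta_spread_kcal, delta_spread_kcal),
    nrow = length(labels), dimnames = list(labels, AA_ALPHABET)))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "parent_peptide"))
    chars <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
    for (lab in intersect(labels, reference$labels$label)) {
      delta[lab, chars[offset_for_label(reference, lab) + 1L]] <- 0
    }
  }
  structure(list(base_affinity_kcal = as.numeric(base_affinity_kcal),
                 delta = delta,
                 noise_sd_kcal = as.numeric(noise_sd_kcal),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Planted additive docking model\n")
  cat(sprintf("  base %g kcal/mol, noise sd %g kcal/mol, seed %d\n",
              x$base_affinity_kcal, x$noise_sd_kcal, x$seed))
  cat("  positions:", paste(rownames(x$delta), collapse = " "), "\n")
  invisible(x)
}

# Noise-free additive affinity of one peptide under the model.
#' @keywords internal
#' @noRd
additive_affinity <- function(model, sequence, parent) {
  chars <- strsplit(check_sequence(sequence), "", fixed = TRUE)[[1L]]
  labs <- intersect(rownames(model$delta), parent$labels$label)
  offs <- offset_for_label(parent, labs)
  model$base_affinity_kcal +
    sum(model$delta[cbind(labs, chars[offs + 1L])])
}

#' Simulate a docking affinity for one peptide
#'
#' Affinity = base + sum over covered positions of `delta(label, residue)` +
#' Gaussian noise (sd `noise_sd_kcal`, drawn from the model's seeded stream).
#' Positions the model does not cover contribute nothing, mirroring
#' binding-core-only scoring. With `noise_sd_kcal = 0` the value is exact.
#'
#' @param model A [sample_ground_truth()] model.
#' @param sequence Peptide sequence.
#' @param parent A [parent_peptide()] providing the label-to-offset register
#'   for `sequence` (which must have the parent's length).
#' @return Affinity in kcal/mol.
#' @export
simulate_score <- function(model, sequence, parent) {
  stopifnot(inherits(model, "ground_truth"),
            inherits(parent, "parent_peptide"))
  if (nchar(sequence) != nchar(parent$sequence)) {
    stop("sequence length differs from the register-defining parent",
         call. = FALSE)
  }
  missing <- setdiff(rownames(model$delta), parent$labels$label)
  if (length(missing)) {
    stop("register does not cover model position(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eps <- if (model$noise_sd_kcal > 0) {
    with_seed(model$seed + 1L, stats::rnorm(1, 0, model$noise_sd_kcal))
  } else 0
  additive_affinity(model, sequence, parent) + eps
}

#' Simulate best docking affinities for a whole SAAS library
#'
#' One affinity per library member, in library order, from a single seeded
#' noise stream (`model$seed + 1`), so the resulting table is byte-identical
#' across runs with the same model.
#'
#' @param model A [sample_ground_truth()] model.
#' @param lib A [build_saas_library()] library.
#' @return A [score_table()] with `engine_tag = "synthetic"`.
#' @export
simulate_library_scores <- function(model, lib) {
  stopifnot(inherits(model, "ground_truth"), inherits(lib, "saas_library"))
  missing <- setdiff(rownames(model$delta), lib$parent$labels$label)
  if (length(missing)) {
    stop("library register does not cover model position(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  exact <- vapply(lib$variants$sequence, additive_affinity,
                  numeric(1), model = model, parent = lib$parent)
  eps <- if (model$noise_sd_kcal > 0) {
    with_seed(model$seed + 1L,
              stats::rnorm(length(exact), 0, model$noise_sd_kcal))
  } else 0
  score_table(lib$variants$peptide_id, unname(exact) + eps,
              config = docking_config(engine_tag = "synthetic"))
}
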