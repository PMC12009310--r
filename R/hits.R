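# Machine-readable rule codes attached to every non-hit / exclusion.
RULE_CODES <- c(
  below_cutoff = "z_cilia_below_cutoff",
  cytotoxic_plates = "cytotoxic_on_more_than_2_of_4_plates",
  delta_below = "delta_z_cilia_below_threshold",
  cytotoxic_zcell = "cytotoxic_z_cell_le_minus2",
  not_both_reps = "not_significant_in_both_replicates",
  cell_change = "cell_number_change",
  not_all_transcripts = "sirna_not_all_transcripts",
  no_orthologue = "no_human_orthologue",
  below_mean = "mean_z_cilia_below_2",
  not_evaluable = "missing_z_in_required_replicate"
)

hit_frame <- function(condition, tier, status, mean_z_cell, mean_z_cilia,
                      reasons) {
  data.frame(condition = condition, tier = tier, status = status,
             mean_z_cell = mean_z_cell, mean_z_cilia = mean_z_cilia,
             reasons = vapply(reasons, paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Primary drug-screen hit calling with batch cutoffs
#'
#' A test condition is a hit if its mean `z_cilia` (over all plates and
#' runs) reaches the batch's cilia cutoff. Independently, it is excluded
#' as cytotoxic if `z_cell` falls at or below the batch's cell cutoff on
#' more than 2 of the batch's 4 plates; the count is evaluated per run and
#' exclusion in either run excludes the condition. Exclusion overrides the
#' hit call.
#'
#' @param z Z-score table from [screen_zscores()] (all replicates).
#' @param cutoffs Cutoff table from [batch_cutoffs()].
#' @return Hit table with columns `condition`, `tier`, `status`
#'   (`"hit"`, `"excluded_cytotoxic"`, `"not_hit"` or `"not_evaluable"`),
#'   `mean_z_cell`, `mean_z_cilia`, `reasons` (semicolon-joined codes).
#' @export
call_primary_drug_hits <- function(z, cutoffs) {
  tests <- z[z$role == "test", , drop = FALSE]
  parts <- split(tests, tests$condition)
  out <- lapply(parts, function(g) {
    cond <- g$condition[1]
    if (length(unique(g$batch)) > 1)
      stop("condition ", cond, " spans multiple batches", call. = FALSE)
    cut <- cutoffs[cutoffs$batch == g$batch[1], , drop = FALSE]
    if (nrow(cut) != 1)
      stop("no cutoff for batch ", g$batch[1], call. = FALSE)
    if (anyNA(g$z_cilia) || anyNA(g$z_cell))
      return(hit_frame(cond, "primary_drug", "not_evaluable", NA, NA,
                       RULE_CODES["not_evaluable"]))
    mz_cilia <- mean(g$z_cilia)
    mz_cell <- mean(g$z_cell)
    # per-run count of plates at or below the cell cutoff
    per_run <- vapply(split(g, g$replicate), function(r) {
      plate_z <- tapply(r$z_cell, r$plate, mean)
      sum(plate_z <= cut$z_cell_cutoff)
    }, 0)
    reasons <- character(0)
    if (any(per_run > 2)) reasons <- RULE_CODES["cytotoxic_plates"]
    status <- if (length(reasons)) "excluded_cytotoxic"
              else if (mz_cilia >= cut$z_cilia_cutoff) "hit"
              else {
                reasons <- RULE_CODES["below_cutoff"]
                "not_hit"
              }
    hit_frame(cond, "primary_drug", status, mz_cell, mz_cilia,
              list(reasons))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Secondary / tertiary confirmation hit calling
#'
#' Confirmation tiers score each condition's mean `z_cilia` difference
#' from its matched relevant control (the same-knockdown vehicle-treated
#' condition). A condition is a hit if the difference reaches `threshold`
#' (2 for the secondary tier, 1.5 for the tertiary tier) and its mean
#' `z_cell > -2`; conditions with `z_cell <= -2` are excluded as
#' cytotoxic.
#'
#' @param z Z-score table; if it has a `knockdown` column, conditions are
#'   matched to `control_reference` by knockdown label.
#' @param control_reference Either a single reference `z_cilia` value or a
#'   data frame with columns `knockdown` and `z_cilia`.
#' @param threshold Minimum difference from the control, in z units.
#' @param tier Tier label recorded in the output.
#' @return Hit table (see [call_primary_drug_hits()] for columns).
#' @export
call_confirmation_hits <- function(z, control_reference, threshold = 2,
                                   tier = "secondary_drug") {
  tests <- if ("role" %in% names(z)) z[z$role == "test", , drop = FALSE] else z
  parts <- split(tests, tests$condition)
  out <- lapply(parts, function(g) {
    cond <- g$condition[1]
    if (is.data.frame(control_reference)) {
      if (!"knockdown" %in% names(g))
        stop("z table needs a knockdown column to match controls",
             call. = FALSE)
      ref <- control_reference$z_cilia[
        control_reference$knockdown == g$knockdown[1]]
      if (length(ref) != 1)
        stop("no matched control for condition ", cond, call. = FALSE)
    } else ref <- control_reference
    if (anyNA(g$z_cilia) || anyNA(g$z_cell))
      return(hit_frame(cond, tier, "not_evaluable", NA, NA,
                       RULE_CODES["not_evaluable"]))
    mz_cilia <- mean(g$z_cilia)
    mz_cell <- mean(g$z_cell)
    delta <- mz_cilia - ref
    if (mz_cell <= -2)
      return(hit_frame(cond, tier, "excluded_cytotoxic", mz_cell, mz_cilia,
                       RULE_CODES["cytotoxic_zcell"]))
    if (delta >= threshold)
      hit_frame(cond, tier, "hit", mz_cell, mz_cilia, list(character(0)))
    else
      hit_frame(cond, tier, "not_hit", mz_cell, mz_cilia,
                RULE_CODES["delta_below"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-screen re-analysis filter chain
#'
#' A condition is a candidate iff, in every experimental replicate,
#' `z_cilia >= +2` and `-2 <= z_cell <= +2`, and its siRNA pool targets
#' all annotated transcripts and the gene has a human orthologue. Every
#' failed criterion is recorded; the candidate set is the conjunction of
#' the four filters and hence independent of filter order.
#'
#' @param z Z-score table with one record per (condition, replicate).
#' @param flags Annotation flags as [simulate_annotation_flags()]. Flags
#'   must be present for any condition surviving the z filters; missing
#'   flags are an error, never defaulted.
#' @return Hit table with tier `"genome_primary"`.
#' @export
genome_refilter <- function(z, flags) {
  tests <- if ("role" %in% names(z)) z[z$role == "test", , drop = FALSE] else z
  parts <- split(tests, tests$condition)
  out <- lapply(parts, function(g) {
    cond <- g$condition[1]
    if (anyNA(g$z_cilia) || anyNA(g$z_cell))
      return(hit_frame(cond, "genome_primary", "not_evaluable", NA, NA,
                       RULE_CODES["not_evaluable"]))
    reasons <- character(0)
    if (!all(g$z_cilia >= 2)) reasons <- c(reasons, RULE_CODES["not_both_reps"])
    if (!all(g$z_cell >= -2 & g$z_cell <= 2))
      reasons <- c(reasons, RULE_CODES["cell_change"])
    if (length(reasons) == 0 || cond %in% flags$condition) {
      fl <- flags[flags$condition == cond, , drop = FALSE]
      if (nrow(fl) == 0)
        stop("missing annotation flags for surviving condition ", cond,
             call. = FALSE)
      if (!fl$targets_all_transcripts)
        reasons <- c(reasons, RULE_CODES["not_all_transcripts"])
      if (!fl$has_human_orthologue)
        reasons <- c(reasons, RULE_CODES["no_orthologue"])
    }
    status <- if (length(reasons) == 0) "hit" else "not_hit"
    hit_frame(cond, "genome_primary", status, mean(g$z_cell),
              mean(g$z_cilia), list(reasons))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average-z hit calling (secondary siRNA screen rule)
#'
#' Averages robust z-scores across replicates; a condition is a hit iff
#' its mean `z_cilia >= 2` (boundary inclusive).
#'
#' @param z Z-score table with one or more records per condition.
#' @return Hit table with tier `"genome_secondary"`.
#' @export
average_z_hits <- function(z) {
  tests <- if ("role" %in% names(z)) z[z$role == "test", , drop = FALSE] else z
  parts <- split(tests, tests$condition)
  out <- lapply(parts, function(g) {
    cond <- g$condition[1]
    if (anyNA(g$z_cilia) || anyNA(g$z_cell))
      return(hit_frame(cond, "genome_secondary", "not_evaluable", NA, NA,
                       RULE_CODES["not_evaluable"]))
    mz <- mean(g$z_cilia)
    if (mz >= 2)
      hit_frame(cond, "genome_secondary", "hit", mean(g$z_cell), mz,
                list(character(0)))
    else
      hit_frame(cond, "genome_secondary", "not_hit", mean(g$z_cell), mz,
                RULE_CODES["below_mean"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
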