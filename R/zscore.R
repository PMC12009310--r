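#' Cilia incidence of a well
#'
#' Percentage of cells in a well bearing a single cilium.
#'
#' @param ciliated_count,cell_count Non-negative integer vectors.
#' @return Numeric vector, `100 * ciliated_count / cell_count`. Wells with
#'   `cell_count == 0` have undefined incidence and return `NA` (they are
#'   excluded, with a message, by [screen_zscores()]).
#' @examples
#' cilia_incidence(400, 1000)
#' @export
cilia_incidence <- function(ciliated_count, cell_count) {
  if (any(ciliated_count > cell_count, na.rm = TRUE))
    stop("ciliated_count exceeds cell_count", call. = FALSE)
  ifelse(cell_count > 0, 100 * ciliated_count / cell_count, NA_real_)
}

#' Robust z-score against a pooled control distribution
#'
#' `(x - median(controls)) / (scale_constant * MAD(controls))`, where MAD
#' is the raw (unscaled) median absolute deviation. The default
#' `scale_constant` 1.4826 makes the score comparable to a classical
#' z-score under normality; pass 1 for the unscaled convention.
#'
#' @param x Numeric vector of measurements to score.
#' @param controls Numeric vector of pooled control measurements (>= 4).
#' @param scale_constant MAD consistency constant.
#' @param batch Optional batch id, included in the degenerate-controls
#'   error message.
#' @return Numeric vector of robust z-scores.
#' @examples
#' robust_z(5, c(1, 2, 3, 4, 5))
#' @export
robust_z <- function(x, controls, scale_constant = 1.4826, batch = NULL) {
  controls <- controls[!is.na(controls)]
  if (length(controls) < 4)
    stop("need at least 4 control values", call. = FALSE)
  s <- stats::mad(controls, constant = scale_constant)
  if (s == 0) {
    msg <- "degenerate controls: MAD is zero"
    if (!is.null(batch)) msg <- paste0(msg, " (batch ", batch, ")")
    cond <- simpleError(msg)
    class(cond) <- c("degenerate_controls_error", class(cond))
    stop(cond)
  }
  (x - stats::median(controls)) / s
}

#' Strictly standardised mean difference (SSMD)
#'
#' Method-of-moments SSMD between negative and positive control samples,
#' `(mean(neg) - mean(pos)) / sqrt(var(neg) + var(pos))` with sample
#' (n - 1) variances. Used as a screen quality metric: the separation of
#' control classes in units of their combined spread.
#'
#' @param neg,pos Numeric vectors (each length >= 2).
#' @return A single number.
#' @seealso [ssmd_class()] for the conventional effect-size bands.
#' @export
ssmd <- function(neg, pos) {
  if (length(neg) < 2 || length(pos) < 2)
    stop("need at least 2 values per control group", call. = FALSE)
  v <- stats::var(neg) + stats::var(pos)
  if (v == 0)
    stop("zero variance in both control groups", call. = FALSE)
  (mean(neg) - mean(pos)) / sqrt(v)
}

#' @rdname ssmd
#' @param x An SSMD value.
#' @return `ssmd_class()` returns the conventional band label for `|x|`:
#'   `"extremely strong"` (>= 5), `"very strong"` (\[3, 5)), `"strong"`
#'   (\[2, 3)), `"fairly strong"` (\[1.645, 2)), `"moderate/weak"`
#'   ((0, 1.645)) or `"no effect"` (0).
#' @export
ssmd_class <- function(x) {
  a <- abs(x)
  ifelse(a == 0, "no effect",
  ifelse(a >= 5, "extremely strong",
  ifelse(a >= 3, "very strong",
  ifelse(a >= 2, "strong",
  ifelse(a >= 1.645, "fairly strong", "moderate/weak")))))
}

#' Replicate concordance (squared Pearson correlation)
#'
#' R-squared between two replicates' z-scores over matched conditions.
#'
#' @param zA,zB Z-score tables (data frames with `condition` and the
#'   chosen `field`).
#' @param field `"z_cilia"` or `"z_cell"`.
#' @return R-squared in \[0, 1\]; `NA` (with a warning) if either vector
#'   has zero variance.
#' @export
replicate_concordance <- function(zA, zB, field = c("z_cilia", "z_cell")) {
  field <- match.arg(field)
  m <- merge(zA[, c("condition", field)], zB[, c("condition", field)],
             by = "condition", suffixes = c(".A", ".B"))
  if (nrow(m) < 3)
    stop("need at least 3 matched conditions", call. = FALSE)
  a <- m[[paste0(field, ".A")]]
  b <- m[[paste0(field, ".B")]]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a replicate; concordance undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Robust z-score tables for a screen
#'
#' Scores every well's cilia incidence and cell count against the median
#' and scaled MAD of a pooled control set. Pool membership and pooling
#' scope are explicit, never inferred:
#'
#' * `pool = "negatives_only"` pools the scrambled, no-mouse-target and
#'   mock-transfection negative controls (the siRNA-screen convention and
#'   the package default).
#' * `pool = "all_controls"` additionally pools the positive and
#'   transfection controls (the drug-screen description); the spare
#'   `other` role is never pooled.
#' * `scope = "batch"` pools controls per batch across all replicates
#'   (a drug-screen batch is its four plates within both runs);
#'   `"replicate_batch"` pools per (replicate, batch);
#'   `"replicate"` pools per replicate across all its plates.
#'
#' @param wells Well table as produced by [simulate_screen()] or
#'   [read_well_table()].
#' @param pool Control pool membership (see Details).
#' @param scope Pooling scope (see Details).
#' @param scale_constant MAD consistency constant, see [robust_z()].
#' @return Data frame with columns `condition`, `replicate`, `batch`,
#'   `plate`, `row`, `col`, `role`, `z_cell`, `z_cilia`.
#' @export
screen_zscores <- function(wells,
                           pool = c("negatives_only", "all_controls"),
                           scope = c("batch", "replicate_batch",
                                     "replicate"),
                           scale_constant = 1.4826) {
  pool <- match.arg(pool)
  scope <- match.arg(scope)
  pool_roles <- switch(pool,
    negatives_only = NEG_ROLES,
    all_controls = c(NEG_ROLES, POS_ROLES, "transfection_plk1"))
  wells$incidence <- cilia_incidence(wells$ciliated_count, wells$cell_count)
  n_empty <- sum(is.na(wells$incidence))
  if (n_empty > 0) {
    message(n_empty, " well(s) with zero cells excluded from z-scoring")
    wells <- wells[!is.na(wells$incidence), , drop = FALSE]
  }
  key <- switch(scope,
    batch = wells$batch,
    replicate_batch = paste(wells$replicate, wells$batch, sep = "/"),
    replicate = wells$replicate)
  parts <- split(wells, key)
  out <- lapply(parts, function(g) {
    ctrl <- g[g$role %in% pool_roles, , drop = FALSE]
    g$z_cilia <- robust_z(g$incidence, ctrl$incidence,
                          scale_constant = scale_constant,
                          batch = g$batch[1])
    g$z_cell <- robust_z(g$cell_count, ctrl$cell_count,
                         scale_constant = scale_constant,
                         batch = g$batch[1])
    g
  })
  z <- do.call(rbind, out)
  rownames(z) <- NULL
  z[order(z$replicate, z$batch, z$plate, z$col, z$row),
    c("condition", "replicate", "batch", "plate", "row", "col", "role",
      "z_cell", "z_cilia")]
}

#' Per-batch hit-calling cutoffs from negative controls
#'
#' Normalised cutoffs per the batch-control rule: the upper cilia cutoff
#' is the batch's negative-control median z_cilia plus `margin`; the
#' lower cytotoxicity cutoff is the negative-control median z_cell minus
#' `margin`.
#'
#' @param z Z-score table from [screen_zscores()] (any number of batches).
#' @param margin Cutoff margin in robust z units (default 2, the printed
#'   rule).
#' @return Data frame with columns `batch`, `z_cilia_cutoff`,
#'   `z_cell_cutoff`.
#' @export
batch_cutoffs <- function(z, margin = 2) {
  parts <- split(z, z$batch)
  out <- lapply(parts, function(g) {
    neg <- g[g$role %in% NEG_ROLES, , drop = FALSE]
    if (nrow(neg) == 0)
      stop("batch ", g$batch[1], " has no negative-control records",
           call. = FALSE)
    data.frame(batch = g$batch[1],
               z_cilia_cutoff = stats::median(neg$z_cilia) + margin,
               z_cell_cutoff = stats::median(neg$z_cell) - margin)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plate quality-control gate
#'
#' A plate passes if every positive-control record has `z_cilia <= -2`
#' and every negative-control record has `z_cilia` within \[-2, +2\].
#' Records are whatever the caller supplies; [screen_qc()] feeds
#' per-(plate, role) mean z-scores across replicate wells, the convention
#' under which control points are summarised per plate.
#'
#' @param z Data frame with columns `role`, `z_cilia` and optionally
#'   `well` (used in reason strings) for one plate.
#' @return List with `pass` (logical) and `reasons` (character vector,
#'   one entry per violating record; empty when passing).
#' @export
plate_qc <- function(z) {
  pos <- z[z$role %in% POS_ROLES, , drop = FALSE]
  neg <- z[z$role %in% NEG_ROLES, , drop = FALSE]
  if (nrow(pos) == 0 || nrow(neg) == 0)
    stop("plate is missing a control class (need both positive and negative)",
         call. = FALSE)
  lab <- function(g, i) if ("well" %in% names(g)) g$well[i] else g$role[i]
  reasons <- character(0)
  bad_pos <- which(pos$z_cilia > -2)
  if (length(bad_pos))
    reasons <- c(reasons, sprintf(
      "positive control above -2: %s (z_cilia %.2f)",
      vapply(bad_pos, function(i) lab(pos, i), ""), pos$z_cilia[bad_pos]))
  bad_neg <- which(neg$z_cilia < -2 | neg$z_cilia > 2)
  if (length(bad_neg))
    reasons <- c(reasons, sprintf(
      "negative control outside +/-2: %s (z_cilia %.2f)",
      vapply(bad_neg, function(i) lab(neg, i), ""), neg$z_cilia[bad_neg]))
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Screen-wide plate QC report
#'
#' Summarises control z-scores per (batch, plate, role) as means across
#' wells and replicates, then applies [plate_qc()] to each plate.
#'
#' @param z Z-score table from [screen_zscores()].
#' @return Data frame with columns `batch`, `plate`, `pass`, `reasons`
#'   (semicolon-joined; empty string when passing).
#' @export
screen_qc <- function(z) {
  ctrl <- z[z$role %in% c(POS_ROLES, NEG_ROLES), , drop = FALSE]
  agg <- stats::aggregate(z_cilia ~ batch + plate + role, data = ctrl,
                          FUN = mean)
  parts <- split(agg, list(agg$batch, agg$plate), drop = TRUE)
  out <- lapply(parts, function(g) {
    qc <- plate_qc(g)
    data.frame(batch = g$batch[1], plate = g$plate[1], pass = qc$pass,
               reasons = paste(qc$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$batch, res$plate), , drop = FALSE]
  rownames(res) <- NULL
  res
}
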