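WELL_COLUMNS <- c("replicate", "batch", "plate", "row", "col", "condition",
                  "role", "cell_count", "ciliated_count")

#' Read and validate a well-level screen table
#'
#' CSV dialect: header `replicate,batch,plate,row,col,condition,role,`
#' `cell_count,ciliated_count`; rows are letters A--H, columns integers
#' 1--12. Unknown extra columns are preserved.
#'
#' @param path CSV file path.
#' @return Validated well table (data frame).
#' @export
read_well_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(WELL_COLUMNS, names(x))
  if (length(missing_cols))
    stop("well table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  line <- seq_len(nrow(x)) + 1L  # header is line 1
  bad_row <- !x$row %in% LETTERS[1:8]
  if (any(bad_row))
    stop("invalid row label at line(s) ",
         paste(line[bad_row], collapse = ", "), call. = FALSE)
  x$col <- as.integer(x$col)
  bad_col <- is.na(x$col) | x$col < 1 | x$col > 12
  if (any(bad_col))
    stop("invalid column index at line(s) ",
         paste(line[bad_col], collapse = ", "), call. = FALSE)
  x$cell_count <- as.integer(x$cell_count)
  x$ciliated_count <- as.integer(x$ciliated_count)
  bad_count <- is.na(x$cell_count) | is.na(x$ciliated_count) |
    x$cell_count < 0 | x$ciliated_count < 0
  if (any(bad_count))
    stop("malformed count at line(s) ",
         paste(line[bad_count], collapse = ", "), call. = FALSE)
  over <- x$ciliated_count > x$cell_count
  if (any(over))
    stop("ciliated_count exceeds cell_count at line(s) ",
         paste(line[over], collapse = ", "), call. = FALSE)
  x
}

#' @rdname read_well_table
#' @param wells Well table to write.
#' @export
write_well_table <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analyse a screen: z-scores, QC, cutoffs and primary hit calls
#'
#' The central analysis step: robust z-score tables against pooled
#' controls, per-plate QC, per-batch normalised cutoffs and primary-tier
#' hit calling, returned as one classed object.
#'
#' @param wells Well table ([simulate_screen()] / [read_well_table()]).
#' @param pool,scope,scale_constant Passed to [screen_zscores()].
#' @param margin Cutoff margin, see [batch_cutoffs()].
#' @return An object of class `screen_analysis` with components
#'   `zscores`, `qc`, `cutoffs`, `hits`, `controls` (control summary with
#'   the pooled-incidence SSMD of negative vs positive controls) and
#'   `params`.
#' @examples
#' wells <- simulate_screen(screen_config(n_batches = 1, seed = 3))
#' fit <- analyze_screen(wells)
#' summary(fit)
#' @export
analyze_screen <- function(wells, pool = "negatives_only", scope = "batch",
                           margin = 2, scale_constant = 1.4826) {
  z <- screen_zscores(wells, pool = pool, scope = scope,
                      scale_constant = scale_constant)
  qc <- screen_qc(z)
  cutoffs <- batch_cutoffs(z, margin = margin)
  hits <- call_primary_drug_hits(z, cutoffs)
  inc <- cilia_incidence(wells$ciliated_count, wells$cell_count)
  neg <- inc[wells$role %in% NEG_ROLES]
  pos <- inc[wells$role %in% POS_ROLES]
  screen_ssmd <- ssmd(neg[!is.na(neg)], pos[!is.na(pos)])
  structure(list(
    zscores = z, qc = qc, cutoffs = cutoffs, hits = hits,
    controls = list(ssmd = screen_ssmd,
                    ssmd_class = ssmd_class(screen_ssmd),
                    neg_mean_incidence = mean(neg, na.rm = TRUE),
                    pos_mean_incidence = mean(pos, na.rm = TRUE)),
    params = list(pool = pool, scope = scope, margin = margin,
                  scale_constant = scale_constant)
  ), class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  cat("High-content ciliogenesis screen analysis\n")
  cat(sprintf("  %d well z-scores over %d batch(es); pool = %s, scope = %s\n",
              nrow(x$zscores), nrow(x$cutoffs), x$params$pool,
              x$params$scope))
  cat(sprintf("  plate QC: %d/%d passed\n", sum(x$qc$pass), nrow(x$qc)))
  tab <- table(x$hits$status)
  cat("  primary calls:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.screen_analysis <- function(object, ...) {
  conc <- NA_real_
  reps <- unique(object$zscores$replicate)
  if (length(reps) >= 2) {
    za <- object$zscores[object$zscores$replicate == reps[1] &
                           object$zscores$role == "test", ]
    zb <- object$zscores[object$zscores$replicate == reps[2] &
                           object$zscores$role == "test", ]
    za <- stats::aggregate(z_cilia ~ condition, za, mean)
    zb <- stats::aggregate(z_cilia ~ condition, zb, mean)
    conc <- replicate_concordance(za, zb, "z_cilia")
  }
  out <- list(
    n_wells = nrow(object$zscores),
    qc_pass_fraction = mean(object$qc$pass),
    ssmd = object$controls$ssmd,
    ssmd_class = object$controls$ssmd_class,
    replicate_r2_cilia = conc,
    hit_counts = table(object$hits$status),
    cutoffs = object$cutoffs
  )
  class(out) <- "summary.screen_analysis"
  out
}

#' @export
print.summary.screen_analysis <- function(x, ...) {
  cat("Screen summary\n")
  cat(sprintf("  wells scored:          %d\n", x$n_wells))
  cat(sprintf("  plate QC pass rate:    %.1f%%\n",
              100 * x$qc_pass_fraction))
  cat(sprintf("  control SSMD:          %.3f (%s)\n", x$ssmd, x$ssmd_class))
  if (!is.na(x$replicate_r2_cilia))
    cat(sprintf("  replicate R2 (cilia):  %.3f\n", x$replicate_r2_cilia))
  cat("  primary calls:        ",
      paste(sprintf("%s %d", names(x$hit_counts), x$hit_counts),
            collapse = ", "), "\n")
  cat("  batch cutoffs:\n")
  print(x$cutoffs, row.names = FALSE)
  invisible(x)
}

#' @export
plot.screen_analysis <- function(x, ...) {
  z <- x$zscores
  test_z <- z$z_cilia[z$role == "test"]
  graphics::hist(test_z, breaks = 50, col = "grey85", border = "white",
                 main = "Test-well robust z (cilia incidence)",
                 xlab = expression(z[cilia]), ...)
  graphics::abline(v = x$cutoffs$z_cilia_cutoff, col = "firebrick",
                   lty = 2)
  invisible(x)
}

#' Run the full screening pipeline and write its artifacts
#'
#' Simulate (or load) wells, z-score, QC, derive batch cutoffs, call
#' primary hits, and write all tables plus a machine-readable run
#' manifest to `out_dir`. Outputs are byte-identical across runs with the
#' same configuration and seed.
#'
#' @param config A [screen_config()].
#' @param out_dir Output directory (created if needed).
#' @param wells Optional pre-existing well table; when `NULL` the wells
#'   are simulated from `config`.
#' @param pool,scope,margin Passed to [analyze_screen()].
#' @return Invisibly, a list with the `screen_analysis` object, the
#'   written file paths and `qc_ok` (no plate failed QC).
#' @export
run_pipeline <- function(config, out_dir, wells = NULL,
                         pool = "negatives_only", scope = "batch",
                         margin = 2) {
  stopifnot(inherits(config, "screen_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(wells)) wells <- simulate_screen(config)
  fit <- analyze_screen(wells, pool = pool, scope = scope, margin = margin)
  paths <- list(
    wells = file.path(out_dir, "wells.csv"),
    zscores = file.path(out_dir, "zscores.csv"),
    qc = file.path(out_dir, "qc.csv"),
    cutoffs = file.path(out_dir, "cutoffs.csv"),
    hits = file.path(out_dir, "hits.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_well_table(wells, paths$wells)
  utils::write.csv(fit$zscores, paths$zscores, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fit$qc, paths$qc, row.names = FALSE)
  utils::write.csv(fit$cutoffs, paths$cutoffs, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fit$hits, paths$hits, row.names = FALSE)
  manifest <- list(
    package = "ciliascreen",
    version = as.character(utils::packageVersion("ciliascreen")),
    seed = config$seed,
    n_batches = config$n_batches,
    plates_per_batch = config$plates_per_batch,
    n_replicates = config$n_replicates,
    pool = pool, scope = scope, margin = margin,
    qc_pass = sum(fit$qc$pass), qc_total = nrow(fit$qc),
    hit_counts = as.list(table(fit$hits$status))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(analysis = fit, paths = paths,
                 qc_ok = all(fit$qc$pass)))
}
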