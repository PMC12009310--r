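# Control role vocabulary. `other` is a neutral spare control slot: it is
# never pooled into control statistics and never enters plate QC.
NEG_ROLES <- c("neg_scr", "neg_mlnr", "neg_mock")
POS_ROLES <- c("pos_ift88", "pos_rpgrip1l", "pos_mks1")
ALL_CONTROL_ROLES <- c(NEG_ROLES, POS_ROLES, "transfection_plk1", "other")

#' Standard 96-well screening plate layout
#'
#' Eight control roles occupy columns 1 and 12 (one well per role per
#' column, so every role appears exactly twice per plate); the 80 wells of
#' columns 2--11 hold test conditions.
#'
#' @param control_roles Character vector of 8 distinct control roles, the
#'   top-to-bottom order of rows A--H in the two control columns.
#' @return An object of class `plate_layout` with fields `rows`, `cols`,
#'   `control_roles`.
#' @examples
#' lay <- plate_layout()
#' lay$control_roles
#' @export
plate_layout <- function(control_roles = c("neg_scr", "pos_ift88",
                                           "neg_mlnr", "pos_rpgrip1l",
                                           "neg_mock", "pos_mks1",
                                           "transfection_plk1", "other")) {
  if (length(control_roles) != 8L || anyDuplicated(control_roles))
    stop("a plate layout needs 8 distinct control roles", call. = FALSE)
  bad <- setdiff(control_roles, ALL_CONTROL_ROLES)
  if (length(bad))
    stop("unknown control role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(rows = 8L, cols = 12L, control_roles = control_roles),
            class = "plate_layout")
}

#' Default control effect sizes
#'
#' Effect sizes applied to control wells by [simulate_screen()]. The
#' transfection control kills 78.4% of cells; the IFT88 and RPGRIP1L
#' knockdown controls drop cilia incidence by 9.8 and 17.1 percentage
#' points. The MKS1 knockdown (-12 points) and the residual incidence
#' effect of the transfection control (-10 points) are synthetic choices
#' of comparable magnitude; negative controls and the spare `other` slot
#' are neutral.
#'
#' @return Data frame with columns `role`, `cell_multiplier`,
#'   `incidence_delta` (percentage points added to the baseline incidence).
#' @export
default_control_effects <- function() {
  data.frame(
    role = c(NEG_ROLES, "other", "pos_ift88", "pos_rpgrip1l", "pos_mks1",
             "transfection_plk1"),
    cell_multiplier = c(1, 1, 1, 1, 1, 1, 1, 1 - 0.784),
    incidence_delta = c(0, 0, 0, 0, -9.8, -17.1, -12, -10),
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic ciliogenesis screen
#'
#' Full parameterisation of the generative model behind
#' [simulate_screen()]: plate layout, replicate/batch structure, baseline
#' phenotype levels, noise magnitudes, control effect sizes and planted
#' test-condition effects. Identical configurations with identical seeds
#' produce byte-identical datasets.
#'
#' Cell counts are negative-binomial (gamma-Poisson) around
#' `baseline_cells` x condition cell multiplier x a per-plate log-normal
#' factor (`plate_sigma` on the log scale); ciliated counts are binomial
#' with a per-well success probability jittered on the logit scale
#' (`well_sigma`) around `baseline_incidence` + delta/100.
#'
#' @param n_batches Number of 4-plate batches. Each batch carries its own
#'   set of 80 test conditions; the plates of a batch are technical
#'   replicates of that condition set.
#' @param plates_per_batch Plates per batch (default 4).
#' @param n_replicates Experimental replicates (runs) of the whole screen.
#' @param layout A [plate_layout()].
#' @param baseline_incidence Negative-control cilia incidence as a
#'   fraction in (0,1).
#' @param baseline_cells Mean cells per untreated well.
#' @param cell_dispersion Negative-binomial size parameter for cell
#'   counts; larger is less overdispersed.
#' @param plate_sigma Log-scale sd of the per-plate multiplicative factor
#'   on cell number.
#' @param well_sigma Logit-scale sd of per-well incidence noise.
#' @param control_effects Data frame as [default_control_effects()].
#' @param planted_hits Optional data frame with columns `condition`,
#'   `incidence_delta` (percentage points) and `cell_multiplier`, naming
#'   test conditions (see [test_conditions()]) to perturb.
#' @param seed Master integer seed.
#' @return An object of class `screen_config`.
#' @examples
#' cfg <- screen_config(n_batches = 1, seed = 7)
#' head(test_conditions(cfg))
#' @export
screen_config <- function(n_batches = 2L, plates_per_batch = 4L,
                          n_replicates = 2L, layout = plate_layout(),
                          baseline_incidence = 0.40, baseline_cells = 2000,
                          cell_dispersion = 200, plate_sigma = 0.05,
                          well_sigma = 0.10,
                          control_effects = default_control_effects(),
                          planted_hits = NULL, seed = 1L) {
  stopifnot(inherits(layout, "plate_layout"),
            n_batches >= 1, plates_per_batch >= 1, n_replicates >= 1,
            baseline_cells > 0, cell_dispersion > 0,
            plate_sigma >= 0, well_sigma >= 0)
  if (!(baseline_incidence > 0 && baseline_incidence < 1))
    stop("baseline_incidence must lie in (0, 1)", call. = FALSE)
  req <- c("role", "cell_multiplier", "incidence_delta")
  if (!all(req %in% names(control_effects)))
    stop("control_effects needs columns role, cell_multiplier, incidence_delta",
         call. = FALSE)
  if (any(control_effects$cell_multiplier < 0))
    stop("cell multipliers must be >= 0", call. = FALSE)
  missing_roles <- setdiff(layout$control_roles, control_effects$role)
  if (length(missing_roles))
    stop("no control effect declared for role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  check_probability <- function(delta, who) {
    p <- baseline_incidence + delta / 100
    bad <- which(p <= 0 | p >= 1)
    if (length(bad))
      stop("incidence delta drives probability outside (0,1) for: ",
           paste(who[bad], collapse = ", "), call. = FALSE)
  }
  check_probability(control_effects$incidence_delta, control_effects$role)
  if (!is.null(planted_hits)) {
    if (!all(c("condition", "incidence_delta", "cell_multiplier") %in%
             names(planted_hits)))
      stop("planted_hits needs columns condition, incidence_delta, cell_multiplier",
           call. = FALSE)
    if (any(planted_hits$cell_multiplier < 0))
      stop("planted cell multipliers must be >= 0", call. = FALSE)
    check_probability(planted_hits$incidence_delta, planted_hits$condition)
  }
  structure(list(
    n_batches = as.integer(n_batches),
    plates_per_batch = as.integer(plates_per_batch),
    n_replicates = as.integer(n_replicates),
    layout = layout,
    baseline_incidence = baseline_incidence,
    baseline_cells = baseline_cells,
    cell_dispersion = cell_dispersion,
    plate_sigma = plate_sigma,
    well_sigma = well_sigma,
    control_effects = control_effects,
    planted_hits = planted_hits,
    seed = as.integer(seed)
  ), class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Synthetic ciliogenesis screen configuration\n")
  cat(sprintf("  %d batch(es) x %d plate(s), %d replicate(s); seed %d\n",
              x$n_batches, x$plates_per_batch, x$n_replicates, x$seed))
  cat(sprintf("  baseline: %.1f%% cilia incidence, %.0f cells/well\n",
              100 * x$baseline_incidence, x$baseline_cells))
  cat(sprintf("  noise: NB dispersion %.0f, plate sigma %.3f, well sigma %.3f\n",
              x$cell_dispersion, x$plate_sigma, x$well_sigma))
  n_planted <- if (is.null(x$planted_hits)) 0L else nrow(x$planted_hits)
  cat(sprintf("  planted test-condition effects: %d\n", n_planted))
  invisible(x)
}

#' Test-condition identifiers of a configured screen
#'
#' Each batch has its own set of 80 test conditions, one per test well
#' position, repeated on every plate of the batch and in every replicate.
#'
#' @param config A [screen_config()].
#' @return Character vector of condition ids, e.g. `"b01_A02"`.
#' @export
test_conditions <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  rows <- LETTERS[seq_len(config$layout$rows)]
  cols <- seq(2L, config$layout$cols - 1L)
  unlist(lapply(seq_len(config$n_batches), function(b)
    as.vector(outer(rows, cols, function(r, cc)
      sprintf("b%02d_%s%02d", b, r, cc)))))
}

#' Read / write a screen configuration as a flat YAML file
#'
#' Every scalar default of [screen_config()] can be overridden from the
#' file; `control_effects` and `planted_hits` are stored as column lists.
#'
#' @param path File path.
#' @return `read_screen_config()` returns a [screen_config()];
#'   `write_screen_config()` returns `path` invisibly.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("n_batches", "plates_per_batch", "n_replicates",
               "baseline_incidence", "baseline_cells", "cell_dispersion",
               "plate_sigma", "well_sigma", "seed")
  for (s in intersect(scalars, names(raw))) args[[s]] <- raw[[s]]
  if (!is.null(raw$control_roles))
    args$layout <- plate_layout(unlist(raw$control_roles))
  if (!is.null(raw$control_effects))
    args$control_effects <- as.data.frame(raw$control_effects,
                                          stringsAsFactors = FALSE)
  if (!is.null(raw$planted_hits))
    args$planted_hits <- as.data.frame(raw$planted_hits,
                                       stringsAsFactors = FALSE)
  do.call(screen_config, args)
}

#' @rdname read_screen_config
#' @param config A [screen_config()] to serialise.
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  out <- list(
    n_batches = config$n_batches,
    plates_per_batch = config$plates_per_batch,
    n_replicates = config$n_replicates,
    control_roles = config$layout$control_roles,
    baseline_incidence = config$baseline_incidence,
    baseline_cells = config$baseline_cells,
    cell_dispersion = config$cell_dispersion,
    plate_sigma = config$plate_sigma,
    well_sigma = config$well_sigma,
    control_effects = as.list(config$control_effects),
    seed = config$seed
  )
  if (!is.null(config$planted_hits))
    out$planted_hits <- as.list(config$planted_hits)
  yaml::write_yaml(out, path)
  invisible(path)
}
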