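#' Simulate a well-level screen dataset
#'
#' Draws one well table per the generative model described in
#' [screen_config()]. Each plate gets its own RNG stream derived from the
#' master seed, so any plate can be regenerated independently and the
#' whole dataset is reproducible bit-for-bit.
#'
#' @param config A [screen_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Data frame of well records with columns `replicate`, `batch`,
#'   `plate`, `row`, `col`, `condition`, `role`, `cell_count`,
#'   `ciliated_count`. `role` is `"test"` for test wells.
#' @examples
#' wells <- simulate_screen(screen_config(n_batches = 1, seed = 11))
#' table(wells$role)
#' @export
simulate_screen <- function(config, seed = NULL) {
  stopifnot(inherits(config, "screen_config"))
  master <- if (is.null(seed)) config$seed else as.integer(seed)
  lay <- config$layout
  rows <- LETTERS[seq_len(lay$rows)]
  n_streams <- config$n_replicates * config$n_batches * config$plates_per_batch
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  subseeds <- sample.int(.Machine$integer.max - 1L, n_streams)

  # per-well condition, role and effect vectors (identical on every plate
  # of a batch and across replicates)
  effects <- config$control_effects
  rownames(effects) <- effects$role
  planted <- config$planted_hits

  plate_wells <- function(batch) {
    col <- rep(seq_len(lay$cols), each = lay$rows)
    row <- rep(rows, times = lay$cols)
    role <- rep("test", length(col))
    cond <- sprintf("b%02d_%s%02d", batch, row, col)
    ctrl <- col == 1L | col == lay$cols
    role[ctrl] <- lay$control_roles[match(row[ctrl], rows)]
    cond[ctrl] <- role[ctrl]
    mult <- rep(1, length(col))
    delta <- rep(0, length(col))
    mult[ctrl] <- effects[role[ctrl], "cell_multiplier"]
    delta[ctrl] <- effects[role[ctrl], "incidence_delta"]
    if (!is.null(planted)) {
      hit <- match(cond, planted$condition)
      sel <- !is.na(hit)
      mult[sel] <- planted$cell_multiplier[hit[sel]]
      delta[sel] <- planted$incidence_delta[hit[sel]]
    }
    data.frame(row = row, col = col, condition = cond, role = role,
               mult = mult, delta = delta, stringsAsFactors = FALSE)
  }
  templates <- lapply(seq_len(config$n_batches), plate_wells)

  out <- vector("list", n_streams)
  k <- 0L
  for (rep_i in seq_len(config$n_replicates)) {
    for (batch in seq_len(config$n_batches)) {
      tpl <- templates[[batch]]
      for (plate in seq_len(config$plates_per_batch)) {
        k <- k + 1L
        set.seed(subseeds[k])
        plate_factor <- exp(stats::rnorm(1, 0, config$plate_sigma))
        mu <- config$baseline_cells * tpl$mult * plate_factor
        cells <- stats::rnbinom(nrow(tpl), mu = mu,
                                size = config$cell_dispersion)
        p <- stats::plogis(stats::qlogis(config$baseline_incidence +
                                           tpl$delta / 100) +
                             stats::rnorm(nrow(tpl), 0, config$well_sigma))
        ciliated <- stats::rbinom(nrow(tpl), cells, p)
        out[[k]] <- data.frame(
          replicate = rep_i, batch = batch, plate = plate,
          row = tpl$row, col = tpl$col, condition = tpl$condition,
          role = tpl$role, cell_count = cells, ciliated_count = ciliated,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' @rdname simulate_screen
#' @param object A [screen_config()].
#' @param nsim Number of datasets to draw.
#' @param ... Unused.
#' @return The `simulate` method returns a list of `nsim` well tables
#'   (a single table if `nsim = 1`), successive datasets using seeds
#'   `seed`, `seed + 1`, ...
#' @export
simulate.screen_config <- function(object, nsim = 1, seed = NULL, ...) {
  base_seed <- if (is.null(seed)) object$seed else as.integer(seed)
  sims <- lapply(seq_len(nsim) - 1L,
                 function(i) simulate_screen(object, seed = base_seed + i))
  if (nsim == 1) sims[[1]] else sims
}

#' Simulate paired z-stack intensity profiles with known docking labels
#'
#' Generates unimodal two-channel intensity profiles (channel A: distal
#' appendage stain; channel B: apical stain). A "docked" pair has a
#' peak-slice offset of at most 2 slices; an undocked pair has an offset
#' of at least 3. Ground-truth labels are returned so classifier recovery
#' can be checked exactly.
#'
#' @param n Number of profile pairs.
#' @param docked_fraction Fraction of pairs constructed as docked.
#' @param n_slices Number of z slices (>= 5; undocked pairs need room for
#'   an offset > 2).
#' @param spacing_um Slice spacing in micrometres.
#' @param seed Integer seed.
#' @return List with elements `pairs` (list of data frames with columns
#'   `slice`, `intensity_a`, `intensity_b` and attribute `spacing_um`) and
#'   `label` (character, `"docked"`/`"undocked"`).
#' @export
simulate_zprofiles <- function(n, docked_fraction, n_slices = 9L,
                               spacing_um = 0.5, seed = 1L) {
  stopifnot(n >= 1, docked_fraction >= 0, docked_fraction <= 1)
  if (n_slices < 5L)
    stop("n_slices must be >= 5 to place an undocked offset > 2",
         call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n_docked <- round(n * docked_fraction)
  label <- rep(c("docked", "undocked"), c(n_docked, n - n_docked))
  bump <- function(peak) {
    base <- exp(-((seq_len(n_slices) - peak)^2) / (2 * 1.5^2))
    base + stats::runif(n_slices, 0, 0.05)  # noise < inter-slice drop of the bump
  }
  pairs <- lapply(label, function(lab) {
    if (lab == "docked") {
      pa <- sample.int(n_slices, 1)
      off <- sample(-2:2, 1)
      pb <- min(max(pa + off, 1L), n_slices)
    } else {
      # peak A must leave room for a partner more than 2 slices away
      ok_a <- which(seq_len(n_slices) + 3L <= n_slices |
                      seq_len(n_slices) - 3L >= 1L)
      pa <- ok_a[sample.int(length(ok_a), 1)]
      lo <- seq_len(n_slices)[abs(seq_len(n_slices) - pa) > 2]
      pb <- lo[sample.int(length(lo), 1)]
    }
    structure(data.frame(slice = seq_len(n_slices),
                         intensity_a = bump(pa), intensity_b = bump(pb)),
              spacing_um = spacing_um)
  })
  list(pairs = pairs, label = label)
}

#' Simulate a small grayscale texture image
#'
#' Fixture generator for the Gabor fibre score: either a uniform field
#' (optionally with Gaussian noise) or a sinusoidal grating of given
#' wavelength, orientation and contrast superimposed on a mid-grey
#' background.
#'
#' @param size Image side length in pixels (square image).
#' @param mode `"uniform"` or `"grating"`.
#' @param wavelength Grating wavelength in pixels.
#' @param angle Grating orientation in degrees.
#' @param contrast Peak-to-peak amplitude as a fraction of full range,
#'   in \[0, 1\].
#' @param level Background grey level.
#' @param noise_sd Gaussian pixel noise sd (uniform mode).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return Numeric `size` x `size` matrix.
#' @export
simulate_fibre_image <- function(size = 64L,
                                 mode = c("uniform", "grating"),
                                 wavelength = 8, angle = 0, contrast = 1,
                                 level = 0.5, noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (contrast < 0 || contrast > 1)
    stop("contrast must lie in [0, 1]", call. = FALSE)
  if (mode == "grating" && size < 4 * wavelength)
    stop("image side must be at least 4x the grating wavelength",
         call. = FALSE)
  if (mode == "uniform") {
    img <- matrix(level, size, size)
    if (noise_sd > 0) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(as.integer(seed))
      img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
    }
    return(img)
  }
  th <- angle * pi / 180
  x <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  level + (contrast / 2) * sin(2 * pi * (x * cos(th) + y * sin(th)) /
                                 wavelength)
}

#' Fabricate siRNA annotation flags for a set of conditions
#'
#' The genome-screen re-filter requires, per condition, whether the siRNA
#' pool targets all annotated transcripts and whether the gene has a human
#' orthologue. These flags are inputs to the analysis; this helper draws
#' them at configurable rates for simulated screens.
#'
#' @param conditions Character vector of condition ids.
#' @param p_all_transcripts,p_orthologue Bernoulli probabilities.
#' @param seed Integer seed.
#' @return Data frame with columns `condition`, `targets_all_transcripts`,
#'   `has_human_orthologue`.
#' @export
simulate_annotation_flags <- function(conditions, p_all_transcripts = 0.9,
                                      p_orthologue = 0.95, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  data.frame(
    condition = conditions,
    targets_all_transcripts =
      stats::runif(length(conditions)) < p_all_transcripts,
    has_human_orthologue = stats::runif(length(conditions)) < p_orthologue,
    stringsAsFactors = FALSE
  )
}
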