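#' Classify basal body docking from a paired z-stack profile
#'
#' A basal body is docked at the apical membrane when the most intensely
#' stained slice of the distal-appendage channel lies within
#' `tolerance_slices` slices (default 2, i.e. 1 um at 0.5 um spacing) of
#' the most intensely stained slice of the apical channel. Ties in the
#' peak slice resolve to the lowest slice index.
#'
#' @param intensity_a,intensity_b Non-negative per-slice intensity vectors
#'   (same length, slices in ascending order) for the distal-appendage and
#'   apical stains.
#' @param tolerance_slices Maximum peak-slice offset counted as docked.
#' @return `"docked"`, `"undocked"`, or `"unclassifiable"` when a channel
#'   is all zero.
#' @examples
#' docking_classify(c(0, 1, 5, 2), c(0, 2, 4, 6))
#' @export
docking_classify <- function(intensity_a, intensity_b,
                             tolerance_slices = 2L) {
  stopifnot(length(intensity_a) == length(intensity_b),
            length(intensity_a) >= 2, tolerance_slices >= 0)
  if (any(intensity_a < 0) || any(intensity_b < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (all(intensity_a == 0) || all(intensity_b == 0))
    return("unclassifiable")
  off <- abs(which.max(intensity_a) - which.max(intensity_b))
  if (off <= tolerance_slices) "docked" else "undocked"
}

#' Docking rate over a set of profile pairs
#'
#' @param pairs List of profile pairs: each element either a data frame
#'   with columns `intensity_a`, `intensity_b` (as produced by
#'   [simulate_zprofiles()]) or a list with those elements.
#' @param ciliated Optional logical vector, one flag per pair, marking
#'   pairs whose basal body bears an axoneme; enables the
#'   docked-without-axoneme rate.
#' @param tolerance_slices Passed to [docking_classify()].
#' @return List with `percent_docked`, `n` (classifiable pairs),
#'   `n_unclassifiable`, and `percent_docked_unciliated` when `ciliated`
#'   is supplied (docked AND not ciliated, as a percentage of all
#'   classifiable pairs).
#' @export
docking_rate <- function(pairs, ciliated = NULL, tolerance_slices = 2L) {
  if (length(pairs) == 0) stop("empty profile list", call. = FALSE)
  cls <- vapply(pairs, function(p)
    docking_classify(p$intensity_a, p$intensity_b, tolerance_slices), "")
  n_un <- sum(cls == "unclassifiable")
  if (n_un == length(pairs))
    stop("all ", n_un, " profile pairs are unclassifiable", call. = FALSE)
  ok <- cls != "unclassifiable"
  out <- list(percent_docked = 100 * mean(cls[ok] == "docked"),
              n = sum(ok), n_unclassifiable = n_un)
  if (!is.null(ciliated)) {
    stopifnot(length(ciliated) == length(pairs))
    out$percent_docked_unciliated <-
      100 * mean(cls[ok] == "docked" & !ciliated[ok])
  }
  out
}

#' Ciliary RAB8A intensity: per-ROI maximum over the stack, image mean
#'
#' For each region of interest, the maximum intensity over the z stack is
#' taken; the image summary is the mean of the per-ROI maxima.
#'
#' @param rois List of numeric vectors, one per ROI, giving per-slice
#'   intensities.
#' @return List with `per_roi_max` (numeric vector) and `image_mean`.
#' @export
rab8a_ciliary_intensity <- function(rois) {
  stopifnot(length(rois) >= 1, all(lengths(rois) >= 1))
  mx <- vapply(rois, max, 0)
  list(per_roi_max = mx, image_mean = mean(mx))
}

#' SMO occupancy ratio
#'
#' Total Smoothened-positive area within ciliary regions divided by the
#' number of cilia, controlling for variable cilia size.
#'
#' @param total_smo_area Total SMO area (um^2 or pixels).
#' @param n_cilia Number of cilia in the field.
#' @return The ratio; `NA` with a warning when `n_cilia` is 0.
#' @export
smo_occupancy <- function(total_smo_area, n_cilia) {
  stopifnot(total_smo_area >= 0, n_cilia >= 0)
  if (n_cilia == 0) {
    warning("no cilia in field: SMO occupancy undefined")
    return(NA_real_)
  }
  total_smo_area / n_cilia
}

#' Gabor filter-bank parameters
#'
#' @param scale Gaussian envelope sd in pixels.
#' @param wavelength Sinusoid wavelength in pixels (>= 2, Nyquist).
#' @param n_angles Number of orientations, uniform over \[0, pi).
#' @param normalization Response normalization; only
#'   `"regional_intensity"` (divide by the mean image intensity over the
#'   scored region) is defined.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(scale = 2, wavelength = 8, n_angles = 8L,
                         normalization = "regional_intensity") {
  stopifnot(scale > 0, n_angles >= 1)
  if (wavelength < 2)
    stop("wavelength must be >= 2 pixels (Nyquist)", call. = FALSE)
  normalization <- match.arg(normalization, "regional_intensity")
  structure(list(scale = scale, wavelength = wavelength,
                 n_angles = as.integer(n_angles),
                 normalization = normalization), class = "gabor_params")
}

# Quadrature (even/odd) Gabor kernel pair at one orientation. The even
# kernel has its DC component removed so a constant image gives exactly
# zero response; the odd kernel is zero-sum by symmetry.
gabor_kernel_pair <- function(theta, scale, wavelength) {
  r <- max(ceiling(3.5 * scale), ceiling(wavelength / 2))
  g <- seq(-r, r)
  x <- outer(g, g, function(i, j) j)  # column offset
  y <- outer(g, g, function(i, j) i)  # row offset
  u <- x * cos(theta) + y * sin(theta)
  env <- exp(-(x^2 + y^2) / (2 * scale^2))
  even <- env * cos(2 * pi * u / wavelength)
  odd <- env * sin(2 * pi * u / wavelength)
  even <- even - env * sum(even) / sum(env)
  list(even = even, odd = odd, radius = r)
}

#' Gabor filter-bank score of fibre-like image structure
#'
#' Quantifies oriented fibre-like texture (e.g. phospho-MLCII acto-myosin
#' fibres) with a bank of quadrature Gabor kernels: for each of
#' `n_angles` orientations the magnitude response
#' `sqrt(even^2 + odd^2)` is computed, the maximum across orientations is
#' taken per pixel, and the mean of that maximum over the scored region
#' is divided by the mean regional intensity. The image is mean-removed
#' before filtering and the kernels carry no DC component, so a constant
#' image scores exactly 0 and the unnormalised response is invariant to
#' adding a constant offset.
#'
#' @param image Numeric matrix (grayscale), a file path readable by
#'   [read_fibre_image()], or an object coercible to a matrix.
#' @param mask Optional logical matrix selecting the scored region. The
#'   default is the interior of the image at a margin of one kernel
#'   radius, which keeps boundary effects out of the score.
#' @param params A [gabor_params()].
#' @return A single non-negative score.
#' @examples
#' img <- simulate_fibre_image(64, "grating", wavelength = 8)
#' gabor_fibre_score(img)
#' @export
gabor_fibre_score <- function(image, mask = NULL, params = gabor_params()) {
  if (is.character(image)) image <- read_fibre_image(image)
  image <- as.matrix(image)
  stopifnot(is.numeric(image), inherits(params, "gabor_params"))
  thetas <- (seq_len(params$n_angles) - 1L) * pi / params$n_angles
  kerns <- lapply(thetas, gabor_kernel_pair, scale = params$scale,
                  wavelength = params$wavelength)
  r <- kerns[[1]]$radius
  if (nrow(image) <= 2 * r + 1 || ncol(image) <= 2 * r + 1)
    stop("image smaller than the kernel support", call. = FALSE)
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
    mask[(r + 1):(nrow(image) - r), (r + 1):(ncol(image) - r)] <- TRUE
  }
  stopifnot(identical(dim(mask), dim(image)))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  regional <- mean(image[mask])
  ac <- image - regional
  if (all(ac == 0)) return(0)
  maxmag <- matrix(-Inf, nrow(image), ncol(image))
  for (k in kerns) {
    e <- EBImage::filter2(ac, k$even, boundary = "circular")
    o <- EBImage::filter2(ac, k$odd, boundary = "circular")
    maxmag <- pmax(maxmag, sqrt(e^2 + o^2))
  }
  response <- mean(maxmag[mask])
  if (regional <= 0) {
    if (response == 0) return(0)
    stop("regional mean intensity is not positive; score undefined",
         call. = FALSE)
  }
  response / regional
}

#' Read a grayscale image for fibre scoring
#'
#' Accepts single-channel TIFF or PNG (via EBImage) or a plain
#' whitespace-delimited numeric matrix in a text file.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_fibre_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff", "png")) {
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) > 2) img <- img[, , 1]
    return(as.matrix(img))
  }
  as.matrix(utils::read.table(path))
}

#' Elliptical tubule area
#'
#' Tubule area from its longest axis `a` and the perpendicular axis `b`,
#' by the ellipse formula `pi * a * b` (axes treated as semi-axes; set
#' `axes_are_semi_axes = FALSE` to treat them as diameters, dividing
#' by 4).
#'
#' @param a,b Axis lengths in um, `a >= b > 0` (vectorised).
#' @param axes_are_semi_axes Interpretation flag, default `TRUE`.
#' @return Area(s) in um^2.
#' @examples
#' tubule_area(4, 2)
#' @export
tubule_area <- function(a, b, axes_are_semi_axes = TRUE) {
  if (any(b <= 0)) stop("axes must be positive", call. = FALSE)
  if (any(a < b))
    stop("a must be the longest axis (a >= b)", call. = FALSE)
  area <- pi * a * b
  if (!axes_are_semi_axes) area <- area / 4
  area
}

#' Count organoid cysts from staged surface anomalies
#'
#' Surface anomalies are graded 0 (normal), 1 (small bulges), 2 (rounded
#' cyst-like, smooth edges) or 3 (uneven cyst-like, broken borders);
#' anomalies of stage 2 or 3 count as cysts.
#'
#' @param grades Data frame with columns `organoid` and `stage`, one row
#'   per anomaly (an organoid with no anomalies contributes a row with
#'   stage 0).
#' @return List with `n_cysts`, `n_organoids`, `mean_per_organoid`, and
#'   `per_organoid` (data frame of cyst counts).
#' @export
cyst_count <- function(grades) {
  stopifnot(is.data.frame(grades),
            all(c("organoid", "stage") %in% names(grades)))
  if (!all(grades$stage %in% 0:3))
    stop("invalid stage: stages must be integers 0-3", call. = FALSE)
  is_cyst <- grades$stage >= 2
  per <- stats::aggregate(list(n_cysts = is_cyst),
                          by = list(organoid = grades$organoid), FUN = sum)
  list(n_cysts = sum(is_cyst), n_organoids = nrow(per),
       mean_per_organoid = sum(is_cyst) / nrow(per), per_organoid = per)
}

#' Dual-luciferase ratio normalisation
#'
#' Per-well firefly:Renilla ratios normalised to the reference (vehicle
#' control) ratio.
#'
#' @param firefly,renilla Matched numeric vectors of raw luminescence.
#' @param reference_ratio Firefly:Renilla ratio of the unstimulated
#'   vehicle control.
#' @return Numeric vector of normalised ratios.
#' @export
luciferase_normalize <- function(firefly, renilla, reference_ratio) {
  stopifnot(length(firefly) == length(renilla))
  if (any(renilla <= 0))
    stop("zero or negative Renilla signal in well(s) ",
         paste(which(renilla <= 0), collapse = ", "), call. = FALSE)
  if (reference_ratio <= 0)
    stop("reference_ratio must be positive", call. = FALSE)
  (firefly / renilla) / reference_ratio
}

#' Dose-response summary against a vehicle-well population
#'
#' For each dose group, computes the robust z of cilia incidence and cell
#' number against the vehicle wells (reusing [robust_z()]) and the
#' fold-change in mean incidence relative to the vehicle mean.
#'
#' @param wells Well table with a `dose` column plus `cell_count` and
#'   `ciliated_count`.
#' @param vehicle Well table of the vehicle-control group for the same
#'   genotype.
#' @param scale_constant Passed to [robust_z()].
#' @return Data frame with columns `dose`, `n_wells`, `z_cilia`, `z_cell`,
#'   `fold_change` (dose-group mean incidence / vehicle mean incidence).
#' @export
dose_response_table <- function(wells, vehicle, scale_constant = 1.4826) {
  stopifnot(nrow(vehicle) > 0, "dose" %in% names(wells))
  v_inc <- cilia_incidence(vehicle$ciliated_count, vehicle$cell_count)
  v_cells <- vehicle$cell_count
  parts <- split(wells, wells$dose)
  out <- lapply(parts, function(g) {
    inc <- cilia_incidence(g$ciliated_count, g$cell_count)
    data.frame(dose = g$dose[1], n_wells = nrow(g),
               z_cilia = mean(robust_z(inc, v_inc, scale_constant)),
               z_cell = mean(robust_z(g$cell_count, v_cells,
                                      scale_constant)),
               fold_change = mean(inc) / mean(v_inc))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
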