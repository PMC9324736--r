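# Synthetic digital prostate phantom.
#
# Ellipsoidal compartments with ground-truth ADC and baseline signal S0,
# painted in list order (later compartments overwrite earlier ones), signals
# following the mono-exponential law S(b) = S0 * exp(-b * ADC) at every
# simulated b-value, with optional Rician noise on the magnitude images.
#
# Default tissue values are config defaults chosen for diffusion-MRI
# plausibility (this method's source data publishes no tissue statistics):
# ADC in 1e-6 mm^2/s — tumor 700, peripheral zone 1600, transitional zone
# 1200, bladder fluid 3000, fat-suppressed background 300. Baseline signals
# make bladder fluid dominate the per-patient maximum at b = 0 (as urine
# does in vivo, which is what the DWI normalization relies on) and keep the
# background dark at every b-value.

#' Phantom specification
#'
#' @param shape grid shape (slice, row, column).
#' @param compartments list of compartments, each a list with `name`,
#'   `label` (legend value), `center` and `radii` in voxels (length 3,
#'   slice/row/col), `s0` baseline signal, `adc` ground-truth ADC in
#'   1e-6 mm^2/s. Painted in order: later entries overwrite earlier ones.
#' @param background_s0,background_adc tissue values outside every
#'   compartment (label 0).
#' @param b_values b-values to simulate, s/mm^2.
#' @param noise_sigma Rician noise scale; 0 (default) is noise-free.
#' @param seed integer seed used when `noise_sigma > 0`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(16L, 64L, 64L),
                         compartments = default_compartments(shape),
                         background_s0 = 80, background_adc = 300,
                         b_values = c(0, 800), noise_sigma = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("`shape` must be 3 positive integers", call. = FALSE)
  if (!is.list(compartments) || length(compartments) == 0L) {
    stop("`compartments` must be a non-empty list", call. = FALSE)
  }
  for (cp in compartments) {
    need <- c("name", "label", "center", "radii", "s0", "adc")
    if (!all(need %in% names(cp))) {
      stop(sprintf("each compartment needs fields: %s", paste(need, collapse = ", ")),
           call. = FALSE)
    }
    if (cp$adc < 0 || cp$adc > ADC_MAX) {
      stop("compartment ADC must lie in [0, 4095] storage units", call. = FALSE)
    }
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(list(shape = shape, compartments = compartments,
                 background_s0 = background_s0, background_adc = background_adc,
                 b_values = as.numeric(b_values), noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom compartments
#'
#' Peripheral zone, transitional zone, a tumor inside the PZ, and a bladder
#' whose b = 0 fluid signal dominates the series maximum. Centers/radii are
#' in voxels of the given grid.
#'
#' @param shape grid shape (slice, row, column).
#' @return List of compartment definitions (painter's order).
#' @export
default_compartments <- function(shape = c(16L, 64L, 64L)) {
  sc <- shape / c(16, 64, 64)  # scale the canonical layout to the grid
  cp <- function(name, label, center, radii, s0, adc) {
    list(name = name, label = label, center = center * sc, radii = radii * sc,
         s0 = s0, adc = adc)
  }
  list(
    cp("pz",      2L, c(8, 44, 32), c(5.0, 9.0, 16.0), s0 = 700,  adc = 1600),
    cp("tz",      3L, c(8, 38, 32), c(4.0, 6.0, 10.0), s0 = 600,  adc = 1200),
    cp("tumor",   1L, c(8, 47, 22), c(3.5, 3.5, 3.5),  s0 = 1100, adc = 700),
    cp("bladder", 0L, c(8, 18, 32), c(5.0, 9.0, 14.0), s0 = 2000, adc = 3000)
  )
}

# coordinate grids in voxel units, index order (slice, row, col)
voxel_grids <- function(shape) {
  list(
    z = array(seq_len(shape[1]), shape),
    y = array(rep(seq_len(shape[2]), each = shape[1]), shape),
    x = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
  )
}

rician_noise <- function(signal, sigma) {
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Generate a phantom
#'
#' Paints the compartments, simulates the mono-exponential signal at every
#' requested b-value, and (optionally) applies magnitude Rician noise with
#' the spec's seed, reproducibly.
#'
#' @param spec a [phantom_spec()].
#' @return List with `series` ([diffusion_series()]), `mask`
#'   ([label_mask()]), `adc_true` ([adc_volume()]; noise-free ground
#'   truth), and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec", call. = FALSE)
  shape <- spec$shape
  g <- voxel_grids(shape)

  labels <- array(0L, shape)
  s0 <- array(spec$background_s0, shape)
  adc <- array(spec$background_adc, shape)
  for (cpt in spec$compartments) {
    ctr <- cpt$center
    r <- pmax(cpt$radii, 1e-9)
    inside <- ((g$z - ctr[1]) / r[1])^2 + ((g$y - ctr[2]) / r[2])^2 +
      ((g$x - ctr[3]) / r[3])^2 <= 1
    labels[inside] <- as.integer(cpt$label)
    s0[inside] <- cpt$s0
    adc[inside] <- cpt$adc
  }

  if (spec$noise_sigma > 0) set.seed(spec$seed)
  vols <- lapply(spec$b_values, function(b) {
    s <- s0 * exp(-b * adc / ADC_STORAGE_PER_PHYS)
    if (spec$noise_sigma > 0) s <- array(rician_noise(s, spec$noise_sigma), shape)
    volume3d(s)
  })

  list(
    series = diffusion_series(vols, spec$b_values),
    mask = label_mask(labels),
    adc_true = adc_volume(adc),
    spec = spec
  )
}

#' Simulate a training cohort of phantoms
#'
#' Draws `n_subjects` independent phantoms from the base spec with
#' per-subject jitter on compartment ADC, baseline signal, position and
#' size, plus Rician noise — a stand-in for a multi-patient training set
#' used to pool per-class 2D histograms.
#'
#' @param n_subjects number of phantoms, >= 1.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param base_spec jitter is applied around this [phantom_spec()].
#' @param adc_jitter,s0_jitter,radii_jitter multiplicative jitter
#'   half-widths (uniform in `1 +/- jitter`).
#' @param center_jitter positional jitter half-width in voxels.
#' @param noise_sigma Rician noise scale for the cohort (default 15).
#' @return List of `n_subjects` outputs of [generate_phantom()].
#' @export
default_study <- function(n_subjects, seed = 1L, base_spec = phantom_spec(),
                          adc_jitter = 0.1, s0_jitter = 0.15,
                          center_jitter = 2, radii_jitter = 0.1,
                          noise_sigma = 15) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(sub_seeds[i])
    jmul <- function(x, j) x * stats::runif(length(x), 1 - j, 1 + j)
    cps <- lapply(base_spec$compartments, function(cpt) {
      cpt$adc <- min(jmul(cpt$adc, adc_jitter), ADC_MAX)
      cpt$s0 <- jmul(cpt$s0, s0_jitter)
      cpt$center <- cpt$center + stats::runif(3, -center_jitter, center_jitter)
      cpt$radii <- jmul(cpt$radii, radii_jitter)
      cpt
    })
    spec_i <- phantom_spec(
      shape = base_spec$shape, compartments = cps,
      background_s0 = jmul(base_spec$background_s0, s0_jitter),
      background_adc = min(jmul(base_spec$background_adc, adc_jitter), ADC_MAX),
      b_values = base_spec$b_values, noise_sigma = noise_sigma,
      seed = sub_seeds[i]
    )
    generate_phantom(spec_i)
  })
}

#' Pool per-class histograms over a cohort
#'
#' Runs the full per-patient chain (ADC fit, computed DWI at `b_target`,
#' normalization) on each phantom and accumulates one pooled
#' `histogram2d` per tissue class.
#'
#' @param study output of [default_study()].
#' @param classes legend names to pool (default all four).
#' @param b_low,b_high,b_target see [normalize_patient()].
#' @return Named list of pooled `histogram2d` objects.
#' @export
pool_histograms <- function(study, classes = c("background", "pca", "pz", "tz"),
                            b_low = 0, b_high = 800, b_target = 1500) {
  pooled <- NULL
  for (subj in study) {
    pair <- normalize_patient(subj$series, b_low = b_low, b_high = b_high,
                              b_target = b_target)
    hs <- lapply(classes, function(cl) accumulate(pair, subj$mask, cl))
    names(hs) <- classes
    if (is.null(pooled)) {
      pooled <- hs
    } else {
      for (cl in classes) {
        s <- unclass(pooled[[cl]]) + unclass(hs[[cl]])
        pooled[[cl]] <- structure(s,
          n_total = attr(pooled[[cl]], "n_total") + attr(hs[[cl]], "n_total"),
          class_label = cl, class = c("histogram2d", "matrix", "array"))
      }
    }
  }
  pooled
}
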