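#' Simulation configuration
#'
#' Defines the study conditions for the synthetic cohorts and BOLD-like
#' voxel data: UK-Biobank-style acquisition geometry (490 timepoints at TR
#' 0.735 s), a reference frontal grey-matter region plus 15 analysis
#' regions (three brainstem subdivisions, bilateral amygdala, hippocampus,
#' thalamus, insula and visual cortex, midline hypothalamus and a
#' precentral-gyrus control) and a CSF compartment; per-region neuronal
#' amplitudes in the 0.01--0.08 Hz band with a group effect and optional
#' region-specific interaction effects; nuisance components (sub-0.01 Hz
#' drift, cardiac sinusoid at 1 Hz which aliases below Nyquist, respiratory
#' sinusoid at 0.25 Hz, white thermal noise); a broadband CSF power
#' multiplier; and cohort models in which age, BMI and sex confound the
#' hypertension label while systolic/diastolic pressure define it.
#'
#' Amplitudes are in arbitrary BOLD signal units (the fALFF pipeline is
#' scale-invariant); frequencies in Hz; the group and interaction deltas
#' add to the hypertensive group's neuronal amplitude. The default group
#' delta is small (0.02 against a base near 1.2--1.8), matching a
#' tiny-effect regime; simulations that need measurable power pass larger
#' deltas explicitly.
#'
#' @param seed Integer RNG seed; identical config + seed reproduces
#'   identical data.
#' @param n_hypertensive,n_normotensive Cohort sizes (the normotensive pool
#'   acts as the matching donor pool).
#' @param n_timepoints,tr Acquisition length and repetition time (s).
#' @param region_voxels Named integer vector: voxels per region. Must
#'   include `frontal_gm` (the reference) and may include `csf`.
#' @param base_amplitude Named numeric: per-region neuronal amplitude.
#' @param group_delta Added to every analysis region's amplitude for
#'   hypertensive participants.
#' @param interaction_delta Named numeric: extra region-specific
#'   hypertensive amplitude (zero-length means none).
#' @param drift_amplitude,cardiac_freq,cardiac_amplitude,resp_freq,resp_amplitude,noise_sd
#'   Nuisance model: sd of the shaped drift (< 0.01 Hz), cardiac frequency
#'   (Hz; aliased into the sampled band) and sd, respiratory frequency (Hz)
#'   and sd, white-noise sd.
#' @param csf_multiplier Broadband scale factor applied to every component
#'   of CSF voxels.
#' @param age_mean,age_sd,age_shift Hypertensive age distribution and the
#'   (negative) shift of the normotensive pool mean.
#' @param bmi_mean,bmi_sd,bmi_shift As above for BMI.
#' @param sex_p_male,sex_p_shift Proportion male in the hypertensive group
#'   and the shift for the normotensive pool.
#' @param bp_systolic,bp_diastolic Named lists `list(mean = c(h, n), sd =
#'   c(h, n))` for the two groups' blood pressures (mmHg).
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(
    seed = 1L,
    n_hypertensive = 2054L,
    n_normotensive = 1724L,
    n_timepoints = 490L,
    tr = 0.735,
    region_voxels = default_region_voxels(),
    base_amplitude = default_base_amplitude(),
    group_delta = 0.002,
    interaction_delta = numeric(0),
    drift_amplitude = 0.5,
    cardiac_freq = 1.0,
    cardiac_amplitude = 0.3,
    resp_freq = 0.25,
    resp_amplitude = 0.3,
    noise_sd = 1.0,
    csf_multiplier = 5,
    age_mean = 57.7, age_sd = 6.7, age_shift = -3,
    bmi_mean = 27.8, bmi_sd = 4.0, bmi_shift = -1.5,
    sex_p_male = 0.60, sex_p_shift = -0.10,
    bp_systolic = list(mean = c(149.0, 137.0), sd = c(18.1, 17.0)),
    bp_diastolic = list(mean = c(87.0, 81.2), sd = c(10.6, 9.7))) {
  cfg <- as.list(environment())
  if (cfg$n_hypertensive < 1L || cfg$n_normotensive < 1L) stop("cohort sizes must be >= 1")
  if (cfg$n_timepoints < 4L) stop("'n_timepoints' must be >= 4")
  if (cfg$tr <= 0) stop("'tr' must be positive")
  if (!"frontal_gm" %in% names(cfg$region_voxels)) {
    stop("region_voxels must include the reference region 'frontal_gm'")
  }
  if (any(cfg$region_voxels < 1L)) stop("every region needs at least 1 voxel")
  miss <- setdiff(names(cfg$region_voxels), names(cfg$base_amplitude))
  if (length(miss) > 0L) {
    stop("base_amplitude missing for region(s): ", paste(miss, collapse = ", "))
  }
  if (any(cfg$base_amplitude < 0)) stop("base amplitudes must be nonnegative")
  amps <- c(cfg$drift_amplitude, cfg$cardiac_amplitude, cfg$resp_amplitude,
            cfg$noise_sd, cfg$csf_multiplier)
  if (any(amps < 0)) stop("nuisance amplitudes must be nonnegative")
  if (length(cfg$interaction_delta) > 0L &&
      !all(names(cfg$interaction_delta) %in% names(cfg$region_voxels))) {
    stop("interaction_delta names must be regions")
  }
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_region_voxels <- function() {
  c(frontal_gm = 30L,
    midbrain = 10L, pons = 10L, medulla = 10L,
    amygdala_left = 10L, amygdala_right = 10L,
    hippocampus_left = 10L, hippocampus_right = 10L,
    thalamus_left = 10L, thalamus_right = 10L,
    insula_left = 10L, insula_right = 10L,
    visual_cortex_left = 10L, visual_cortex_right = 10L,
    hypothalamus = 10L, precentral_gyrus = 10L,
    csf = 10L)
}

#' @rdname simulation_config
#' @export
default_base_amplitude <- function() {
  # analysis regions sit a little below the frontal reference, spanning
  # about one z-score unit after standardisation -- the scale of regional
  # variation the measured fALFF z-profiles exhibit; the medulla is the
  # lowest. CSF has a weak neuronal component against the same white
  # noise, so its spectrum is nearly flat.
  c(frontal_gm = 1.500,
    midbrain = 1.460, pons = 1.470, medulla = 1.440,
    amygdala_left = 1.470, amygdala_right = 1.475,
    hippocampus_left = 1.465, hippocampus_right = 1.460,
    thalamus_left = 1.480, thalamus_right = 1.478,
    insula_left = 1.470, insula_right = 1.468,
    visual_cortex_left = 1.490, visual_cortex_right = 1.488,
    hypothalamus = 1.455, precentral_gyrus = 1.485,
    csf = 0.600)
}

#' Names of the analysis regions
#'
#' Every configured region except the reference (`frontal_gm`) and the
#' CSF compartment: the 15 levels of the region factor in the ANCOVA.
#'
#' @param cfg A [simulation_config()].
#' @return Character vector of region names.
#' @export
analysis_regions <- function(cfg) {
  setdiff(names(cfg$region_voxels), c("frontal_gm", "csf"))
}

#' Synthetic ROI label volume
#'
#' Builds the [roi_set()] implied by a simulation config: consecutive
#' integer labels in config order, `frontal_gm` as the reference.
#'
#' @param cfg A [simulation_config()].
#' @return A `roi_set`.
#' @export
synthetic_rois <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  nm <- names(cfg$region_voxels)
  labels <- rep(seq_along(nm), cfg$region_voxels)
  name_map <- stats::setNames(nm, as.character(seq_along(nm)))
  roi_set(labels, name_map, reference_label = which(nm == "frontal_gm"))
}

#' Simulate a confounded two-group cohort
#'
#' Draws hypertensive and normotensive participants with normal age and
#' BMI, Bernoulli sex and group-dependent normal blood pressures. The
#' normotensive pool is shifted on age, BMI and proportion male by the
#' configured amounts, so the raw groups are confounded and matching is
#' required to balance them; blood pressure differs by construction
#' (group-defining). Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @param seed Overrides `cfg$seed` if given.
#' @return List with `participants` (data.frame: id, group, age, sex, bmi,
#'   systolic, diastolic) and `truth` (the generating parameters).
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(as.integer(seed))
  n_h <- cfg$n_hypertensive
  n_n <- cfg$n_normotensive
  draw <- function(n, group_idx) {
    shift <- function(base, delta) base + if (group_idx == 2L) delta else 0
    data.frame(
      age = stats::rnorm(n, shift(cfg$age_mean, cfg$age_shift), cfg$age_sd),
      sex = ifelse(
        stats::rbinom(n, 1, min(max(shift(cfg$sex_p_male, cfg$sex_p_shift), 0), 1)) == 1,
        "male", "female"),
      bmi = stats::rnorm(n, shift(cfg$bmi_mean, cfg$bmi_shift), cfg$bmi_sd),
      systolic = stats::rnorm(n, cfg$bp_systolic$mean[group_idx],
                              cfg$bp_systolic$sd[group_idx]),
      diastolic = stats::rnorm(n, cfg$bp_diastolic$mean[group_idx],
                               cfg$bp_diastolic$sd[group_idx]),
      stringsAsFactors = FALSE
    )
  }
  h <- draw(n_h, 1L)
  n <- draw(n_n, 2L)
  participants <- rbind(
    cbind(data.frame(id = sprintf("H%05d", seq_len(n_h)),
                     group = "hypertensive", stringsAsFactors = FALSE), h),
    cbind(data.frame(id = sprintf("N%05d", seq_len(n_n)),
                     group = "normotensive", stringsAsFactors = FALSE), n)
  )
  participants$age <- pmax(participants$age, 18)
  participants$bmi <- pmax(participants$bmi, 12)
  list(
    participants = participants,
    truth = list(seed = as.integer(seed),
                 n_hypertensive = n_h, n_normotensive = n_n,
                 age = c(cfg$age_mean, cfg$age_mean + cfg$age_shift),
                 bmi = c(cfg$bmi_mean, cfg$bmi_mean + cfg$bmi_shift),
                 sex_p_male = c(cfg$sex_p_male, cfg$sex_p_male + cfg$sex_p_shift),
                 bp_systolic = cfg$bp_systolic, bp_diastolic = cfg$bp_diastolic)
  )
}

# Fold a frequency into the sampled band [0, 1/(2 tr)] (spectral aliasing),
# then snap to the nearest nonzero DFT bin so the sinusoid lands on a
# clean spectral line.
alias_to_bin <- function(f, n, tr) {
  fs <- 1 / tr
  fm <- f %% fs
  fa <- min(fm, fs - fm)
  k <- max(1L, as.integer(round(fa * n * tr)))
  k <- min(k, n %/% 2L)
  k / (n * tr)
}

# Gaussian noise spectrally shaped into `band`, one unit-sd series per
# voxel (rows). Drawn directly in the DFT domain -- iid complex
# coefficients on the in-band bins, conjugate symmetry elsewhere -- which
# is the same process as ideal-mask filtering of white noise (the DFT of
# iid normals has iid complex coefficients) at a fraction of the cost.
shaped_band_noise <- function(n_vox, n, tr, band) {
  freqs <- dft_frequencies(n, tr)
  idx <- band_bin_index(freqs, band)
  if (length(idx) == 0L) stop("band contains no frequency bins at this length")
  b <- length(idx)
  re <- matrix(stats::rnorm(n_vox * b), b, n_vox)
  im <- matrix(stats::rnorm(n_vox * b), b, n_vox)
  if (n %% 2L == 0L) im[idx == n %/% 2L, ] <- 0   # Nyquist bin is real
  X <- matrix(0 + 0i, n, n_vox)
  X[idx + 1L, ] <- matrix(complex(real = re, imaginary = im), b, n_vox)
  X[n - idx + 1L, ] <- Conj(X[idx + 1L, , drop = FALSE])
  x <- t(Re(stats::mvfft(X, inverse = TRUE)) / n)
  s <- sqrt(rowSums(x^2) / (n - 1))
  s[s == 0] <- 1
  x / s
}

#' Simulate BOLD-like voxel time series for one participant
#'
#' Each voxel is the sum of (i) a band-limited Gaussian "neuronal" process
#' shaped into 0.01--0.08 Hz, scaled by the region's amplitude (base +
#' group delta + region-specific interaction delta for hypertensives),
#' (ii) slow scanner drift shaped below 0.01 Hz, (iii) cardiac and
#' respiratory sinusoids with random phase -- the cardiac fundamental
#' (default 1 Hz) lies above the Nyquist limit of 0.680 Hz and is folded
#' to its alias, mirroring how pulsatile contamination enters a TR 0.735 s
#' acquisition -- and (iv) white thermal noise. CSF voxels have the whole
#' mixture multiplied by the broadband CSF factor and carry only a weak
#' neuronal component, so their power is high at every frequency but their
#' spectrum is flatter than parenchyma: high ALFF, low fALFF.
#'
#' Deterministic given `seed`. Sinusoid frequencies are snapped to the
#' nearest DFT bin (after aliasing) so that requested frequencies on a bin
#' edge are well-defined.
#'
#' @param cfg A [simulation_config()].
#' @param participant Either a one-row data.frame with a `group` column or
#'   the group string itself.
#' @param rois A [roi_set()]; defaults to [synthetic_rois()] of `cfg`.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return List with `ts` (a [bold_ts()]), `rois`, and `truth` (per-region
#'   amplitudes actually used).
#' @export
simulate_voxels <- function(cfg, participant, rois = synthetic_rois(cfg),
                            seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  group <- if (is.character(participant)) participant else participant$group
  if (!group %in% c("hypertensive", "normotensive")) stop("unknown group: ", group)
  set.seed(as.integer(seed))
  n <- cfg$n_timepoints
  tr <- cfg$tr
  region_of <- unname(rois$names[as.character(rois$labels)])
  nv <- length(region_of)

  amp <- cfg$base_amplitude[region_of]
  if (group == "hypertensive") {
    in_analysis <- region_of %in% analysis_regions(cfg)
    amp[in_analysis] <- amp[in_analysis] + cfg$group_delta
    if (length(cfg$interaction_delta) > 0L) {
      for (r in names(cfg$interaction_delta)) {
        amp[region_of == r] <- amp[region_of == r] + cfg$interaction_delta[r]
      }
    }
  }
  amp <- pmax(unname(amp), 0)

  x <- shaped_band_noise(nv, n, tr, band_spec(0.01, 0.08)) * amp
  if (cfg$drift_amplitude > 0) {
    x <- x + shaped_band_noise(nv, n, tr, band_spec(0, 0.01)) * cfg$drift_amplitude
  }
  tsec <- (seq_len(n) - 1) * tr
  add_sinusoid <- function(x, f, a) {
    if (a <= 0) return(x)
    fb <- alias_to_bin(f, n, tr)
    phase <- stats::runif(nv, 0, 2 * pi)
    # cos(wt + phi) expanded so the voxel x time grid is one rank-2 product
    basis <- rbind(cos(2 * pi * fb * tsec), sin(2 * pi * fb * tsec))
    x + a * sqrt(2) * (cbind(cos(phase), -sin(phase)) %*% basis)
  }
  x <- add_sinusoid(x, cfg$cardiac_freq, cfg$cardiac_amplitude)
  x <- add_sinusoid(x, cfg$resp_freq, cfg$resp_amplitude)
  if (cfg$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(nv * n, sd = cfg$noise_sd), nrow = nv)
  }
  is_csf <- region_of == "csf"
  if (any(is_csf)) x[is_csf, ] <- x[is_csf, , drop = FALSE] * cfg$csf_multiplier

  truth_amp <- cfg$base_amplitude[names(cfg$region_voxels)]
  list(
    ts = bold_ts(x, tr),
    rois = rois,
    truth = list(group = group, amplitude = truth_amp,
                 group_delta = cfg$group_delta,
                 interaction_delta = cfg$interaction_delta,
                 seed = as.integer(seed))
  )
}
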