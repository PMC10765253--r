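# Fixture builders shared across test files. All randomness is seeded by
# the caller.

# a sinusoid at DFT bin k for n timepoints
bin_sinusoid <- function(n, tr, k, amplitude = 1, phase = 0) {
  t <- seq_len(n) - 1
  amplitude * cos(2 * pi * k * t / n + phase)
}

# participant table with a confounded hypertension label: treated are
# older, heavier and more often male
confounded_cohort <- function(n_treated, n_control, seed,
                              age_shift = 3, bmi_shift = 1.5, sexp_shift = 0.10) {
  set.seed(seed)
  mk <- function(n, group, am, bm, pm, sm, dm) {
    data.frame(
      id = sprintf("%s%04d", toupper(substr(group, 1, 1)), seq_len(n)),
      group = group,
      age = rnorm(n, am, 6.7),
      sex = ifelse(rbinom(n, 1, pm) == 1, "male", "female"),
      bmi = rnorm(n, bm, 4.0),
      systolic = rnorm(n, sm, 18),
      diastolic = rnorm(n, dm, 10),
      stringsAsFactors = FALSE
    )
  }
  rbind(
    mk(n_treated, "hypertensive", 57.7, 27.8, 0.60, 149, 87),
    mk(n_control, "normotensive", 57.7 - age_shift, 27.8 - bmi_shift,
       0.60 - sexp_shift, 137, 81.2)
  )
}

# regional-table fixture for ANCOVA tests, built directly (no voxel
# simulation): balanced 2 x R design with optional effects
make_regional_data <- function(n_per_group, regions, seed,
                               group_effect = 0, region_effects = NULL,
                               interaction = NULL, sigma = 1,
                               beta_age = 0, beta_bmi = 0, beta_sex = 0) {
  set.seed(seed)
  if (is.null(region_effects)) region_effects <- stats::setNames(rep(0, length(regions)), regions)
  n <- 2 * n_per_group
  pt <- data.frame(
    participant_id = sprintf("p%04d", seq_len(n)),
    group = rep(c("hypertensive", "normotensive"), each = n_per_group),
    age = rnorm(n, 58, 7),
    bmi = rnorm(n, 28, 4),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  dat <- merge(expand.grid(participant_id = pt$participant_id,
                           region = regions, stringsAsFactors = FALSE), pt)
  dat$mean_z <- region_effects[dat$region] +
    group_effect * (dat$group == "hypertensive") +
    beta_age * dat$age + beta_bmi * dat$bmi +
    beta_sex * (dat$sex == "male") +
    rnorm(nrow(dat), 0, sigma)
  if (!is.null(interaction)) {
    for (r in names(interaction)) {
      hit <- dat$region == r & dat$group == "hypertensive"
      dat$mean_z[hit] <- dat$mean_z[hit] + interaction[r]
    }
  }
  dat
}

# small simulation config used by the pipeline-level tests: 4 voxels per
# analysis region keeps each replicate light while preserving all 15
# analysis regions and the CSF compartment; the reference stays large (80
# voxels) because tight reference statistics are what keep the
# participant-level standardisation noise small, as in real frontal ROIs
small_sim_config <- function(...) {
  rv <- default_region_voxels()
  rv[] <- 4L
  rv["frontal_gm"] <- 80L
  simulation_config(region_voxels = rv, ...)
}

# balanced participant table (no confounding) for direct regional
# simulation
balanced_participants <- function(n_per_group, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  data.frame(
    id = sprintf("p%04d", seq_len(n)),
    group = rep(c("hypertensive", "normotensive"), n_per_group),
    age = rnorm(n, 58, 7),
    sex = sample(c("male", "female"), n, replace = TRUE),
    bmi = rnorm(n, 28, 4),
    stringsAsFactors = FALSE
  )
}
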