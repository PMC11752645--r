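# shared fixtures built in code

tbi_group_names <- c("no", "mild", "modsev")

zero_offsets <- function(n_rois = 200L) {
  z <- matrix(0, n_rois, 3, dimnames = list(NULL, tbi_group_names))
  list(abeta = z, tau = z)
}

flat_slopes <- function(n_rois = 200L, slope = 0.3) {
  default_coupling_template(n_rois, slope)
}

# cohort with no injected group effects and uniform coupling
null_config <- function(seed, n_rois = 200L, ...) {
  sim_config(seed = seed,
             regional_offset_template = zero_offsets(n_rois),
             coupling_slope_template = flat_slopes(n_rois),
             n_rois = n_rois, ...)
}

# ROIs carrying the injected coupling-slope difference in recovery tests
injected_rois <- 60:84

# the standard cohort used by df-accounting and pipeline checks
default_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- generate_cohort(sim_config(seed = 42))
    co
  }
})
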