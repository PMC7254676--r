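#' Generator parameters for a synthetic neuronal culture
#'
#' Bundles and validates every knob of the synthetic-culture generator. The
#' defaults correspond to the acquisition and indicator constants used
#' throughout the package: 20 frames/s recordings, a calcium transient of
#' 1% dF/F0 amplitude with a 3 s single-exponential decay.
#'
#' Cultures are drawn from a two-state population: with probability
#' `bursty_fraction` a culture exhibits recurring network bursts (a renewal
#' process with gamma-distributed inter-onset intervals of mean `mean_ibi`
#' and shape `ibi_shape`) on top of background activity at `independent_rate`;
#' otherwise it only shows background activity at `independent_rate_nonbursty`.
#' Background ("independent") spikes are placed so that each is more than one
#' frame away from every other spike in the culture, which makes the planted
#' independent-spike count the ground truth for the isolation statistic
#' measured by [independent_spike_fraction()].
#'
#' @param n_rois Total number of ROIs in the field of view.
#' @param frac_active Fraction of cell (non-glia) ROIs that are spiking
#'   neurons, in `[0, 1]`.
#' @param frac_glia Fraction of ROIs that are glia, in `[0, 1]`.
#' @param duration Recording duration in seconds.
#' @param frame_rate Acquisition rate in frames/s; `duration * frame_rate`
#'   must be a whole number of frames.
#' @param mean_ibi Mean inter-burst (onset-to-onset) interval in seconds.
#' @param ibi_shape Gamma shape of the inter-onset interval distribution.
#' @param bursty_fraction Probability that a culture is bursty, in `[0, 1]`.
#' @param burst_participation Fraction of active neurons recruited per burst.
#' @param burst_duration Length of the within-burst spiking window in seconds.
#' @param spikes_per_burst_neuron Spikes emitted by each participant per burst.
#' @param independent_rate Background spike rate (spikes/s per active neuron)
#'   in bursty cultures.
#' @param independent_rate_nonbursty Background rate in non-bursty cultures.
#' @param n_modules Number of modules of the planted directed network.
#' @param p_intra,p_inter Within- and between-module edge probabilities.
#' @param participation_weight Relative weight with which members of a burst's
#'   seed module are recruited, versus other modules (intra:inter ratio).
#' @param recruitment_shape Gamma shape of the per-neuron recruitment
#'   propensity (heterogeneous burst recruitment); `Inf` recruits all active
#'   neurons with equal propensity.
#' @param kernel_amplitude Calcium transient amplitude, % dF/F0.
#' @param kernel_decay Calcium transient decay constant, seconds.
#' @param noise_sd Per-frame Gaussian trace noise, % dF/F0.
#' @param drift_amplitude Amplitude of the slow baseline drift, % dF/F0.
#' @param seed Default seed used by the simulator when none is passed.
#' @return An object of class `generator_params` (a validated named list).
#' @seealso [get_preset()] for calibrated parameter sets, [simulate_raster()].
#' @export
generator_params <- function(n_rois = 1000,
                             frac_active = 0.14,
                             frac_glia = 0.10,
                             duration = 600,
                             frame_rate = 20,
                             mean_ibi = 17,
                             ibi_shape = 4,
                             bursty_fraction = 1,
                             burst_participation = 0.26,
                             burst_duration = 0.5,
                             spikes_per_burst_neuron = 2,
                             independent_rate = 0.045,
                             independent_rate_nonbursty = independent_rate,
                             n_modules = 5,
                             p_intra = 0.3,
                             p_inter = 0.05,
                             participation_weight = 3,
                             recruitment_shape = Inf,
                             kernel_amplitude = 1,
                             kernel_decay = 3,
                             noise_sd = 0.15,
                             drift_amplitude = 2,
                             seed = NULL) {
  p <- list(n_rois = as.integer(n_rois), frac_active = frac_active,
            frac_glia = frac_glia, duration = duration,
            frame_rate = frame_rate, mean_ibi = mean_ibi,
            ibi_shape = ibi_shape, bursty_fraction = bursty_fraction,
            burst_participation = burst_participation,
            burst_duration = burst_duration,
            spikes_per_burst_neuron = as.integer(spikes_per_burst_neuron),
            independent_rate = independent_rate,
            independent_rate_nonbursty = independent_rate_nonbursty,
            n_modules = as.integer(n_modules), p_intra = p_intra,
            p_inter = p_inter, participation_weight = participation_weight,
            recruitment_shape = recruitment_shape,
            kernel_amplitude = kernel_amplitude, kernel_decay = kernel_decay,
            noise_sd = noise_sd, drift_amplitude = drift_amplitude,
            seed = seed)
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  fr <- c("frac_active", "frac_glia", "bursty_fraction",
          "burst_participation", "p_intra", "p_inter")
  for (f in fr) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1)
      stop(sprintf("'%s' must be a fraction in [0, 1]", f))
  }
  if (p$n_rois < 1) stop("'n_rois' must be >= 1")
  if (p$duration <= 0 || p$frame_rate <= 0)
    stop("'duration' and 'frame_rate' must be positive")
  nf <- p$duration * p$frame_rate
  if (abs(nf - round(nf)) > 1e-8)
    stop("'duration' * 'frame_rate' must be an integer frame count")
  if (p$mean_ibi <= 0 || p$ibi_shape <= 0)
    stop("'mean_ibi' and 'ibi_shape' must be positive")
  if (p$kernel_amplitude <= 0 || p$kernel_decay <= 0)
    stop("kernel amplitude and decay must be positive")
  if (p$noise_sd < 0 || p$drift_amplitude < 0)
    stop("'noise_sd' and 'drift_amplitude' must be non-negative")
  if (p$independent_rate < 0 || p$independent_rate_nonbursty < 0)
    stop("independent rates must be non-negative")
  if (p$spikes_per_burst_neuron < 1)
    stop("'spikes_per_burst_neuron' must be >= 1")
  if (p$n_modules < 1) stop("'n_modules' must be >= 1")
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic culture generator parameters\n")
  cat(sprintf("  field of view : %d ROIs (%.0f%% glia), %g s at %g fps\n",
              x$n_rois, 100 * x$frac_glia, x$duration, x$frame_rate))
  cat(sprintf("  activity      : %.0f%% of cells active; bursty fraction %.2f\n",
              100 * x$frac_active, x$bursty_fraction))
  cat(sprintf("  bursts        : IBI %g s (gamma shape %g), %0.f%% participation, %d spike(s)/neuron in %g s\n",
              x$mean_ibi, x$ibi_shape, 100 * x$burst_participation,
              x$spikes_per_burst_neuron, x$burst_duration))
  cat(sprintf("  background    : %.4f (bursty) / %.4f (non-bursty) spikes/s/neuron\n",
              x$independent_rate, x$independent_rate_nonbursty))
  cat(sprintf("  network       : %d modules, p_intra %.2f, p_inter %.2f, recruit weight %g\n",
              x$n_modules, x$p_intra, x$p_inter, x$participation_weight))
  cat(sprintf("  transients    : %g%% dF/F0, decay %g s; noise %g%%, drift %g%%\n",
              x$kernel_amplitude, x$kernel_decay, x$noise_sd,
              x$drift_amplitude))
  invisible(x)
}

#' Calibrated generator presets
#'
#' Returns a full [generator_params()] set for one of the shipped presets.
#' `"WT-STR"`, `"HD-STR"`, `"WT-CTX"` and `"HD-CTX"` are calibrated so the
#' planted population statistics match the published wild-type and HD
#' striatal/cortical culture values (e.g. WT-STR plants 14% active neurons
#' and a 17 s inter-burst interval; HD-STR plants 8% and 24 s). `"BIC-like"`
#' and `"NMDA-like"` are purely dynamical presets emulating disinhibition
#' (strong coherent recruitment) and NMDA-driven activity (raised background
#' rate with no coherent bursts); they model no receptor pharmacology.
#'
#' Presets are read from the editable YAML file
#' `system.file("extdata", "presets.yaml", package = "calnet")`.
#'
#' @param name Preset name, one of `"WT-STR"`, `"HD-STR"`, `"WT-CTX"`,
#'   `"HD-CTX"`, `"BIC-like"`, `"NMDA-like"`.
#' @param ... Overrides applied on top of the preset (any
#'   [generator_params()] argument).
#' @return A `generator_params` object.
#' @examples
#' get_preset("WT-STR")$frac_active  # 0.14
#' @export
get_preset <- function(name, ...) {
  path <- system.file("extdata", "presets.yaml", package = "calnet")
  presets <- yaml::read_yaml(path)
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")))
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(generator_params, args)
}
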