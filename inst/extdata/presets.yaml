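# Synthetic-culture presets.
#
# Each preset is a complete generator parameter set (see ?generator_params for
# units). The four genotype/region presets are calibrated so that the planted
# population statistics match the corresponding published culture statistics:
# percentage of active neurons, network inter-burst interval, per-burst
# participation, global activity rate and independent-spike fraction.
#
# Burst recruitment is community-weighted (`participation_weight`) with
# gamma-heterogeneous per-neuron propensity (`recruitment_shape`), which is
# what gives the GTE-inferred effective networks their published efficiency
# and modularity range.
#
# Cultures are modelled as a two-state population: a `bursty_fraction` of
# cultures exhibits recurring network bursts (renewal process with
# gamma-distributed inter-onset intervals), the remainder shows only
# background activity at `independent_rate_nonbursty`. The bursty fractions
# reproduce the observed shares of bursty cultures per group.
#
# Rates are spikes/s per active neuron; durations in seconds; amplitudes in
# percent dF/F0.

WT-STR:
  n_rois: 1000
  frac_active: 0.14
  frac_glia: 0.10
  duration: 600
  frame_rate: 20
  mean_ibi: 17
  ibi_shape: 4
  bursty_fraction: 0.579
  burst_participation: 0.26
  burst_duration: 0.5
  spikes_per_burst_neuron: 2
  independent_rate: 0.0446
  independent_rate_nonbursty: 0.0159
  n_modules: 5
  p_intra: 0.30
  p_inter: 0.05
  participation_weight: 8
  recruitment_shape: 2.3
  kernel_amplitude: 1
  kernel_decay: 3
  noise_sd: 0.15
  drift_amplitude: 2

HD-STR:
  n_rois: 1000
  frac_active: 0.08
  frac_glia: 0.10
  duration: 600
  frame_rate: 20
  mean_ibi: 24
  ibi_shape: 4
  bursty_fraction: 0.432
  burst_participation: 0.29
  burst_duration: 0.5
  spikes_per_burst_neuron: 2
  independent_rate: 0.0408
  independent_rate_nonbursty: 0.0146
  n_modules: 4
  p_intra: 0.30
  p_inter: 0.05
  participation_weight: 8
  recruitment_shape: 10
  kernel_amplitude: 1
  kernel_decay: 3
  noise_sd: 0.15
  drift_amplitude: 2

WT-CTX:
  n_rois: 1000
  frac_active: 0.31
  frac_glia: 0.10
  duration: 600
  frame_rate: 20
  mean_ibi: 10
  ibi_shape: 4
  bursty_fraction: 1.0
  burst_participation: 0.37
  burst_duration: 0.5
  spikes_per_burst_neuron: 1
  independent_rate: 0.0348
  independent_rate_nonbursty: 0.0348
  n_modules: 5
  p_intra: 0.30
  p_inter: 0.05
  participation_weight: 8
  recruitment_shape: 2
  kernel_amplitude: 1
  kernel_decay: 3
  noise_sd: 0.15
  drift_amplitude: 2

HD-CTX:
  n_rois: 1000
  frac_active: 0.29
  frac_glia: 0.10
  duration: 600
  frame_rate: 20
  mean_ibi: 9.4
  ibi_shape: 4
  bursty_fraction: 1.0
  burst_participation: 0.36
  burst_duration: 0.5
  spikes_per_burst_neuron: 1
  independent_rate: 0.0383
  independent_rate_nonbursty: 0.0383
  n_modules: 5
  p_intra: 0.30
  p_inter: 0.05
  participation_weight: 8
  recruitment_shape: 2
  kernel_amplitude: 1
  kernel_decay: 3
  noise_sd: 0.15
  drift_amplitude: 2

# Disinhibition-like dynamical preset: more active neurons, near-total burst
# recruitment, longer inter-burst intervals, few isolated spikes.
BIC-like:
  n_rois: 1000
  frac_active: 0.25
  frac_glia: 0.10
  duration: 600
  frame_rate: 20
  mean_ibi: 25
  ibi_shape: 4
  bursty_fraction: 1.0
  burst_participation: 0.55
  burst_duration: 0.8
  spikes_per_burst_neuron: 3
  independent_rate: 0.010
  independent_rate_nonbursty: 0.010
  n_modules: 5
  p_intra: 0.30
  p_inter: 0.05
  participation_weight: 8
  recruitment_shape: 2
  kernel_amplitude: 1
  kernel_decay: 3
  noise_sd: 0.15
  drift_amplitude: 2

# NMDA-like dynamical preset: raised activity with no coherent network bursts.
NMDA-like:
  n_rois: 1000
  frac_active: 0.25
  frac_glia: 0.10
  duration: 600
  frame_rate: 20
  mean_ibi: 17
  ibi_shape: 4
  bursty_fraction: 0.0
  burst_participation: 0.26
  burst_duration: 0.5
  spikes_per_burst_neuron: 2
  independent_rate: 0.080
  independent_rate_nonbursty: 0.080
  n_modules: 5
  p_intra: 0.30
  p_inter: 0.05
  participation_weight: 8
  recruitment_shape: 2
  kernel_amplitude: 1
  kernel_decay: 3
  noise_sd: 0.15
  drift_amplitude: 2
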