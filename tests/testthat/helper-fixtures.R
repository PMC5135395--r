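# shared fixture builders (all generated in code; no stored data)

# an fv_curve with exact (noise-free) rate values on given bin centers
make_fv_curve <- function(v, nu, residence = 1, dt_s = 5e-5) {
  structure(list(vm_bin_centers = v,
                 residence_s = rep_len(residence, length(v)),
                 pre_spike_counts = nu * rep_len(residence, length(v)),
                 rate_hz = nu, dt_s = dt_s, bin_width = diff(v[1:2]),
                 n_spikes_used = length(v)),
            class = "fv_curve")
}

# amplitude map on an arbitrary electrode layout
make_amplitude_map <- function(amplitude, x, y) {
  structure(list(amplitude_uV = amplitude,
                 electrodes = data.frame(electrode_id = seq_along(x),
                                         x_um = x, y_um = y),
                 noise_sd = 0, source = NULL),
            class = "amplitude_map")
}

# bare vm_distribution with prescribed moments
new_vm_dist_for_test <- function(mean, sd) {
  structure(list(bin_edges = numeric(0), counts = integer(0),
                 mean = mean, sd = sd, skewness = 0,
                 skewness_degenerate = FALSE, n = 100, low_n = FALSE,
                 estimator_kind = "temporal", values = numeric(0)),
            class = "vm_distribution")
}

# canonical fluctuation-driven parameter set: mean drive 3 Vm-SDs below
# threshold (distance 15 mV, sigma_V = 3 mV), tonic drive
fluct_params <- function(Im = 0.6, ...) {
  neuron_params(Im = Im, current_noise_sd = 0.3, duty = 1, ...)
}

# canonical mean-driven set: Rm*Im = 20 mV > 15 mV distance
mean_params <- function(noise = 0, Im = 2, ...) {
  neuron_params(Im = Im, current_noise_sd = noise, duty = 1, ...)
}
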