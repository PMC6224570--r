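# Reference strong-coupling run: azobenzene-like 2-D surrogate in a lossy
# cavity. Units: photon energy eV, g au, times fs (sampling ps), angles deg.
seed = 1
output_dir = "polhop-out"

[model]
name = "azo2d"

[cavity]
photon_energy_ev = 1.3
g = 0.010
polarization = [0, 0, 1]

[sampling]
temperature_K = 300
total_time_ps = 10
equilibration_ps = 1
stride_fs = 10

[simulation]
dt_fs = 0.1
t_total_fs = 500
n_trajectories = 300

[losses]
tau_c_fs = [10, 50, 100]
replicas = 5
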