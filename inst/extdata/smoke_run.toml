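# Tiny smoke-test configuration (seconds, not minutes)
seed = 1
output_dir = "polhop-smoke"

[model]
name = "azo2d"

[cavity]
photon_energy_ev = 1.3
g = 0.010

[sampling]
total_time_ps = 0.3
equilibration_ps = 0.05
stride_fs = 10

[simulation]
dt_fs = 0.1
t_total_fs = 20
n_trajectories = 5

[losses]
tau_c_fs = [10, 50]
replicas = 2
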