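# Baseline parameter configuration.
# Flat key/value YAML; every key is a parameter of default_parameters().
# Units: rates per day; times as named (min/hours/days/seconds); thresholds
# in pMHC x minutes of contact; concentrations in cells/mm3; dc_recruit_count
# and ln_target_cells are full-scale values (the scale factor is applied by
# the simulator).

s_n4_0: 0.27
s_n8_0: 0.1216
thymic_decline: 0.05
n4_0: 450.0
n8_0: 320.0
delta_n4: 0.0006
delta_n8: 0.00038
delta_e4: 0.3
delta_e8: 0.3
delta_cm4: 0.0016
delta_cm8: 9.4951669e-05
delta_em4: 0.06
delta_em8: 0.06
xi_e4: 0.7
xi_e8: 0.7
xi_em4: 0.07
xi_em8: 0.05
alpha_em4: 0.03
alpha_em8: 0.013
bind_time: 480.0
cm_bind_time: 240.0
priming_threshold: 45000.0
effector_threshold: 75000.0
em_threshold: 160000.0
aicd_threshold: 320000.0
aicd_enabled: 1.0
cd8_threshold_scale: 1.0
cd8_effector_scale: 1.6
cd8_aicd_scale: 1.4
prob_em: 0.25
prob_cm: 0.35
cm_signal_efficiency: 2.0
dc_licensing_prob: 0.3
licensing_boost: 1.5
extra_recruitment: 2.0
divisions_activated_cd4: 0.0
divisions_activated_cd8: 2.0
divisions_activated_cm: 2.0
cm_refractory_days: 7.0
div_signal_slope: 3.4
div_max_extra: 9.0
divisions_effector: 2.0
divisions_effector_cd8: 2.0
cell_cycle_h: 5.0
cognate_frequency: 0.0001
cd8_requires_ldc: 1.0
k_bind: 100.0
dc_pmhc_sdlog: 0.55
dc_max_bound: 10.0
dc_lifespan_days: 5.0
t_speed: 10.0
site_capacity: 8.0
ln_transit_h: 16.0
ln_target_cells: 170000.0
ln_density: 4000000.0
dc_recruit_count: 200.0
dc_pmhc_level: 200.0
dc_window_days: 2.0
replicates: 5.0
presim_days: 3.0
compartment_scale: 0.005
cells_to_concentration: 4.6e-07
abm_dt: 25.0
ode_substeps: 100.0
blood_only_dt: 0.01
scale: 1.0
seed: 1.0

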