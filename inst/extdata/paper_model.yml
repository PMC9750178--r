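# Example pipeline configuration: the standard-cell curvature-coupling run.
stages: [shape, energy, density, sample, spots]
seed: 1
diameter_um: 8.0
central_thickness_um: 1.0
max_thickness_um: 2.5
target_area_um2: 138
Kb_kBT: 20
K_P_kBT: 20
dome_S_cap_nm2: 450
dome_R_P0_nm: 42
n_energy_grid: 25
segmentation: curvature-sign
n_cells: 5
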