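# Default run configuration: the Notch-inhibition timecourse measured
# for ptc2 and sox2. Any field omitted here falls back to the package
# defaults (see ?phreshConfig); fields are in the units stated.
recipe: fig_notch_timecourse
seed: 1

n_embryos: 8          # embryos per condition
n_sections: 8         # transverse sections measured per embryo
timepoints: [1, 2]    # hours of LY-411575 treatment
markers: [ptc2, sox2]
drug_start: 20        # hpf
duration: 10          # hours heat shock -> fixation (fig_gli1_rescue)
heatshock_time: 20    # hpf (fig_gli1_rescue)

cell_spacing: 2.5     # um between cell centres
amplitude: 50         # marker expression amplitude, a.u.
embryo_sigma: 0.03    # lognormal sd of embryo-level domain-size factor
brightness_sigma: 0.10 # lognormal sd of embryo-level staining intensity

geometry:
  dv_height: 50       # um
  ml_width: 20        # um
  ap_length: 250      # um (five 50-um somites)
  canal_dv_frac: 0.3
  canal_ml_frac: 0.5
  somite_length: 50   # um
  cell_diameter: 5    # um

optics:
  voxel_size: [1, 1, 1]   # um per voxel (ML, DV, AP)
  psf_sigma: [1, 1, 1]    # um
  background_offset: 5    # counts

noise:
  photon_gain: 50         # counts per a.u.
  read_noise_sigma: 2     # counts

# Mann-Whitney comparisons run on control-max normalized per-embryo
# values after measurement.
comparisons:
  - {a: LY411575_1h, b: DMSO, marker: ptc2}
  - {a: LY411575_1h, b: DMSO, marker: sox2}
  - {a: LY411575_2h, b: DMSO, marker: ptc2}
  - {a: LY411575_2h, b: DMSO, marker: sox2}

# out_dir: results/fig_notch_timecourse
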