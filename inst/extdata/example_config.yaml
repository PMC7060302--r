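# Synthetic example configuration for a paediatric whole-body dosimetry run.
# The probe CSV alongside this file was produced by gen_probe_series()
# (seed 20) for the same administered activity.
patient:
  mass_kg: 17.5
  sigma_mass_kg: 0.5
  admin_activity_MBq: 6893
  admin_datetime: "2019-03-04 10:00:00"
protocol:
  target_wb_dose_Gy: 4
  n_fractions: 2
  alpha: 0.05
camera:
  Q_cps_per_MBq: 29.2
  tau_low_us: 12.8
  tau_high_us: 0.47
  mode_switch_cps: 20000
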