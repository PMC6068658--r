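# Demonstration pipeline configuration: simulate a small push-broom scan,
# calibrate wavelength from mercury-lamp frames, assemble the cube and map
# vegetation with RLRI. Paths are relative to the working directory.
output_dir: pushbroom_out
seed: 42
simulate:
  enabled: true
  sensor_rows: 24          # slit rows (spatial axis)
  sensor_cols: 480         # spectral columns
  scan_lines: 30           # frames in the scan
  vegetation_fraction: 0.3333333
  dispersion: [400.0, 0.73]   # ground-truth lambda(col), nm
  n_lamp_frames: 3
calibrate:
  order: 1                 # dispersion fit order (1 or 2)
analyze:
  threshold: 0.3
  nir_window: [740, 750]
  red_window: [680, 690]
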