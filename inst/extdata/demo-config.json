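{
  "seed": 11,
  "out_dir": "diamorph-demo",
  "alpha": 0.05,
  "ratio_mode": "mean_widths",
  "cohort": {
    "parameters": "printed",
    "n_per_group": 6
  },
  "images": {
    "enabled": false,
    "n_longitudinal": 1,
    "n_section": 1,
    "pixel_size_um": 0.15,
    "section_pixel_size_um": 0.5,
    "image_shape": [512, 512],
    "n_section_fibers": 16,
    "channels": {"laminin": 1, "nuclei": 2, "cd68": 3}
  },
  "report": {
    "enabled": true
  }
}
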