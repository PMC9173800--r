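[
  {
    "label": "DA 0.01",
    "flash_strength": 0.01,
    "background_kind": "dark",
    "background_scotopic_luminance": 0,
    "background_photopic_luminance": 0,
    "mode": "single_flash"
  },
  {
    "label": "DA 3",
    "flash_strength": 3,
    "background_kind": "dark",
    "background_scotopic_luminance": 0,
    "background_photopic_luminance": 0,
    "mode": "single_flash"
  },
  {
    "label": "DA 10",
    "flash_strength": 10,
    "background_kind": "dark",
    "background_scotopic_luminance": 0,
    "background_photopic_luminance": 0,
    "mode": "single_flash"
  },
  {
    "label": "LA 30Hz",
    "flash_strength": 3,
    "background_kind": "white_photopic",
    "background_scotopic_luminance": 0,
    "background_photopic_luminance": 30,
    "mode": "flicker_30hz"
  },
  {
    "label": "LA 3",
    "flash_strength": 3,
    "background_kind": "white_photopic",
    "background_scotopic_luminance": 0,
    "background_photopic_luminance": 30,
    "mode": "single_flash"
  },
  {
    "label": "X0.67-dark",
    "flash_strength": 0.67,
    "background_kind": "dark",
    "background_scotopic_luminance": 0,
    "background_photopic_luminance": 0,
    "mode": "single_flash"
  },
  {
    "label": "X4-dark",
    "flash_strength": 4,
    "background_kind": "dark",
    "background_scotopic_luminance": 0,
    "background_photopic_luminance": 0,
    "mode": "single_flash"
  },
  {
    "label": "X13-dark",
    "flash_strength": 13,
    "background_kind": "dark",
    "background_scotopic_luminance": 0,
    "background_photopic_luminance": 0,
    "mode": "single_flash"
  },
  {
    "label": "X67-dark",
    "flash_strength": 67,
    "background_kind": "dark",
    "background_scotopic_luminance": 0,
    "background_photopic_luminance": 0,
    "mode": "single_flash"
  },
  {
    "label": "X0.67-blue",
    "flash_strength": 0.67,
    "background_kind": "blue_rod_saturating",
    "background_scotopic_luminance": 30,
    "background_photopic_luminance": 1,
    "mode": "single_flash"
  },
  {
    "label": "X4-blue",
    "flash_strength": 4,
    "background_kind": "blue_rod_saturating",
    "background_scotopic_luminance": 30,
    "background_photopic_luminance": 1,
    "mode": "single_flash"
  },
  {
    "label": "X13-blue",
    "flash_strength": 13,
    "background_kind": "blue_rod_saturating",
    "background_scotopic_luminance": 30,
    "background_photopic_luminance": 1,
    "mode": "single_flash"
  },
  {
    "label": "X67-blue",
    "flash_strength": 67,
    "background_kind": "blue_rod_saturating",
    "background_scotopic_luminance": 30,
    "background_photopic_luminance": 1,
    "mode": "single_flash"
  }
]
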