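[
  {
    "laser_source": "HoYAG",
    "fiber_diameter_um": 272,
    "composition": "COM",
    "pulse_energy_J": 0.8,
    "frequency_Hz": 10,
    "ablation_speed_mm3_per_s": 1.0,
    "note": "illustrative example value, not a clinical calibration"
  },
  {
    "laser_source": "HoYAG_MOSES",
    "fiber_diameter_um": 272,
    "composition": "COM",
    "pulse_energy_J": 0.8,
    "frequency_Hz": 10,
    "ablation_speed_mm3_per_s": 1.6,
    "note": "illustrative example value, not a clinical calibration"
  },
  {
    "laser_source": "TFL",
    "fiber_diameter_um": 272,
    "composition": "COM",
    "pulse_energy_J": 0.5,
    "frequency_Hz": 20,
    "ablation_speed_mm3_per_s": 2.5,
    "note": "illustrative example value, not a clinical calibration"
  },
  {
    "laser_source": "TFL",
    "fiber_diameter_um": 150,
    "composition": "UA",
    "pulse_energy_J": 0.5,
    "frequency_Hz": 20,
    "ablation_speed_mm3_per_s": 2.0,
    "note": "illustrative example value, not a clinical calibration"
  }
]
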