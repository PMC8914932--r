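{
  "schema_version": 1,
  "calibration": {"p1": 186.1, "p2": 224.5, "p3": 64.76, "p4": -18.59, "p5": 0},
  "layout": {
    "yi": [0, 1.5, 3, 4.5, 6, 12, 13.08, 14.16, 15.24, 16.32, 17.4, 18.48, 19.56, 20.64, 21.72, 22.8],
    "region": ["heel", "heel", "heel", "heel", "heel", "forefoot", "forefoot", "forefoot", "forefoot", "forefoot", "forefoot", "forefoot", "forefoot", "forefoot", "forefoot", "forefoot"],
    "wyi": [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
  },
  "thresholds": {"VT": -0.05, "vGRFT": 15},
  "imu_thresholds": {
    "wxT_MSw": 75, "wxT_TO": -65, "aT": 7,
    "hs_search_window": 0.75, "idle_after_hs": 0.4, "pre_peak_window": 0.03
  },
  "branch": [-2, 0],
  "simulation": {
    "stride_period": 1.6, "duty_factor": 0.62, "body_mass": 70,
    "n_strides": 20, "fs_sensors": 100, "fs_forceplate": 200,
    "noise_sd_voltage": 0.005, "noise_sd_accel": 0.1, "noise_sd_gyro": 1,
    "noise_sd_force": 0.5, "peak_scale": 10.4, "cop_start": 2,
    "cop_end": 21, "hs_impact_delay": 0.02, "seed": 1
  }
}
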