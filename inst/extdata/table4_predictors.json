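{
  "F1": {"(Intercept)": 79.64, "G": -13.04, "BM": -0.3728},
  "F2": {"(Intercept)": 43.77, "G": -9.741, "BM": -0.3182, "HR_0_inv": 4381},
  "F3": {"(Intercept)": 77.58, "G": -9.769, "BM": -0.2676, "RMS_bl_y_1": -14.41},
  "F4": {"(Intercept)": 25.78, "G": -8.861, "BM": -0.2538, "HR_0_inv": 5546, "VAR_t_total_0_inv": 4.879}
}
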