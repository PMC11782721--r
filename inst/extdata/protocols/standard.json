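{
  "tr_mp2rage_s": 5,
  "tr_flash_s": 0.00718,
  "ti1_s": 0.7,
  "ti2_s": 2.5,
  "fa1_deg": 4,
  "fa2_deg": 5,
  "n_exc": 138,
  "inv_eff": 0.96,
  "b1_scale": 1.0
}
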