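# Built-in vaccine scenarios. The two arms differ only in the IKK-beta
# degradation rate: 0.840 1/h for conventionally matured DCs, 0.216 1/h for
# DCs electroporated with constitutively active IKK. The maturation stimulus
# received ex vivo is a unit pulse on the first 4 h.
normal_dc:
  stimulus:
    time: [0, 4]
    value: [1, 0]
caikk_dc:
  stimulus:
    time: [0, 4]
    value: [1, 0]
  overrides:
    k_deg_IKKb: 0.216
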