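# Example generator configuration (mirrors the package defaults, smaller n)
n_reports: 1000
seed: 42
duplicate_fraction: 0.1
drugs:
  CLOTRIMAZOLE: 0.2259
  ECONAZOLE: 0.0491
  KETOCONAZOLE: 0.1904
  MICONAZOLE: 0.5346
planted:
  - drug: MICONAZOLE
    event: HAEMATURIA
    lambda: 8
  - drug: ECONAZOLE
    event: ABORTION SPONTANEOUS
    lambda: 10
    age_group: g19_39
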