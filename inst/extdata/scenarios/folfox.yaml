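# Scenario 2: toxicity occurred on first-line FOLFOX.
# Identical to scenario 1 except reduced FOLFOX replaces reduced CAPOX.
scenario:
  name: folfox
  reference_strategy: stop_iri
  strategies:
  - name: stop_iri
    label: "Stop -> irinotecan"
    first_line: ~
    second_line:
      name: irinotecan_mono
      components: [iri_mono]
      admin: admin_short
      cycle_weeks: 3
    rr_os: 1.50
    rr_ttp: 1.50
    discontinuation: yes
    s1_based: no
    ae: {p_hfs: 0.0, p_cvt: 0.0, p_diarrhoea: 0.0, p_anorexia: 0.0,
         cost_hfs: 50, cost_cvt: 200, disutility: 0.15, duration_weeks: 2}
  - name: redFOLFOX_iri
    label: "Reduced FOLFOX -> irinotecan"
    first_line:
      name: reduced_folfox
      components: [fu_lv, oxaliplatin]
      admin: admin_long
      cycle_weeks: 2
    second_line:
      name: irinotecan_mono
      components: [iri_mono]
      admin: admin_short
      cycle_weeks: 3
    rr_os: 1.0
    rr_ttp: 1.0
    discontinuation: no
    s1_based: no
    ae: {p_hfs: 0.55, p_cvt: 0.40, p_diarrhoea: 0.0, p_anorexia: 0.0,
         cost_hfs: 50, cost_cvt: 200, disutility: 0.15, duration_weeks: 2}
  - name: SOX_iri
    label: "SOX -> irinotecan"
    first_line:
      name: sox
      components: [s1_combo, oxaliplatin]
      admin: admin_short
      cycle_weeks: 3
    second_line:
      name: irinotecan_mono
      components: [iri_mono]
      admin: admin_short
      cycle_weeks: 3
    rr_os: 0.93
    rr_ttp: 1.0
    discontinuation: no
    s1_based: yes
    ae: {p_hfs: 0.05, p_cvt: 0.04, p_diarrhoea: 0.0, p_anorexia: 0.0,
         cost_hfs: 50, cost_cvt: 200, disutility: 0.15, duration_weeks: 2}
  - name: SOX_IRIS
    label: "SOX -> IRIS"
    first_line:
      name: sox
      components: [s1_combo, oxaliplatin]
      admin: admin_short
      cycle_weeks: 3
    second_line:
      name: iris
      components: [s1_combo, iri_combo]
      admin: admin_short
      cycle_weeks: 3
    rr_os: 0.93
    rr_ttp: 1.0
    discontinuation: no
    s1_based: yes
    ae: {p_hfs: 0.05, p_cvt: 0.04, p_diarrhoea: 0.0, p_anorexia: 0.0,
         cost_hfs: 50, cost_cvt: 200, disutility: 0.15, duration_weeks: 2}
settings:
  horizon_weeks: 780
  discount_costs: 0.03
  discount_qalys: 0.015
  p_second_line: 0.80
  cohort_size: 1000
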