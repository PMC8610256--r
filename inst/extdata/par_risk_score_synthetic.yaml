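# SYNTHETIC stand-in for the PAR-Risk Score point table.
#
# The published point table (supplement of the original development study) is
# not redistributable here. The only weight fixed by the validation study's
# main text is anaemia = 2 points; the remaining 11 weights below are
# plausible synthetic integers chosen once, ordered roughly by the published
# unadjusted odds ratios, with a maximum attainable score (42) comfortably
# above the adapted high-risk cut (25). Replace this file with a transcription
# of the published table before validating the real score.
label: "PAR-Risk Score (synthetic point table; anaemia = 2 is the only published weight)"
items:
  - name: prior_adm_6m
    points: 5
  - name: los_gt4
    points: 4
  - name: anaemia
    points: 2
  - name: hypertension
    points: 2
  - name: heart_failure
    points: 4
  - name: acute_mi
    points: 3
  - name: chronic_ihd
    points: 2
  - name: diabetes_organ
    points: 3
  - name: cancer
    points: 4
  - name: metastatic_ca
    points: 6
  - name: opioids
    points: 4
  - name: hyperkalaemia
    points: 3
thresholds:
  cut_low: 3
  cut_high: 10
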