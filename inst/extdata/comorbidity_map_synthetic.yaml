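# SYNTHETIC stand-in for the per-comorbidity ICD-10 code lists.
#
# The code lists used by the validation study live in the supplement of the
# original development publication and are not redistributable here. These
# prefixes are the standard ICD-10 chapter ranges for each condition
# (Charlson-style): anaemia D50-D64; hypertensive disease I10-I15; heart
# failure I50; acute myocardial infarction I21-I22; chronic ischaemic heart
# disease I25; diabetes with organ involvement E10-E14 with fourth digit 2-7;
# malignant neoplasm C00-C76 and C81-C96; secondary/metastatic and unspecified
# malignancy C77-C80. Matching is prefix-based on uppercased, dot-stripped
# codes. Replace with the published lists before validating the real score.
anaemia:
- D50
- D51
- D52
- D53
- D54
- D55
- D56
- D57
- D58
- D59
- D60
- D61
- D62
- D63
- D64
hypertension:
- I10
- I11
- I12
- I13
- I14
- I15
heart_failure: I50
acute_mi:
- I21
- I22
chronic_ihd: I25
diabetes_organ:
- E102
- E112
- E122
- E132
- E142
- E103
- E113
- E123
- E133
- E143
- E104
- E114
- E124
- E134
- E144
- E105
- E115
- E125
- E135
- E145
- E106
- E116
- E126
- E136
- E146
- E107
- E117
- E127
- E137
- E147
cancer:
- C00
- C01
- C02
- C03
- C04
- C05
- C06
- C07
- C08
- C09
- C10
- C11
- C12
- C13
- C14
- C15
- C16
- C17
- C18
- C19
- C20
- C21
- C22
- C23
- C24
- C25
- C26
- C27
- C28
- C29
- C30
- C31
- C32
- C33
- C34
- C35
- C36
- C37
- C38
- C39
- C40
- C41
- C42
- C43
- C44
- C45
- C46
- C47
- C48
- C49
- C50
- C51
- C52
- C53
- C54
- C55
- C56
- C57
- C58
- C59
- C60
- C61
- C62
- C63
- C64
- C65
- C66
- C67
- C68
- C69
- C70
- C71
- C72
- C73
- C74
- C75
- C76
- C81
- C82
- C83
- C84
- C85
- C86
- C87
- C88
- C89
- C90
- C91
- C92
- C93
- C94
- C95
- C96
metastatic_ca:
- C77
- C78
- C79
- C80

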