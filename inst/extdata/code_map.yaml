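fracture_sites:
  clinical_vertebral:
  - S12
  - S22.0
  - S22.1
  - S32.0
  - M80
  hip:
  - S72.0
  - S72.1
  - S72.2
  wrist_forearm: S52
  humerus:
  - S42.2
  - S42.3
  - S42.4
  clavicle: S42.0
  pelvis:
  - S32.1
  - S32.3
  - S32.4
  - S32.5
  - S32.8
  femur:
  - S72.3
  - S72.4
  - S72.8
  - S72.9
exclusions:
  cancer: C
  paget: M88
  osteogenesis_imperfecta: Q78.0
fracture_procedures:
- 5-78
- 5-79
- 5-82
- 8-200
hysterectomy_procedures: 5-683
drug_classes:
- denosumab
- iv_ibandronate
- iv_zoledronate
- oral_bisphosphonate
- teriparatide
- raloxifene
- hrt
hierarchy:
- denosumab
- - iv_ibandronate
  - iv_zoledronate
- oral_bisphosphonate
- teriparatide
- raloxifene
- hrt
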