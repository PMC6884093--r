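# Reference configuration: frozen clusters, negative-APR polarity map,
# PPMS + SPMS merged into PMS, covariate selection and FDR at alpha 0.05.
panel:
  - {analyte: serum_albumin, compartment: blood, polarity: negative, units: g/dL}
  - {analyte: ceruloplasmin, compartment: blood, polarity: positive, units: mg/dL}
  - {analyte: wbc, compartment: blood, polarity: positive, units: cells/uL}
  - {analyte: crp, compartment: blood, polarity: positive, units: mg/L}
  - {analyte: esr, compartment: blood, polarity: positive, units: mm/h}
  - {analyte: iron, compartment: blood, polarity: negative, units: mcg/dL}
  - {analyte: ferritin, compartment: blood, polarity: positive, units: mcg/L}
  - {analyte: transferrin, compartment: blood, polarity: negative, units: mg/dL}
  - {analyte: scd14, compartment: csf, polarity: positive, units: ng/mL}
  - {analyte: scd163, compartment: csf, polarity: positive, units: ng/mL}
  - {analyte: chi3l1, compartment: csf, polarity: positive, units: ng/mL}
  - {analyte: sbcma, compartment: csf, polarity: positive, units: pg/mL}
  - {analyte: scd27, compartment: csf, polarity: positive, units: U/mL}
  - {analyte: csf_albumin, compartment: csf, polarity: positive, units: mg/dL}
  - {analyte: csf_igg, compartment: csf, polarity: positive, units: mg/dL}
  - {analyte: igg_index, compartment: csf, polarity: positive, units: ratio}
grouping:
  HD: HD
  RRMS: RRMS
  PPMS: PMS
  SPMS: PMS
covariates: [age, sex, race]
selection_alpha: 0.05
lambda_grid: {from: -3, to: 3, by: 0.01}
cluster_mode: frozen
r_threshold: 0.3
subcohorts:
  MS: [RRMS, PMS]
  RRMS: [RRMS]
  PMS: [PMS]
icc_flag: 0.8
alpha: 0.05
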