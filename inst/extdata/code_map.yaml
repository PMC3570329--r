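# Drug code map: raw dispensing codes -> product / drug class, with optional
# comorbidity marker and chronic-disease-score class. Matches the codes the
# synthetic generator emits; replace for real claims extracts.
codes:
  ASA-400: {product: ASACOL_OR_GENERIC, drug_class: FIVE_ASA}
  PEN-500: {product: PENTASA, drug_class: FIVE_ASA}
  SAL-500: {product: SALOFALK, drug_class: FIVE_ASA}
  MEZ-1200: {product: MEZAVANT, drug_class: FIVE_ASA}
  COR-PRED: {drug_class: CORTICOSTEROID, cds_class: corticosteroid}
  MRK-HTN: {drug_class: COMORBIDITY_MARKER, comorbidity: hypertension,
            cds_class: hypertension}
  MRK-CARD: {drug_class: COMORBIDITY_MARKER, comorbidity: heart_disease,
             cds_class: heart_disease}
  MRK-RESP: {drug_class: COMORBIDITY_MARKER, comorbidity: respiratory_illness,
             cds_class: respiratory_illness}
  MRK-DIAB: {drug_class: COMORBIDITY_MARKER, comorbidity: diabetes,
             cds_class: diabetes}
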