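# SYNTHETIC placeholder code registry.
#
# Real claims studies resolve each treatment/test concept to curated lists of
# GPI, HCPCS, CPT and ICD procedure codes maintained by the study team; those
# dictionaries are proprietary and are NOT shipped here. Every code below is a
# synthetic stand-in (prefix "SYN") so the pipeline, the synthetic-claims
# generator and all tests can run at concept level. Replace this file with
# your own concept -> code mapping for use against real claims.
#
# Schema: <concept>: list of {system: one of GPI|HCPCS|CPT|ICD9_PROC|
# ICD10_PROC|ICD9_DX|ICD10_DX, code: string}.

cisplatin:
  - {system: GPI, code: "SYN-GPI-2110-CIS"}
  - {system: HCPCS, code: "SYN-J-CIS"}
carboplatin:
  - {system: GPI, code: "SYN-GPI-2110-CAR"}
  - {system: HCPCS, code: "SYN-J-CAR"}
etoposide:
  - {system: GPI, code: "SYN-GPI-2130-ETO"}
  - {system: HCPCS, code: "SYN-J-ETO"}
irinotecan:
  - {system: GPI, code: "SYN-GPI-2140-IRI"}
  - {system: HCPCS, code: "SYN-J-IRI"}
topotecan:
  - {system: GPI, code: "SYN-GPI-2140-TOP"}
  - {system: HCPCS, code: "SYN-J-TOP"}
cyclophosphamide:
  - {system: GPI, code: "SYN-GPI-2105-CYC"}
  - {system: HCPCS, code: "SYN-J-CYC"}
doxorubicin:
  - {system: GPI, code: "SYN-GPI-2120-DOX"}
  - {system: HCPCS, code: "SYN-J-DOX"}
vincristine:
  - {system: GPI, code: "SYN-GPI-2150-VCR"}
  - {system: HCPCS, code: "SYN-J-VCR"}
temozolomide:
  - {system: GPI, code: "SYN-GPI-2105-TMZ"}
ifosfamide:
  - {system: GPI, code: "SYN-GPI-2105-IFO"}
  - {system: HCPCS, code: "SYN-J-IFO"}
bendamustine:
  - {system: GPI, code: "SYN-GPI-2105-BEN"}
  - {system: HCPCS, code: "SYN-J-BEN"}
paclitaxel:
  - {system: GPI, code: "SYN-GPI-2160-PAC"}
  - {system: HCPCS, code: "SYN-J-PAC"}
nab_paclitaxel:
  - {system: GPI, code: "SYN-GPI-2160-NAB"}
  - {system: HCPCS, code: "SYN-J-NAB"}
docetaxel:
  - {system: GPI, code: "SYN-GPI-2160-DOC"}
  - {system: HCPCS, code: "SYN-J-DOC"}
gemcitabine:
  - {system: GPI, code: "SYN-GPI-2115-GEM"}
  - {system: HCPCS, code: "SYN-J-GEM"}
vinorelbine:
  - {system: GPI, code: "SYN-GPI-2150-VNR"}
  - {system: HCPCS, code: "SYN-J-VNR"}
vinblastine:
  - {system: GPI, code: "SYN-GPI-2150-VBL"}
  - {system: HCPCS, code: "SYN-J-VBL"}
pemetrexed:
  - {system: GPI, code: "SYN-GPI-2115-PEM"}
  - {system: HCPCS, code: "SYN-J-PEM"}
bevacizumab:
  - {system: GPI, code: "SYN-GPI-2170-BEV"}
  - {system: HCPCS, code: "SYN-J-BEV"}
erlotinib:
  - {system: GPI, code: "SYN-GPI-2180-ERL"}
afatinib:
  - {system: GPI, code: "SYN-GPI-2180-AFA"}
gefitinib:
  - {system: GPI, code: "SYN-GPI-2180-GEF"}
osimertinib:
  - {system: GPI, code: "SYN-GPI-2180-OSI"}
crizotinib:
  - {system: GPI, code: "SYN-GPI-2185-CRI"}
alectinib:
  - {system: GPI, code: "SYN-GPI-2185-ALE"}
ceritinib:
  - {system: GPI, code: "SYN-GPI-2185-CER"}
pet_scan:
  - {system: CPT, code: "SYN-CPT-PET-1"}
  - {system: CPT, code: "SYN-CPT-PET-2"}
  - {system: HCPCS, code: "SYN-G-PET"}
lung_resection:
  - {system: CPT, code: "SYN-CPT-LOBECT"}
  - {system: CPT, code: "SYN-CPT-PNEUMON"}
  - {system: ICD10_PROC, code: "SYN-0BT-RESECT"}
  - {system: ICD9_PROC, code: "SYN-32-RESECT"}
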