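# NSCLC Case-Finding Algorithm: first-line treatment and test criteria.
# SCLC-indicative chemotherapy regimens veto an NSCLC label (exclusion_first
# policy); NSCLC-indicative tests and first-line regimens rule a patient in.
# Combination regimens are recognised when every component drug appears
# within combo_window_days of a common anchor date (one chemotherapy cycle).
name: nsclc_case_finding
policy: exclusion_first
default_label: SCLC
eval_window: [90, 90]
criteria:
  # ---- small cell lung cancer exclusion criteria ----
  - {name: "Cisplatin and etoposide", role: SCLC_exclusion, components: [cisplatin, etoposide], combo_window_days: 21}
  - {name: "Cisplatin and irinotecan", role: SCLC_exclusion, components: [cisplatin, irinotecan], combo_window_days: 21}
  - {name: "Carboplatin and etoposide", role: SCLC_exclusion, components: [carboplatin, etoposide], combo_window_days: 21}
  - {name: "Topotecan", role: SCLC_exclusion, components: [topotecan]}
  - {name: "Cyclophosphamide, doxorubicin, and vincristine", role: SCLC_exclusion, components: [cyclophosphamide, doxorubicin, vincristine], combo_window_days: 21}
  - {name: "Carboplatin and irinotecan", role: SCLC_exclusion, components: [carboplatin, irinotecan], combo_window_days: 21}
  - {name: "Temozolomide", role: SCLC_exclusion, components: [temozolomide]}
  - {name: "Ifosfamide", role: SCLC_exclusion, components: [ifosfamide]}
  - {name: "Bendamustine", role: SCLC_exclusion, components: [bendamustine]}
  # ---- non-small cell lung cancer inclusion criteria ----
  - {name: "PET scan imaging", role: NSCLC_inclusion, components: [pet_scan]}
  - {name: "Lung removal or resection surgery", role: NSCLC_inclusion, components: [lung_resection]}
  - {name: "Carboplatin and paclitaxel", role: NSCLC_inclusion, components: [carboplatin, paclitaxel], combo_window_days: 21}
  - {name: "Carboplatin and gemcitabine", role: NSCLC_inclusion, components: [carboplatin, gemcitabine], combo_window_days: 21}
  - {name: "Carboplatin and vinorelbine", role: NSCLC_inclusion, components: [carboplatin, vinorelbine], combo_window_days: 21}
  - {name: "Cisplatin and gemcitabine", role: NSCLC_inclusion, components: [cisplatin, gemcitabine], combo_window_days: 21}
  - {name: "Cisplatin and vinorelbine", role: NSCLC_inclusion, components: [cisplatin, vinorelbine], combo_window_days: 21}
  - {name: "Gemcitabine and vinorelbine", role: NSCLC_inclusion, components: [gemcitabine, vinorelbine], combo_window_days: 21}
  - {name: "Erlotinib", role: NSCLC_inclusion, components: [erlotinib]}
  - {name: "Cisplatin and docetaxel", role: NSCLC_inclusion, components: [cisplatin, docetaxel], combo_window_days: 21}
  - {name: "Cisplatin and pemetrexed", role: NSCLC_inclusion, components: [cisplatin, pemetrexed], combo_window_days: 21}
  - {name: "Cisplatin and paclitaxel", role: NSCLC_inclusion, components: [cisplatin, paclitaxel], combo_window_days: 21}
  - {name: "Cisplatin and vinblastine", role: NSCLC_inclusion, components: [cisplatin, vinblastine], combo_window_days: 21}
  - {name: "Carboplatin and pemetrexed", role: NSCLC_inclusion, components: [carboplatin, pemetrexed], combo_window_days: 21}
  - {name: "Carboplatin and docetaxel", role: NSCLC_inclusion, components: [carboplatin, docetaxel], combo_window_days: 21}
  - {name: "Gemcitabine and docetaxel", role: NSCLC_inclusion, components: [gemcitabine, docetaxel], combo_window_days: 21}
  - {name: "Bevacizumab, carboplatin, and paclitaxel", role: NSCLC_inclusion, components: [bevacizumab, carboplatin, paclitaxel], combo_window_days: 21}
  - {name: "Bevacizumab, carboplatin, and pemetrexed", role: NSCLC_inclusion, components: [bevacizumab, carboplatin, pemetrexed], combo_window_days: 21}
  - {name: "Bevacizumab, cisplatin, and pemetrexed", role: NSCLC_inclusion, components: [bevacizumab, cisplatin, pemetrexed], combo_window_days: 21}
  - {name: "Afatinib", role: NSCLC_inclusion, components: [afatinib]}
  - {name: "Gefitinib", role: NSCLC_inclusion, components: [gefitinib]}
  - {name: "Osimertinib", role: NSCLC_inclusion, components: [osimertinib]}
  - {name: "Crizotinib", role: NSCLC_inclusion, components: [crizotinib]}
  - {name: "Alectinib", role: NSCLC_inclusion, components: [alectinib]}
  - {name: "Ceritinib", role: NSCLC_inclusion, components: [ceritinib]}
  - {name: "Abraxane (nab-paclitaxel)", role: NSCLC_inclusion, components: [nab_paclitaxel]}
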