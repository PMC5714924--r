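# Control algorithm: the combined guideline list of first-line lung-cancer
# treatments and tests (NSCLC and SCLC alike) used purely as inclusion
# criteria, with no exclusions. By construction it cannot separate the two
# subtypes; it exists as a comparison baseline for the case-finding rule.
name: control
policy: inclusion_only
default_label: SCLC
eval_window: [90, 90]
criteria:
  - {name: "Cisplatin and etoposide", role: NSCLC_inclusion, components: [cisplatin, etoposide], combo_window_days: 21}
  - {name: "Cisplatin and irinotecan", role: NSCLC_inclusion, components: [cisplatin, irinotecan], combo_window_days: 21}
  - {name: "Carboplatin and etoposide", role: NSCLC_inclusion, components: [carboplatin, etoposide], combo_window_days: 21}
  - {name: "Topotecan", role: NSCLC_inclusion, components: [topotecan]}
  - {name: "Cyclophosphamide, doxorubicin, and vincristine", role: NSCLC_inclusion, components: [cyclophosphamide, doxorubicin, vincristine], combo_window_days: 21}
  - {name: "Carboplatin and irinotecan", role: NSCLC_inclusion, components: [carboplatin, irinotecan], combo_window_days: 21}
  - {name: "Temozolomide", role: NSCLC_inclusion, components: [temozolomide]}
  - {name: "Ifosfamide", role: NSCLC_inclusion, components: [ifosfamide]}
  - {name: "Bendamustine", role: NSCLC_inclusion, components: [bendamustine]}
  - {name: "PET scan imaging", role: NSCLC_inclusion, components: [pet_scan]}
  - {name: "Lung removal or resection surgery", role: NSCLC_inclusion, components: [lung_resection]}
  - {name: "Carboplatin and paclitaxel", role: NSCLC_inclusion, components: [carboplatin, paclitaxel], combo_window_days: 21}
  - {name: "Carboplatin and gemcitabine", role: NSCLC_inclusion, components: [carboplatin, gemcitabine], combo_window_days: 21}
  - {name: "Carboplatin and vinorelbine", role: NSCLC_inclusion, components: [carboplatin, vinorelbine], combo_window_days: 21}
  - {name: "Cisplatin and gemcitabine", role: NSCLC_inclusion, components: [cisplatin, gemcitabine], combo_window_days: 21}
  - {name: "Cisplatin and vinorelbine", role: NSCLC_inclusion, components: [cisplatin, vinorelbine], combo_window_days: 21}
  - {name: "Gemcitabine and vinorelbine", role: NSCLC_inclusion, components: [gemcitabine, vinorelbine], combo_window_days: 21}
  - {name: "Paclitaxel", role: NSCLC_inclusion, components: [paclitaxel]}
  - {name: "Docetaxel", role: NSCLC_inclusion, components: [docetaxel]}
  - {name: "Erlotinib", role: NSCLC_inclusion, components: [erlotinib]}
  - {name: "Gemcitabine", role: NSCLC_inclusion, components: [gemcitabine]}
  - {name: "Etoposide", role: NSCLC_inclusion, components: [etoposide]}
  - {name: "Vinorelbine", role: NSCLC_inclusion, components: [vinorelbine]}
  - {name: "Irinotecan", role: NSCLC_inclusion, components: [irinotecan]}
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
  - {name: "Pemetrexed", role: NSCLC_inclusion, components: [pemetrexed]}
  - {name: "Abraxane (nab-paclitaxel)", role: NSCLC_inclusion, components: [nab_paclitaxel]}
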