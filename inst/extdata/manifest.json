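{
  "table2_national.csv": {
    "origin": "Published Table 2: actual and predicted national health outcomes, Sri Lanka 1982-2002",
    "notes": "Rows per indicator-year; counterfactual columns under 5-yr and 10-yr pre-war trends; trend columns printed on the 1982 rows"
  },
  "table3_imr_districts.csv": {
    "origin": "Published Table 3: actual and counterfactual IMR at the district level, 1982-2002",
    "notes": "'n/a' preserved verbatim; Colombo conflict-period rate printed blank; Gampaha has a conflict rate but no pre-war trend"
  },
  "table4_imr_labels.csv": {
    "origin": "Published Table 4: severity of conflict impact on IMR, summary labels",
    "notes": "Label column is the printed 'Summary of Conflict Induced Outcome'"
  },
  "table5_mmr_districts.csv": {
    "origin": "Published Table 5: actual and counterfactual MMR at the district level, 1982-2002",
    "notes": "endpoint_1999 marks rows footnoted 'Data from 1999 used as endpoint'; 'Kilinochi' spelling preserved as printed"
  },
  "table6_mmr_labels.csv": {
    "origin": "Published Table 6: severity of conflict impact on MMR, summary labels",
    "notes": "Label column is the printed 'Conflict Induced MMR'; endpoint_1999 marks footnoted rows"
  },
  "table9_impact_histogram.csv": {
    "origin": "Published Table 9: impact of conflict on districts (weight histogram)",
    "notes": "Preserved as printed; the published histogram is not recomputable from Tables 4/6"
  },
  "national_series.csv": {
    "origin": "National anchor values from published Tables 1-2 (World Bank IMR; Ministry of Health MMR)",
    "notes": "Long-format input for the national trend examples"
  }
}
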