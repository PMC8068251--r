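{
  "name": "peng_rna_results_variant",
  "kind": "rna",
  "description": "Variant of peng_rna_v1 with the exhaustion signature as a 3-of-6 rule (PDCD1, HAVCR2, LAG3, TIGIT, CTLA4, ENTPD1), matching the narrative definition rather than the 4-of-8 methods definition. Both are shipped; the discrepancy is deliberate and surfaced in provenance.",
  "thresholds": { "q75": 0.0, "mean": 0.05 },
  "aliases": {
    "ENTPD-1": "ENTPD1",
    "PD-1": "PDCD1",
    "PD1": "PDCD1",
    "CD39": "ENTPD1",
    "CD57": "B3GAT1",
    "TIM-3": "HAVCR2",
    "TIM3": "HAVCR2",
    "LAG-3": "LAG3"
  },
  "tcell_gate": {
    "any": [
      { "symbol": "CD3D", "statistic": "q75", "comparator": "positive" },
      { "symbol": "CD3E", "statistic": "q75", "comparator": "positive" },
      { "symbol": "CD3G", "statistic": "q75", "comparator": "positive" }
    ]
  },
  "lineage_order": ["tcell_dn", "tcell_dp", "tcell_cd4", "tcell_cd8"],
  "lineages": {
    "tcell_dn": { "all": [
      { "symbol": "CD8A", "statistic": "q75", "comparator": "negative" },
      { "symbol": "CD8B", "statistic": "q75", "comparator": "negative" },
      { "symbol": "CD4", "statistic": "mean", "comparator": "negative" }
    ] },
    "tcell_dp": { "all": [
      { "symbol": "CD8A", "statistic": "q75", "comparator": "positive" },
      { "symbol": "CD8B", "statistic": "q75", "comparator": "positive" },
      { "symbol": "CD4", "statistic": "mean", "comparator": "positive" }
    ] },
    "tcell_cd4": { "all": [
      { "symbol": "CD4", "statistic": "mean", "comparator": "positive" }
    ] },
    "tcell_cd8": { "all": [
      { "symbol": "CD8A", "statistic": "q75", "comparator": "positive" },
      { "symbol": "CD8B", "statistic": "q75", "comparator": "positive" }
    ] }
  },
  "states": {
    "treg": { "all": [
      { "symbol": "FOXP3", "statistic": "q75", "comparator": "positive" }
    ] },
    "senescent": { "all": [
      { "symbol": "CD27", "statistic": "q75", "comparator": "negative" },
      { "symbol": "CD28", "statistic": "q75", "comparator": "negative" },
      { "symbol": "KLRG1", "statistic": "q75", "comparator": "positive" },
      { "symbol": "B3GAT1", "statistic": "mean", "comparator": "positive" }
    ] },
    "exhausted": {
      "kofn": {
        "genes": ["PDCD1", "HAVCR2", "LAG3", "TIGIT", "CTLA4", "ENTPD-1"],
        "k": 3,
        "statistic": "q75",
        "comparator": "positive"
      },
      "exclude": [
        { "symbol": "TRDC", "statistic": "q75", "comparator": "positive" }
      ]
    }
  }
}
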