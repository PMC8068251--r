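{
  "name": "cytof_protein_v1",
  "kind": "cytof",
  "description": "Marker-threshold annotations for mass-cytometry metaclusters over per-marker 0-1 normalised heatmap values. 'high' means value >= 0.5, 'low' means value <= 0.25 on the normalised scale; both thresholds are configurable because the source heatmaps were annotated by eye.",
  "thresholds": { "high": 0.5, "low": 0.25 },
  "aliases": {
    "PDCD1": "PD-1",
    "HAVCR2": "TIM-3",
    "ENTPD1": "CD39",
    "B3GAT1": "CD57",
    "LAG3": "LAG-3"
  },
  "states": {
    "senescent": { "all": [
      { "symbol": "CD57", "statistic": "heatmap", "comparator": "high" },
      { "symbol": "CD27", "statistic": "heatmap", "comparator": "low" },
      { "symbol": "CD28", "statistic": "heatmap", "comparator": "low" }
    ] },
    "terminally_differentiated": { "all": [
      { "symbol": "CD45RA", "statistic": "heatmap", "comparator": "high" },
      { "symbol": "CD27", "statistic": "heatmap", "comparator": "low" },
      { "symbol": "CD28", "statistic": "heatmap", "comparator": "low" }
    ] },
    "activated": { "all": [
      { "symbol": "4-1BB", "statistic": "heatmap", "comparator": "high" },
      { "symbol": "HLA-DR", "statistic": "heatmap", "comparator": "high" }
    ] },
    "naive": { "all": [
      { "symbol": "CCR7", "statistic": "heatmap", "comparator": "high" },
      { "symbol": "CD45RA", "statistic": "heatmap", "comparator": "high" }
    ] },
    "treg": { "all": [
      { "symbol": "CD4", "statistic": "heatmap", "comparator": "high" },
      { "symbol": "FOXP3", "statistic": "heatmap", "comparator": "high" }
    ] },
    "activated_treg": {
      "requires": "treg",
      "all": [
        { "symbol": "TIGIT", "statistic": "heatmap", "comparator": "high" },
        { "symbol": "ICOS", "statistic": "heatmap", "comparator": "high" },
        { "symbol": "CD39", "statistic": "heatmap", "comparator": "high" }
      ]
    },
    "exhausted_protein": {
      "kofn": {
        "genes": ["PD-1", "TIGIT", "TIM-3", "LAG-3", "CD39"],
        "k": 3,
        "statistic": "heatmap",
        "comparator": "high"
      }
    }
  }
}
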