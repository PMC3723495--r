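{
  "schema_version": 1,
  "name": "resilencing_demo",
  "reference": {
    "name": "promoter_amplicon",
    "length": 600,
    "cpg_density": 0.04,
    "gpc_density": 0.05,
    "tss_offset": 300
  },
  "nucleosome_width": 147,
  "assay": {
    "gpc_methylase_efficiency": 0.97,
    "bisulfite_conversion_rate": 0.995,
    "inappropriate_conversion_rate": 0.002,
    "sequencing_error_rate": 0.001
  },
  "days": [
    {
      "day": 0,
      "classes": { "hypermethylated": 25 },
      "tss_occupied_prob": { "hypermethylated": 1.0 }
    },
    {
      "day": 5,
      "classes": { "demethylated": 10, "hypermethylated": 22 },
      "tss_occupied_prob": { "demethylated": 0.6, "hypermethylated": 1.0 }
    },
    {
      "day": 8,
      "classes": { "demethylated": 16, "hypermethylated": 29 },
      "tss_occupied_prob": { "demethylated": 1.0, "hypermethylated": 1.0 }
    }
  ],
  "expression": {
    "target": "GENE",
    "ref_gene": "REF",
    "calibrator_day": 5,
    "treatment_end_day": 3,
    "base_ct": 25,
    "noise_sd": 0.05,
    "quantities": {
      "0": 0.01, "3": 0.5, "4": 0.8, "5": 1.0,
      "6": 0.9, "7": 0.6, "8": 0.45, "17": 0.175
    }
  },
  "timecourse": {
    "nucleosome_t50": 6,
    "methylation_t50": 11,
    "noise_sd": 4
  }
}
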