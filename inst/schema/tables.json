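{
  "activity_within.tsv": ["pathway_id", "name", "category", "comparison", "n_used", "statistic", "direction", "p_value", "testable"],
  "activity_between.tsv": ["pathway_id", "name", "category", "comparison", "n_used", "statistic", "direction", "p_value", "testable"],
  "glpap.tsv": ["pathway_id", "name", "category"],
  "category_enrichment.tsv": ["category", "p_value"],
  "network_edges.tsv": ["pathway_a", "pathway_b", "weight"],
  "network_nodes.tsv": ["pathway_id", "name", "category", "closeness", "degree", "selected"],
  "hypotheses.tsv": ["hypothesis", "n_seeds", "coefficient", "parametric_p", "empirical_p", "topk_coefficient", "topk_parametric_p"]
}
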