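{
  "package": "fibronet",
  "version": "0.1.0",
  "seed": 1,
  "run_config": {
    "fdr": 0.05,
    "top_fraction": 0.25,
    "resolution": 1,
    "seed": 0,
    "alpha": 0.05,
    "min_present": 2,
    "knn_k": 3
  },
  "sim_config": {
    "n_genes": 30,
    "n_metabolites": 12,
    "n_modules": 3,
    "groups": ["control", "d7", "d14", "d21", "d28"],
    "replicates": 3,
    "gene_module_fraction": 0.6,
    "metabolite_module_fraction": 0.75,
    "loading_sd": 1,
    "nb_dispersion": 0.1,
    "baseline_logmean": 5,
    "baseline_logmean_sd": 1,
    "library_size_range": [0.7, 1.3],
    "metabolite_logmean": 3,
    "metabolite_logmean_sd": 1,
    "metabolite_noise_sd": 0.1,
    "missing_threshold_quantile": 0.1,
    "missing_prob": 0.5,
    "seed": 1
  },
  "outputs": {
    "counts.tsv": "5590c3ea27a3be304a1ba328ae7a5ba2",
    "metabolites.tsv": "bc46bc12be75151422f569b009cffd15",
    "phenotypes.tsv": "880c36721171e48ba95be5041b49ce24",
    "design.tsv": "767e0773ce99960e1a1f26a723afe9e8",
    "gene_modules.tsv": "c44785ce2bd89cb9f024cc35b73a7ef9",
    "de_d7.tsv": "d2aee9663680db3fc003df76e3f61d9d",
    "de_d14.tsv": "f0d9df1c6826770167aa19c4fd85f1d2",
    "de_d21.tsv": "beb6ed76f6d82a585104ca6bc41cb793",
    "de_d28.tsv": "a4cb22226a841ac486760430daf254fc",
    "deg0.tsv": "dbb8fc038511b1cc0911aa7cda15bf12",
    "deg1.tsv": "968790ccce61b6700eb9a05381610e72",
    "dm_d7.tsv": "36d8cf54f8bcfee38936387270ea6da1",
    "dm_d14.tsv": "b6c430b25947bd674ad9f69bcb82a236",
    "dm_d21.tsv": "f6fbe1201a94ebe091c7536bdcd4ed93",
    "dm_d28.tsv": "4c6e955022be5eb3662608146eb36e54",
    "gcn_edges.tsv": "b629a95ce2efbfafbd22e615565f1e07",
    "gcn_nodes.tsv": "33750337e278f462d4a315c4b5749a09",
    "mcn_edges.tsv": "d50d5c590e211053c981837f550023b5",
    "mcn_nodes.tsv": "2015f86897cb3b821ecba41fb7906a3b",
    "bridges.tsv": "9c6806e8c6a56ea1ed780cfe51fee0dc",
    "validated_genes.tsv": "cab416eea617882367d4d2b2639765ab",
    "reversal.tsv": "d891d6720edcf3aa6985aac0c4e47cc5"
  },
  "timings": {
    "simulate": 0.003,
    "differential_genes": 0.006,
    "differential_metabolites": 0.011,
    "gcn": 0.146,
    "mcn": 0.004,
    "integrate": 0.031,
    "crossspecies": 0.003,
    "reversal": 0.007
  }
}
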