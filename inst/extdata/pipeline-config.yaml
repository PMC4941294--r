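# Bundled synthetic-study pipeline configuration.
# outdir is supplied by the caller (e.g. `config$outdir <- "my-run"`)
# or defaults to ./lncsig-run.
seed: 1
probe_identity: 0.90
set_fraction: 0.90
annotation_mode: probe_fraction
de_method: moderated
alpha: 0.01
k_top: 100
n_perm: 200
gsea_scheme: phenotype
simulate:
  n_coding: 150
  n_lnc: 150
  n_probesets: 80
  n_de: 20
  coexpr_module_size: 20
  surv_n: 150
  n_gene_sets: 10
  dataset_sizes:
    - [50, 50]
    - [50, 50]
    - [25, 25]
    - [25, 25]
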