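seed: 1
output_dir: panfelis_out
synthetic: yes
n_genes: 978
paths: []
stages:
  landscape: yes
  signatures: yes
  cna: yes
  burden: yes
  drivers: yes
  cross_species: yes
  actionability: yes
  germline: yes
  viral: yes
parameters:
  gain_threshold: 0.32
  loss_threshold: -0.4
  focal_max_mb: 10.0
  bin_size: 1000000.0
  coverage_min: 0.8
  hotspot_min_tumors: 2
  hotspot_tolerance: 1
  q_max: 0.1
  top_k: 5
  uv_signature: SYN_UV
  min_fraction: 0.2
  min_snvs: 20
  viral_k: 31
  read_min_containment: 0.6
  sample_min_reads: 5
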