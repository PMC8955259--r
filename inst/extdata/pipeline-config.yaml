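# reefwater pipeline configuration template.
# Every field is optional; omitted fields take the package defaults.

# one global seed; each stage derives its own seed from it
seed: 1
output_dir: reefwater_run

# Synthetic mode (default): communities generated under the simulator.
# Replace this block with an `input:` block (below) to analyse real data.
synthetic:
  n_tips: 100              # OTUs / tree tips
  birth_rate: 1.0          # Yule speciation rate
  trait_sigma2: 1.0        # Brownian rate of the niche-optimum trait
  n_stations: 3
  n_layers: 2
  replicates_per_cell: 6
  env_values: [-2.0, 0.0, 2.0]   # station gradient (nitrite proxy)
  filtering_strength: 5.0  # 0 = neutral assembly
  niche_breadth: 1.0
  sequencing_depth: 2000
  metacommunity_shape: 1.0 # lognormal sigma of metacommunity abundances
  cfix_fraction: 0.1       # fraction of tips labelled carbon fixers
  n_cfix_clusters: 4
  layer_effect: 0.5        # bottom-layer environmental offset
  seed: 1

# Real-data mode: uncomment and point at your files.
# input:
#   otu_table: data/otu_table.tsv      # rows = OTUs, cols = samples
#   tree: data/tree.nwk                # rooted, branch lengths, tips = OTU ids
#   metadata: data/metadata.tsv        # sample_id, station, layer, variables
#   cbbl_table: data/cbbl_table.tsv    # optional carbon-fixer OTU table
#   cluster_map: data/cluster_map.tsv  # optional otu_id -> cluster map

ordination:
  k: 2
  n_restarts: 20

tests:
  n_permutations: 999

forward:
  alpha: 0.05
  n_permutations: 199

keytaxa:
  top_k: 30
  n_trees: 1000

network:
  fdr: 0.05
  n_iter: 1000
  min_support: 2
  p_method: empirical      # or gaussian

assembly:
  n_null: 999
  group_by: station_layer  # or station / layer
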