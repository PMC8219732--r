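# Optional real-connectome validation data

The integration tests in `tests/testthat/test-connectome-integration.R`
validate motif counts against three public connectomes. The datasets are not
redistributed with this package and the tests skip themselves unless the
data are present locally.

## Setup

Create a directory, export its path, and place one edgelist CSV per dataset
in it (columns `source,target`, one row per directed chemical synapse /
connection; optional `<name>_nodes.csv` sidecars add node attributes):

```sh
export MOTIFQUERY_CONNECTOME_DIR=/path/to/connectomes
ls $MOTIFQUERY_CONNECTOME_DIR
# celegans.csv  microns.csv  hemibrain.csv  hemibrain_nodes.csv
```

## Fetch instructions

* `celegans.csv` — C. elegans chemical-synapse connectome: download the
  July 2020 hermaphrodite adjacency matrices from <https://wormwiring.org>,
  keep chemical synapses only, and export the directed edge list
  (296 nodes / 3427 edges).
* `microns.csv` — MICrONS v185 proofread soma subgraph: download from
  <https://microns-explorer.org> (334 nodes / 1736 edges) and export the
  directed soma-to-soma edge list.
* `hemibrain.csv` — Hemibrain v1.2: export the neuron-to-neuron connection
  table via the neuPrint API at <https://neuprint.janelia.org>
  (21,740 nodes / 3,550,404 edges). The sidecar `hemibrain_nodes.csv`
  must provide `name,type` with neuPrint cell types (used to select mALT
  and Kenyon-cell neurons); edge weights go in a `weight` column.

## What the tests check

* MICrONS v185, direction ignored: 6894 unique triangle monomorphisms
  (atlas id 7) and 123,264 unique 4-cycle monomorphisms (atlas id 16),
  one representative per automorphism class.
* Hemibrain v1.2: seven instances of the antennal-lobe-tract to
  Kenyon-cell motif (`inst/extdata/motifs/malt_kc.motif`).

These counts are far beyond desk scale for the in-repo test suite (the
Hemibrain graph alone has 3.5 million edges), which is why they are wired
as optional integration tests rather than CI assertions.
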