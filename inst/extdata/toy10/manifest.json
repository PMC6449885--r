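{
  "seed": {},
  "config": {
    "name": "toy10"
  },
  "files": {
    "associations.tsv": "6c1ad3c8a8e792643cbee68409fe0fd4",
    "mirna_targets.tsv": "beaffe436ff2384cde230cac0197d56e",
    "disease_genes.tsv": "4f35c0723de31b8f32d5f0553da408c3",
    "family.tsv": "e05017e8743bba087707b279fd764da1",
    "mesh.tsv": "d19b5df80464cbcbfa19ca1b63596c3c",
    "coordinates.gff3": "6d437d85cdbba8aa63d31d8ba4078c41"
  }
}
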