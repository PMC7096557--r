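{
  "module_membership": {
    "g031": "mod_a",
    "g032": "mod_a",
    "g033": "mod_a",
    "g034": "mod_a",
    "g035": "mod_a",
    "g036": "mod_a",
    "g037": "mod_a",
    "g038": "mod_a",
    "g039": "mod_a",
    "g040": "mod_a",
    "g041": "mod_a",
    "g042": "mod_a",
    "g043": "mod_a",
    "g044": "mod_a",
    "g045": "mod_a"
  },
  "modules": [
    {
      "module_id": "mod_a",
      "genes": ["g031", "g032", "g033", "g034", "g035", "g036", "g037", "g038", "g039", "g040", "g041", "g042", "g043", "g044", "g045"],
      "active_in": "A",
      "latent_strength": 0.8
    }
  ],
  "marker_genes": {
    "A": {
      "genes": ["g001", "g002", "g003", "g004", "g005", "g006"],
      "fold_up": 8
    },
    "B": {
      "genes": ["g007", "g008", "g009", "g010", "g011", "g012"],
      "fold_up": 8
    },
    "C": {
      "genes": ["g013", "g014", "g015", "g016", "g017", "g018"],
      "fold_up": 8
    }
  },
  "disease_genes": ["g031", "g032", "g033", "g034", "g035", "g036", "g037", "g038", "g039", "g040", "g071", "g072", "g073", "g074", "g075", "g076"],
  "batch": {
    "n00001": "b1",
    "n00002": "b2",
    "n00003": "b2",
    "n00004": "b1",
    "n00005": "b2",
    "n00006": "b2",
    "n00007": "b1",
    "n00008": "b1",
    "n00009": "b2",
    "n00010": "b1",
    "n00011": "b2",
    "n00012": "b1",
    "n00013": "b2",
    "n00014": "b2",
    "n00015": "b1",
    "n00016": "b2",
    "n00017": "b1",
    "n00018": "b2",
    "n00019": "b2",
    "n00020": "b2",
    "n00021": "b2",
    "n00022": "b2",
    "n00023": "b2",
    "n00024": "b1",
    "n00025": "b2",
    "n00026": "b2",
    "n00027": "b2",
    "n00028": "b1",
    "n00029": "b2",
    "n00030": "b2",
    "n00031": "b1",
    "n00032": "b2",
    "n00033": "b2",
    "n00034": "b2",
    "n00035": "b2",
    "n00036": "b2",
    "n00037": "b1",
    "n00038": "b1",
    "n00039": "b2",
    "n00040": "b2",
    "n00041": "b2",
    "n00042": "b2",
    "n00043": "b1",
    "n00044": "b2",
    "n00045": "b1",
    "n00046": "b1",
    "n00047": "b2",
    "n00048": "b2",
    "n00049": "b2",
    "n00050": "b2",
    "n00051": "b2",
    "n00052": "b1",
    "n00053": "b2",
    "n00054": "b1",
    "n00055": "b2",
    "n00056": "b1",
    "n00057": "b2",
    "n00058": "b2",
    "n00059": "b1",
    "n00060": "b2",
    "n00061": "b1",
    "n00062": "b1",
    "n00063": "b1",
    "n00064": "b1",
    "n00065": "b2",
    "n00066": "b2",
    "n00067": "b2",
    "n00068": "b2",
    "n00069": "b1",
    "n00070": "b1"
  },
  "cell_class": {
    "n00001": "A",
    "n00002": "A",
    "n00003": "A",
    "n00004": "A",
    "n00005": "A",
    "n00006": "A",
    "n00007": "A",
    "n00008": "A",
    "n00009": "A",
    "n00010": "A",
    "n00011": "A",
    "n00012": "A",
    "n00013": "A",
    "n00014": "A",
    "n00015": "A",
    "n00016": "A",
    "n00017": "A",
    "n00018": "A",
    "n00019": "A",
    "n00020": "A",
    "n00021": "A",
    "n00022": "A",
    "n00023": "A",
    "n00024": "A",
    "n00025": "A",
    "n00026": "A",
    "n00027": "A",
    "n00028": "A",
    "n00029": "A",
    "n00030": "A",
    "n00031": "B",
    "n00032": "B",
    "n00033": "B",
    "n00034": "B",
    "n00035": "B",
    "n00036": "B",
    "n00037": "B",
    "n00038": "B",
    "n00039": "B",
    "n00040": "B",
    "n00041": "B",
    "n00042": "B",
    "n00043": "B",
    "n00044": "B",
    "n00045": "B",
    "n00046": "B",
    "n00047": "B",
    "n00048": "B",
    "n00049": "B",
    "n00050": "B",
    "n00051": "B",
    "n00052": "B",
    "n00053": "B",
    "n00054": "B",
    "n00055": "C",
    "n00056": "C",
    "n00057": "C",
    "n00058": "C",
    "n00059": "C",
    "n00060": "C",
    "n00061": "C",
    "n00062": "C",
    "n00063": "C",
    "n00064": "C",
    "n00065": "C",
    "n00066": "C",
    "n00067": "C",
    "n00068": "C",
    "n00069": "C",
    "n00070": "C"
  },
  "seed": 42
}
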