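{
  "schema_version": 1,
  "panel_marker_count": 23,
  "loci": [
    {"name": "D1S1656", "is_str": true, "period": 4, "motif": "TAGA",
     "blocks": [{"motif": "TAGA", "counted": true}]},
    {"name": "TPOX", "is_str": true, "period": 4, "motif": "AATG",
     "blocks": [{"motif": "AATG", "counted": true}]},
    {"name": "D2S1338", "is_str": true, "period": 4, "motif": "TGCC",
     "blocks": [{"motif": "TGCC", "counted": true}, {"motif": "TTCC", "counted": true}]},
    {"name": "D2S441", "is_str": true, "period": 4, "motif": "TCTA",
     "blocks": [{"motif": "TCTA", "counted": true}]},
    {"name": "D3S1358", "is_str": true, "period": 4, "motif": "TCTA",
     "blocks": [{"motif": "TCTG", "counted": true}, {"motif": "TCTA", "counted": true}]},
    {"name": "FGA", "is_str": true, "period": 4, "motif": "TTTC",
     "blocks": [{"motif": "TTTC", "counted": true}]},
    {"name": "D5S818", "is_str": true, "period": 4, "motif": "AGAT",
     "blocks": [{"motif": "AGAT", "counted": true}]},
    {"name": "CSF1PO", "is_str": true, "period": 4, "motif": "AGAT",
     "blocks": [{"motif": "AGAT", "counted": true}]},
    {"name": "D7S820", "is_str": true, "period": 4, "motif": "GATA",
     "blocks": [{"motif": "GATA", "counted": true}]},
    {"name": "D8S1179", "is_str": true, "period": 4, "motif": "TCTA",
     "blocks": [{"motif": "TCTA", "counted": true}]},
    {"name": "D10S1248", "is_str": true, "period": 4, "motif": "GGAA",
     "blocks": [{"motif": "GGAA", "counted": true}]},
    {"name": "TH01", "is_str": true, "period": 4, "motif": "AATG",
     "blocks": [{"motif": "AATG", "counted": true}]},
    {"name": "vWA", "is_str": true, "period": 4, "motif": "TCTA",
     "blocks": [{"motif": "TCTA", "counted": true}, {"motif": "TCTG", "counted": true}]},
    {"name": "D12S391", "is_str": true, "period": 4, "motif": "AGAT",
     "blocks": [{"motif": "AGAT", "counted": true}, {"motif": "AGAC", "counted": true}]},
    {"name": "D13S317", "is_str": true, "period": 4, "motif": "TATC",
     "blocks": [{"motif": "TATC", "counted": true}]},
    {"name": "PentaE", "is_str": true, "period": 5, "motif": "AAAGA",
     "blocks": [{"motif": "AAAGA", "counted": true}]},
    {"name": "D16S539", "is_str": true, "period": 4, "motif": "GATA",
     "blocks": [{"motif": "GATA", "counted": true}]},
    {"name": "D18S51", "is_str": true, "period": 4, "motif": "AGAA",
     "blocks": [{"motif": "AGAA", "counted": true}]},
    {"name": "D19S433", "is_str": true, "period": 4, "motif": "AAGG",
     "blocks": [{"motif": "AAGG", "counted": true}, {"motif": "TAGG", "counted": false}, {"motif": "AAGG", "counted": true}]},
    {"name": "D21S11", "is_str": true, "period": 4, "motif": "TCTA",
     "blocks": [{"motif": "TCTA", "counted": true}, {"motif": "TCTG", "counted": true}]},
    {"name": "PentaD", "is_str": true, "period": 5, "motif": "AAAGA",
     "blocks": [{"motif": "AAAGA", "counted": true}]},
    {"name": "D22S1045", "is_str": true, "period": 3, "motif": "ATT",
     "blocks": [{"motif": "ATT", "counted": true}]},
    {"name": "AMEL", "is_str": false, "blocks": []}
  ],
  "variants": [
    {"variant_id": "rs888232687", "locus": "D2S441", "kind": "deletion",
     "region": "3'-flank", "net_length_change": -1,
     "note": "[T/-] deletion of the first base downstream of the repeat block; CE-equivalent 9.3 for a 10-unit repeat"},
    {"variant_id": "rs745607776", "locus": "D19S433", "kind": "deletion",
     "region": "5'-flank", "net_length_change": -2,
     "note": "[CT/-] deletion in the 5' flanking region; CE-equivalent 14.2 for a 15-unit repeat"},
    {"variant_id": "rs1190908807", "locus": "PentaD", "kind": "deletion",
     "region": "5'-flank", "net_length_change": -13,
     "note": "13-nucleotide [AAGAAAGAAAAAA/-] deletion; CE-equivalent 2.2 for a 5-unit repeat"},
    {"variant_id": "rs536566765", "locus": "PentaD", "kind": "deletion",
     "region": "3'-flank", "net_length_change": -1,
     "ce_designation_override": "13.3",
     "note": "[A/-] deletion in the 3' flanking region; observed CE mapping 13.3 for a 14-unit repeat supersedes uniform arithmetic"},
    {"variant_id": "rs147936416", "locus": "D19S433", "kind": "deletion",
     "region": "repeat-boundary", "net_length_change": -2,
     "note": "[TC/-] deletion spanning the border of a counted repeat unit and an uncounted block; yields intermediate X.2 (CE) / X.3 (repeat-count) alleles"},
    {"variant_id": "rs182073376", "locus": "D5S818", "kind": "SNP",
     "region": "5'-flank", "net_length_change": 0,
     "note": "A>G transition 36 nt upstream of the repeat region inside a CE primer binding site; depresses CE heterozygote balance only"},
    {"variant_id": "rs149212737", "locus": "TPOX", "kind": "SNP",
     "region": "3'-flank", "net_length_change": 0,
     "note": "G>T transversion in the flanking region; isometric variant of allele 8"}
  ]
}
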