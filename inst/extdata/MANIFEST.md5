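0d4c67a374c3ef867bdd6a8db2dbefd2  table2.tsv
14ab15a04abff9f3b0c884235bd5ae67  table3.tsv
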