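gene_01	MODULE
gene_02	MODULE
gene_03	MODULE
gene_04	MODULE
gene_05	MODULE
gene_06	MODULE
gene_07	MODULE
gene_08	MODULE
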