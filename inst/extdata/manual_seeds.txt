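# Families forced into the seed set by manual curation: domains that never
# occur alone in any target and therefore cannot be seeded from data, but
# whose ligand binding is established by structural evidence.
Pkinase_Tyr
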