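# Target accessions removed before mapping: protein fragments annotated as
# full-length targets, where the domain that actually binds the ligand is
# missing from the fragment and activities would be mis-assigned.
Q864F1  # N-terminal fragment of pig phosphodiesterase 5: carries the GAF domain but lacks PDEase_I
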