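# Toy splicing-regulatory motif sets bundled for examples and tests.
# Synthetic hexamers, not a published SRE collection: full collections
# (hexamer tables or weight matrices) can be supplied in this same format.
name: toy_ess
class: ESS
applicability: exonic_only
TAGGGA
TTAGGG

name: toy_ese
class: ESE
applicability: exonic_only
GAAGAA
TAAGAA
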