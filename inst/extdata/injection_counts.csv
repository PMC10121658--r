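# Cas9/sgRNA embryo-injection outcomes, one row per biological replicate.
group,injected,hatched,pupae,adult_female,adult_male,feminized_or_deformed
rep1,320,119,110,52,40,20
rep2,187,28,28,11,10,6
rep3,210,45,45,19,19,13
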