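# SYNTHETIC reconstruction of a per-individual mosaic-male phenotype table.
# Only the per-tissue marginal feminization counts are faithful
# (antennae 21/39, maxillary palps 35/39, external genitalia 36/39,
# gonads 33/39); individual-level co-occurrence is arbitrary and malformed
# scores are not reconstructed.
individual_id,group,antennae,maxillary_palps,external_genitalia,gonads
mosaic_01,mosaic,feminized,feminized,feminized,feminized
mosaic_02,mosaic,feminized,feminized,feminized,feminized
mosaic_03,mosaic,feminized,feminized,feminized,feminized
mosaic_04,mosaic,feminized,feminized,feminized,feminized
mosaic_05,mosaic,feminized,feminized,feminized,feminized
mosaic_06,mosaic,feminized,feminized,feminized,feminized
mosaic_07,mosaic,feminized,feminized,feminized,feminized
mosaic_08,mosaic,feminized,feminized,feminized,feminized
mosaic_09,mosaic,feminized,feminized,feminized,feminized
mosaic_10,mosaic,feminized,feminized,feminized,feminized
mosaic_11,mosaic,feminized,feminized,feminized,feminized
mosaic_12,mosaic,feminized,feminized,feminized,feminized
mosaic_13,mosaic,feminized,feminized,feminized,feminized
mosaic_14,mosaic,feminized,feminized,feminized,feminized
mosaic_15,mosaic,feminized,feminized,feminized,feminized
mosaic_16,mosaic,feminized,feminized,feminized,feminized
mosaic_17,mosaic,feminized,feminized,feminized,feminized
mosaic_18,mosaic,feminized,feminized,feminized,feminized
mosaic_19,mosaic,feminized,feminized,feminized,feminized
mosaic_20,mosaic,feminized,feminized,feminized,feminized
mosaic_21,mosaic,feminized,feminized,feminized,feminized
mosaic_22,mosaic,normal,feminized,feminized,feminized
mosaic_23,mosaic,normal,feminized,feminized,feminized
mosaic_24,mosaic,normal,feminized,feminized,feminized
mosaic_25,mosaic,normal,feminized,feminized,feminized
mosaic_26,mosaic,normal,feminized,feminized,feminized
mosaic_27,mosaic,normal,feminized,feminized,feminized
mosaic_28,mosaic,normal,feminized,feminized,feminized
mosaic_29,mosaic,normal,feminized,feminized,feminized
mosaic_30,mosaic,normal,feminized,feminized,feminized
mosaic_31,mosaic,normal,feminized,feminized,feminized
mosaic_32,mosaic,normal,feminized,feminized,feminized
mosaic_33,mosaic,normal,feminized,feminized,feminized
mosaic_34,mosaic,normal,feminized,feminized,normal
mosaic_35,mosaic,normal,feminized,feminized,normal
mosaic_36,mosaic,normal,normal,feminized,normal
mosaic_37,mosaic,normal,normal,normal,normal
mosaic_38,mosaic,normal,normal,normal,normal
mosaic_39,mosaic,normal,normal,normal,normal
control_01,control,normal,normal,normal,normal
control_02,control,normal,normal,normal,normal
control_03,control,normal,normal,normal,normal
control_04,control,normal,normal,normal,normal
control_05,control,normal,normal,normal,normal
control_06,control,normal,normal,normal,normal
control_07,control,normal,normal,normal,normal
control_08,control,normal,normal,normal,normal
control_09,control,normal,normal,normal,normal
control_10,control,normal,normal,normal,normal
control_11,control,normal,normal,normal,normal
control_12,control,normal,normal,normal,normal
control_13,control,normal,normal,normal,normal
control_14,control,normal,normal,normal,normal
control_15,control,normal,normal,normal,normal
control_16,control,normal,normal,normal,normal
control_17,control,normal,normal,normal,normal
control_18,control,normal,normal,normal,normal
control_19,control,normal,normal,normal,normal
control_20,control,normal,normal,normal,normal
control_21,control,normal,normal,normal,normal
control_22,control,normal,normal,normal,normal
control_23,control,normal,normal,normal,normal
control_24,control,normal,normal,normal,normal
control_25,control,normal,normal,normal,normal
control_26,control,normal,normal,normal,normal
control_27,control,normal,normal,normal,normal
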