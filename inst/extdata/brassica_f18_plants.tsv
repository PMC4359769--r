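# Published per-plant kinetic estimates from a petiolar [18F]fluoride
# micro-PET study of three young rapid-cycling Brassica oleracea plants.
# sv: trapping probability per unit time (mean over stem ROIs, with s.d.);
# V: transport velocity from the position vs mean-arrival-time regression.
plant_id	age_days	activity_MBq	admin_duration_s	n_rois	sv_per_s	sv_sd_per_s	V_mm_s
RBo019	20	3.18	240	6	0.000287	0.000220	0.326
RBo021	20	8.53	300	8	0.000191	0.000058	0.566
RBo026	26	9.96	180	5	0.000280	0.000029	0.214
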