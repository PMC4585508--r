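# SYNTHETIC nominal centroids (MNI mm) for 13 canonical language regions.
# These are stand-in coordinates for exercising the multivariate ROI
# machinery on generated data; they are NOT a validated parcellation and
# must not be used for substantive anatomical inference.
label,x,y,z
left_angular_gyrus,-48,-60,30
left_anterior_temporal,-50,10,-20
left_cerebellum,-30,-65,-30
left_inferior_frontal,-48,20,15
left_orbital_inferior_frontal,-45,30,-10
left_middle_frontal,-40,30,25
left_mid_anterior_temporal,-58,-10,-15
left_mid_posterior_temporal,-58,-35,-5
left_posterior_temporal,-55,-50,5
left_superior_frontal,-8,50,35
right_cerebellum,30,-65,-30
right_mid_anterior_temporal,58,-10,-15
right_mid_posterior_temporal,58,-35,-5
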