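# 6-mm sphere ROI centres (MNI mm) at which earlier voxel-based morphometry
# studies reported volumetric differences between autistic individuals with
# and without early language delay. direction gives the originally reported
# direction of the difference (delay_gt = larger with delay).
label,tissue,x,y,z,direction
mid_cingulate,GM,10,1,38,delay_gt
thalamus_basal_ganglia,GM,-18,-8,0,delay_lt
post_cingulate_precuneus,GM,-1,-50,45,delay_lt
stg_inferior_parietal,GM,62,-20,11,delay_gt
internal_capsule,WM,-14,-17,-9,delay_gt
medial_prefrontal_wm,WM,-16,46,21,delay_lt
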