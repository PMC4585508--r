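# Printed total tissue volume summaries (cm^3) for the reference adult
# autism cohort, split by history of early language delay
# (group 1 = with delay, group 2 = without delay).
tissue,n1,m1,sd1,n2,m2,sd2,t_printed,p_printed
GM,38,980,111,42,934,96,1.99,0.05
WM,38,492,72,42,498,54,-0.38,0.71
CSF,38,282,83,42,259,69,1.32,0.19
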