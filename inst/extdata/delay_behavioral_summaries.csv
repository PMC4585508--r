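# Printed behavioral group summaries for the reference adult autism cohort,
# split by history of early language delay (group 1 = with delay, group 2 =
# without delay). Parametric rows carry group means (m) and SDs; rows tested
# with the Mann-Whitney U-test (U non-missing) carry the printed medians and
# interquartile ranges in the m/sd columns. stat_printed/p_printed/d_printed
# are the published test statistic, p-value and effect size. Group splits for
# the reduced-n rows (FAS n=78; NWR, ADOS, Eyes Test n=77) are plausible
# reconstructions consistent with the complete-case subsample (35/41).
measure,n1,m1,sd1,n2,m2,sd2,U,stat_printed,p_printed,d_printed
Age,38,23.2,5.6,42,25.2,5.6,,-1.63,0.11,0.36
FIQ,38,106.7,13.1,42,111.1,15.7,,-1.36,0.18,0.30
PIQ,38,106.1,14.2,42,108.0,16.5,,-0.54,0.59,0.12
VIQ,38,105.6,12.6,42,111.6,15.7,,-1.86,0.07,0.42
FAS,36,33.8,11.8,42,41.3,10.3,,-3.02,0.003,0.68
NWR,36,21.1,4.5,41,21.8,3.9,,-0.65,0.52,0.17
ADIR-S,38,20.7,5.1,42,17.0,4.9,,3.29,0.001,0.74
ADIR-C,38,15.0,4.2,42,13.5,3.7,,1.72,0.09,0.38
ADIR-RRB,38,5.0,4.0,42,5.0,3.0,786,0.91,,0.03
ADOS-SC,36,10.5,5.2,41,8.6,4.0,,1.82,0.07,0.41
ADOS-RRB,36,1.0,2.0,41,1.0,2.0,665,0.43,,0.18
AQ,38,30.1,8.0,42,28.8,9.3,,0.67,0.51,0.15
EQ,38,23.5,13.1,42,25.4,11.7,,-0.69,0.49,0.15
EyesTest,36,21.3,5.6,41,22.8,5.6,,-1.11,0.27,0.27
VIQ-PIQ,38,-0.5,12.9,42,3.6,14.8,,-1.31,0.19,0.29
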