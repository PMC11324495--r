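quantity,numerator,denominator
low_prs_of_cohort,31717,49907
high_prs_of_cohort,18190,49907
psa_positive_low_prs_screening_arm,6721,18805
psa_positive_high_prs_screening_arm,4095,10440
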