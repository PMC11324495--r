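outcome,prs_group,psa_group,n,n_events,person_years_thousands
incidence,overall,overall,29245,3576,319.80
incidence,low,negative,12084,364,140.35
incidence,low,positive,6721,1306,71.25
incidence,high,negative,6345,385,71.90
incidence,high,positive,4095,1521,36.31
mortality,overall,overall,29245,298,521.12
mortality,low,negative,12084,54,216.90
mortality,low,positive,6721,89,118.88
mortality,high,negative,6345,45,113.53
mortality,high,positive,4095,110,71.81
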