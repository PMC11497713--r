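{"trial_name":"TRAILBLAZER-ALZ 2","treatment":"Donanemab","duration_weeks":76,"baseline_mean_cdr_sb":3.68000000621201,"arms":[{"arm_label":"placebo","visit_weeks":[0,12,24,36,52,64,76],"mean_change":[0,0.357751249339329,0.734705737171411,1.1303183429668,1.68337928772834,2.1151821603416,2.55974461689224]},{"arm_label":"active","visit_weeks":[0,12,24,36,52,64,76],"mean_change":[0,0.213249493203698,0.434575391317857,0.662275595086771,0.976853472577737,1.2200801637064,1.46933619996905]}]}
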