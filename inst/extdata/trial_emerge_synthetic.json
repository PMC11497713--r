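{"trial_name":"EMERGE","treatment":"Aducanumab","duration_weeks":78,"baseline_mean_cdr_sb":2.49000000243307,"arms":[{"arm_label":"placebo","visit_weeks":[0,13,26,39,52,65,78],"mean_change":[0,0.215775315552593,0.49780539315374,0.780734955965519,1.04967102805792,1.41401781498134,1.81602060255859]},{"arm_label":"active","visit_weeks":[0,13,26,39,52,65,78],"mean_change":[0,0.167141447905206,0.380623786401105,0.612158896162362,0.832071903462445,1.04773480603212,1.33257441507287]}]}
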