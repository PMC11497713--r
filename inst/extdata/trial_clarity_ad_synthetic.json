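{"trial_name":"CLARITY AD","treatment":"Lecanemab","duration_weeks":79,"baseline_mean_cdr_sb":3.22000000434376,"arms":[{"arm_label":"placebo","visit_weeks":[0,13,26,39,52,65,79],"mean_change":[0,0.264275025715893,0.609327009190742,1.00785060253168,1.42768759823773,1.86790684599042,2.36226585687861]},{"arm_label":"active","visit_weeks":[0,13,26,39,52,65,79],"mean_change":[0,0.181496219883241,0.382243614173345,0.639555698991934,0.914369067652355,1.19905465458049,1.51748599305479]}]}
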