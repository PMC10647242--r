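group,characteristic,count,group_size,printed_percent
training,age_lt_60,70,158,44.3
training,age_gt_60,88,158,55.7
training,female,99,158,62.7
training,smoker,35,158,22.2
training,ecog_0,49,158,31.0
training,ecog_1,91,158,57.6
training,ecog_2,11,158,7.0
training,adenocarcinoma,155,158,98.1
training,n_stage_0,45,158,28.5
training,n_stage_3,59,158,37.3
test,age_lt_60,22,68,32.4
test,age_gt_60,46,68,67.6
test,female,35,68,51.5
test,smoker,23,68,33.8
test,ecog_0,35,68,51.5
test,ecog_1,28,68,41.2
test,adenocarcinoma,65,68,95.6
test,n_stage_0,14,68,20.6
test,n_stage_2,22,68,32.4
test,n_stage_3,25,68,36.8
external,age_gt_60,67,96,69.8
external,female,57,96,59.4
external,smoker,21,96,21.9
external,ecog_0,4,96,4.2
external,ecog_1,65,96,67.7
external,adenocarcinoma,89,96,92.7
external,n_stage_2,36,96,37.5
external,n_stage_3,33,96,34.4
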