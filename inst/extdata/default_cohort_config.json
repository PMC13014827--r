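{"n_total":330,"p_discontinue":0.32424242424242422,"group_mean_counts":{"continuation":{"primary_care":9.0299999999999994,"specialist":1.6699999999999999,"pc_emergency":0.57999999999999996,"hospital_emergency":0.32000000000000001},"discontinuation":{"primary_care":8.1999999999999993,"specialist":1.6299999999999999,"pc_emergency":0.31,"hospital_emergency":0.34000000000000002}},"covariate_marginals":{"sex":{"women":0.6996996996996997,"men":0.3003003003003003},"income_band":{"<=18000":0.70570570570570568,">18000":0.29429429429429427},"cci_band":{"0-2":0.41515151515151516,"3-4":0.38787878787878788,">=5":0.19696969696969696},"minor_mental_disorder":{"no":0.963963963963964,"yes":0.036036036036036036},"indication":{"anxiety":0.25401929260450162,"insomnia":0.60771704180064312,"both":0.093247588424437297,"other":0.045016077170418008}},"age_mean_sd":[66.719999999999999,12.408835561808369],"bzd_duration_mean_sd":[4.04,5.1095205254505052],"wonca_baseline_mean_sd":[18.48,5.1095205254505052],"utility_change_mean_sd_by_group":{"continuation":[0.11,0.5196748214027691],"discontinuation":[0.24440000000000001,0.3806621599266205]},"seed":1,"frailty_sdlog":0,"assignment":{}}
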