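drug,event,ror,ci_low,ci_high,n_reports
CRIZOTINIB,Pleural effusion,7.76,6.60,9.12,150
CRIZOTINIB,Pericardial effusion,9.00,7.10,11.41,69
CERITINIB,Pleural effusion,7.36,5.16,10.50,31
CERITINIB,Pericardial effusion,10.80,6.79,17.19,18
ALECTINIB,Pleural effusion,4.76,3.80,5.97,76
ALECTINIB,Pericardial effusion,6.67,4.92,9.04,42
BRIGATINIB,Pleural effusion,8.70,6.58,11.52,50
BRIGATINIB,Pericardial effusion,7.87,4.95,12.51,18
LORLATINIB,Pleural effusion,8.61,6.72,11.02,64
LORLATINIB,Pericardial effusion,12.57,9.08,17.38,37
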