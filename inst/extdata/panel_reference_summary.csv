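quantity,series,value
mean,personal,16.23
sd,personal,4.87
cv_pct,personal,35.50
mean,s1,24.85
sd,s1,9.16
cv_pct,s1,44.97
mean,s2,27.11
sd,s2,10.35
cv_pct,s2,46.82
mean,s3,13.66
sd,s3,4.45
cv_pct,s3,36.91
rmse,s1,23.87
mae,s1,15.17
rmse,s2,24.98
mae,s2,19.08
rmse,s3,4.79
mae,s3,3.70
participant_mean_max,personal,136.58
participant_mean_min,personal,5.76
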