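month,mean_p
Jan,0.968
Feb,1
Mar,0.994
Apr,0.993
May,0.9613
Jun,0.82
Jul,0.813
Aug,0.806
Sep,0.9
Oct,0.845
Nov,0.827
Dec,0.845
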