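system,source,subgroup,n,r,method,transform,significance
calcium_pth,Jorde,female,486,-0.195,pearson,identity,P<0.01
calcium_pth,Jorde,male,460,-0.120,unspecified,identity,P<0.01
calcium_pth,Minisola,female premenopause,35,-0.353,unspecified,identity,P<0.001
calcium_pth,Minisola,female postmenopause,35,-0.064,unspecified,identity,NS
calcium_pth,Minisola,male,45,-0.661,unspecified,identity,P<0.001
glucose_insulin,Gibson,female,148,0.37,unspecified,log,P<0.001
glucose_insulin,Gibson,male,142,0.06,unspecified,log,NS
glucose_insulin,Peplies,male,3640,0.39,pearson,identity,P<0.001
glucose_insulin,Peplies,female,3434,0.42,pearson,identity,P<0.001
glucose_insulin,Chen,male and female,3247,0.0249,pearson,log,P=0.0001
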