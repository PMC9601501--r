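set,configuration,tp,fp,fn,tn,precision_pct,accuracy_pct,sensitivity_pct,specificity_pct,npv_pct,auc_pct,mse
train,serum_only,64,4,0,48,94.12,96.55,100.00,92.31,100.00,99.55,NA
train,plasma_only,61,8,3,44,88.41,90.52,95.31,84.62,93.62,97.25,NA
train,combined,64,3,0,49,95.52,97.41,100.00,94.23,100.00,99.98,NA
train,combined_rfe,64,2,0,50,96.97,98.28,100.00,96.15,100.00,99.16,NA
test,serum_only,14,3,1,10,82.35,85.71,93.33,76.92,90.91,92.78,0.140
test,plasma_only,12,7,3,6,63.16,64.29,80.00,46.15,66.67,70.91,0.353
test,combined,15,4,0,9,78.95,85.71,100.00,69.23,100.00,93.96,0.149
test,combined_rfe,15,3,0,10,83.33,89.29,100.00,76.92,100.00,95.99,0.105
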