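# Per-image SSIM / PSNR (dB) / DSC values reported for the reference
# evaluation of this model family; used as input to aggregate_report()
# to check the cohort aggregation against the published headline means.
case_id,ssim,psnr,dsc
I1,0.9021,57.30,0.87
I2,0.9110,69.01,0.88
I3,0.8251,59.32,0.93
I4,0.8761,61.21,0.93
I5,0.9121,61.65,0.80
I6,0.8366,60.23,0.94
I7,0.9231,62.16,0.90
I8,0.9081,58.52,0.89
I9,0.8845,62.47,0.91
I10,0.9125,68.97,0.89
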