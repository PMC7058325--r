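# Worked aggregation example: per-fold five-fold cross-validation results
# of a fundus-image hypertension CNN evaluated on an enhanced and a
# vessel-segmented dataset variant. accuracy/specificity/precision/recall
# are percentages; auc is a fraction. Rows with fold = "average" hold the
# published averaged values that aggregateCv() must reproduce.
variant,metric,fold,value
enhanced,accuracy,1,53.35
enhanced,accuracy,2,56.47
enhanced,accuracy,3,57.21
enhanced,accuracy,4,59.31
enhanced,accuracy,5,57.46
enhanced,accuracy,average,56.76
enhanced,specificity,1,51.04
enhanced,specificity,2,56.48
enhanced,specificity,3,76.44
enhanced,specificity,4,80.32
enhanced,specificity,5,54.73
enhanced,specificity,average,63.80
enhanced,precision,1,55.45
enhanced,precision,2,52.76
enhanced,precision,3,59.17
enhanced,precision,4,70.40
enhanced,precision,5,57.08
enhanced,precision,average,58.97
enhanced,recall,1,55.45
enhanced,recall,2,56.45
enhanced,recall,3,36.60
enhanced,recall,4,40.93
enhanced,recall,5,60.20
enhanced,recall,average,49.93
enhanced,auc,1,0.5572
enhanced,auc,2,0.6144
enhanced,auc,3,0.6083
enhanced,auc,4,0.6532
enhanced,auc,5,0.6014
enhanced,auc,average,0.6069
segmented,accuracy,1,58.31
segmented,accuracy,2,60.20
segmented,accuracy,3,63.68
segmented,accuracy,4,59.31
segmented,accuracy,5,63.18
segmented,accuracy,average,60.94
segmented,specificity,1,52.60
segmented,specificity,2,48.61
segmented,specificity,3,54.81
segmented,specificity,4,49.47
segmented,specificity,5,52.23
segmented,specificity,average,51.54
segmented,precision,1,59.56
segmented,precision,2,55.24
segmented,precision,3,60.17
segmented,precision,4,60.58
segmented,precision,5,60.82
segmented,precision,average,59.27
segmented,recall,1,63.51
segmented,recall,2,73.66
segmented,recall,3,73.20
segmented,recall,4,67.91
segmented,recall,5,74.13
segmented,recall,average,70.48
segmented,auc,1,0.5893
segmented,auc,2,0.6634
segmented,auc,3,0.6655
segmented,auc,4,0.6558
segmented,auc,5,0.6789
segmented,auc,average,0.6506
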