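{"grid":{"purity":[0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.15,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.35,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.55,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.75,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9,0.9],"coverage":[20,20,20,20,20,20,20,20,20,20,45,45,45,45,45,45,45,45,45,45,70,70,70,70,70,70,70,70,70,70,95,95,95,95,95,95,95,95,95,95,120,120,120,120,120,120,120,120,120,120,20,20,20,20,20,20,20,20,20,20,45,45,45,45,45,45,45,45,45,45,70,70,70,70,70,70,70,70,70,70,95,95,95,95,95,95,95,95,95,95,120,120,120,120,120,120,120,120,120,120,20,20,20,20,20,20,20,20,20,20,45,45,45,45,45,45,45,45,45,45,70,70,70,70,70,70,70,70,70,70,95,95,95,95,95,95,95,95,95,95,120,120,120,120,120,120,120,120,120,120,20,20,20,20,20,20,20,20,20,20,45,45,45,45,45,45,45,45,45,45,70,70,70,70,70,70,70,70,70,70,95,95,95,95,95,95,95,95,95,95,120,120,120,120,120,120,120,120,120,120,20,20,20,20,20,20,20,20,20,20,45,45,45,45,45,45,45,45,45,45,70,70,70,70,70,70,70,70,70,70,95,95,95,95,95,95,95,95,95,95,120,120,120,120,120,120,120,120,120,120],"epsilon":[0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1,0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1],"pass":[0,8,10,10,10,10,10,10,10,10,1,0,0,2,1,1,2,1,0,0,2,3,6,4,3,6,2,1,0,0,2,4,4,3,1,2,3,1,0,0,0,2,1,2,3,1,1,1,1,1,0,2,1,3,6,3,3,5,8,9,0,2,3,0,5,4,3,3,5,5,0,0,0,1,2,0,2,2,1,2,0,0,0,0,0,0,1,1,1,0,0,0,0,0,0,0,0,1,1,0,1,0,3,4,7,4,9,7,7,5,2,2,4,3,3,3,5,2,1,2,0,0,1,1,0,1,0,2,0,1,0,1,0,0,0,0,2,0,0,1,0,0,0,0,0,0,0,0,0,0,0,2,3,3,6,2,8,5,5,4,3,3,6,2,3,2,2,7,3,3,1,0,1,2,0,3,1,0,3,2,0,0,0,0,2,0,0,1,1,3,2,0,0,2,0,0,0,0,1,2,1,4,5,6,6,6,6,8,8,9,0,1,0,4,5,5,3,3,6,4,1,0,0,2,0,3,1,3,7,9,0,2,0,1,1,0,0,1,5,6,0,0,0,0,0,1,0,3,5,9],"reps":[10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10,10],"fpr":[0,0.8,1,1,1,1,1,1,1,1,0.1,0,0,0.2,0.1,0.1,0.2,0.1,0,0,0.2,0.3,0.6,0.4,0.3,0.6,0.2,0.1,0,0,0.2,0.4,0.4,0.3,0.1,0.2,0.3,0.1,0,0,0,0.2,0.1,0.2,0.3,0.1,0.1,0.1,0.1,0.1,0,0.2,0.1,0.3,0.6,0.3,0.3,0.5,0.8,0.9,0,0.2,0.3,0,0.5,0.4,0.3,0.3,0.5,0.5,0,0,0,0.1,0.2,0,0.2,0.2,0.1,0.2,0,0,0,0,0,0,0.1,0.1,0.1,0,0,0,0,0,0,0,0,0.1,0.1,0,0.1,0,0.3,0.4,0.7,0.4,0.9,0.7,0.7,0.5,0.2,0.2,0.4,0.3,0.3,0.3,0.5,0.2,0.1,0.2,0,0,0.1,0.1,0,0.1,0,0.2,0,0.1,0,0.1,0,0,0,0,0.2,0,0,0.1,0,0,0,0,0,0,0,0,0,0,0,0.2,0.3,0.3,0.6,0.2,0.8,0.5,0.5,0.4,0.3,0.3,0.6,0.2,0.3,0.2,0.2,0.7,0.3,0.3,0.1,0,0.1,0.2,0,0.3,0.1,0,0.3,0.2,0,0,0,0,0.2,0,0,0.1,0.1,0.3,0.2,0,0,0.2,0,0,0,0,0.1,0.2,0.1,0.4,0.5,0.6,0.6,0.6,0.6,0.8,0.8,0.9,0,0.1,0,0.4,0.5,0.5,0.3,0.3,0.6,0.4,0.1,0,0,0.2,0,0.3,0.1,0.3,0.7,0.9,0,0.2,0,0.1,0.1,0,0,0.1,0.5,0.6,0,0,0,0,0,0.1,0,0.3,0.5,0.9]},"purities":[0.15,0.35,0.55,0.75,0.9],"coverages":[20,45,70,95,120],"epsilons":[0.01,0.02,0.03,0.04,0.05,0.06,0.07,0.08,0.09,0.1],"reps":10,"seed":20260101,"n_chrom":4,"mutations_per_mb":3,"version":1}
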