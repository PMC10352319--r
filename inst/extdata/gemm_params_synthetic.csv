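group,theta,theta_se,alpha,mu,upsilon
25-29,0.32,0.0256,1.6,15.5,36.8
30-34,0.3,0.024,1.6,15.5,36.8
35-39,0.28,0.0224,1.6,15.5,36.8
40-44,0.26,0.0208,1.6,15.5,36.8
45-49,0.24,0.0192,1.6,15.5,36.8
50-54,0.22,0.0176,1.6,15.5,36.8
55-59,0.2,0.016,1.6,15.5,36.8
60-64,0.18,0.0144,1.6,15.5,36.8
65-69,0.16,0.0128,1.6,15.5,36.8
70-74,0.14,0.0112,1.6,15.5,36.8
75-79,0.12,0.0096,1.6,15.5,36.8
80+,0.1,0.008,1.6,15.5,36.8
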