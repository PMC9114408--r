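id,text,a,b1,b2,b3,b4,offset
D01,I feel depressed and have difficulty in daily life,3.32,0.93,1.84,2.32,3.33,0
D02,I often feel helpless,1.88,0.09,1.13,2.15,2.86,0
D03,I feel hopeless for the future,2.02,0.09,0.98,1.74,2.55,0
D04,I need help with my depression,2.23,1.60,2.29,3.01,3.73,0
D05,Others don't understand me,1.74,0.75,2.07,2.88,4.33,0
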