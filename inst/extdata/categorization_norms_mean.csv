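stimulus,happiness,surprise,anger,sadness,disgust,fear
happiness,97.6,1.5,0.1,0.0,0.8,0.0
surprise,1.7,95.3,0.2,0.1,0.4,2.3
anger,0.0,0.6,92.7,1.2,3.8,1.7
sadness,0.3,0.1,1.4,75.2,7.7,14.3
disgust,0.1,0.8,10.8,4.9,80.4,3.0
fear,0.5,26.0,0.8,2.4,10.5,59.8
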