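stimulus,happiness,surprise,anger,sadness,disgust,fear
happiness,4.9,4.8,0.4,0.3,1.0,0.2
surprise,2.1,4.5,0.6,0.5,0.8,3.6
anger,0.3,1.6,8.8,2.1,6.0,1.8
sadness,1.2,2.2,2.6,20.5,10.9,12.4
disgust,0.4,1.4,15.9,10.1,18.4,5.8
fear,0.8,23.7,1.6,3.5,12.4,20.4
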