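3 0.481250 0.577344 0.271875 0.257812
0 0.437500 0.430469 0.271875 0.270313
3 0.721094 0.425000 0.267188 0.234375
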