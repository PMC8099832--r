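code	phecode	excl_low	excl_high
C91.1	204.1	204	204.99
C92.0	204.8	204	204.99
D73.9	289.5	289	289.99
J45.0	495	495	496
I51.7	416.1	415	417
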