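subject,total_days,valid_days
OAWD1,14,14
OAWD2,13,2
OAWD3,10,10
OAWD4,14,7
OAWD5,14,12
OAWD6,13,8
OAWD7,14,11
OAWD8,14,14
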