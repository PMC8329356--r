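model,deviance,aic,bic
DINO,223233.2,223299.2,223569.3
DINA,223317.0,223383.0,223653.2
GDINA,222641.9,222739.9,223141.0
ACDM,222690.4,222770.4,223097.9
LLM,222687.4,222767.4,223094.8
RRUM,222704.9,222784.9,223112.3
LCDM,222642.0,222740.0,223141.2
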