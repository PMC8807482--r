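name	class	anchor
IGHV1-7*01	V	288
IGHV1-26*01	V	288
IGHV1-82*01	V	288
IGHV2-9*01	V	288
IGHV3-6*01	V	288
IGHV5-6*01	V	288
IGHV6-3*01	V	288
IGHV14-3*01	V	288
IGHJ1*01	J	12
IGHJ2*01	J	12
IGHJ3*01	J	12
IGHJ4*01	J	12
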