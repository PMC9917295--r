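# Synthetic fixture emotion lexicon (token <TAB> emotion <TAB> intensity 0-10).
# Hand-written for examples and demonstrations; NOT a copy of any published
# lexicon.
fury	anger	6
fury	disgust	4
angry	anger	5
dread	fear	5
worried	fear	2
scared	fear	4
reliable	trust	3
minister	trust	1
gloomy	sadness	4
lonely	sadness	5
love	joy	2
love	trust	1
happy	joy	4
shock	surprise	5
wonderful	surprise	2
eager	anticipation	3
hope	anticipation	2
awful	disgust	5
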