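# Synthetic fixture sentiment lexicon (token <TAB> polarity).
# A small English word list sufficient for examples and demonstrations; it
# is NOT a copy of any published lexicon.
love	1
good	1
great	1
happy	1
wonderful	1
safe	1
hope	1
thanks	1
hate	-1
awful	-1
terrible	-1
sad	-1
angry	-1
fear	-1
lonely	-1
gloomy	-1
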