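# synthetic partial list; see README.txt
feel
bad
hurt
die
long
depressed
worse
kill
pain
cry
cried
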