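# synthetic partial list; see README.txt
want
think
see
hard
bad
care
stop
hurt
scary
die
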