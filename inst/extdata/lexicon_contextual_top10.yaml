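# Contextual crisis-support categories, scored by raw occurrence counts.
# Partial lexicons: the full expert-derived lists (137 distress terms,
# 163 suicidality terms) are not published; these are the ten most
# frequently occurring member terms of each, plus the "harm myself"
# bigram phrase.
distress:
  kind: contextual
  terms:
    - hard
    - bad
    - down
    - hurt
    - scary
    - "scar*"
    - "struggl*"
    - "alon*"
    - "depress*"
    - "stress*"
    - "wors*"
suicidality:
  kind: contextual
  terms:
    - "suicid*"
    - "stop*"
    - hurt
    - die
    - kill
    - hate
    - "pain*"
    - plan
    - "harm*"
    - "safe*"
    - harm myself
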