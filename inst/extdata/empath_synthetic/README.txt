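Synthetic partial word lists for four general-emotion lexical categories
(negative_emotion, positive_emotion, suffering, optimism).

These are NOT the full validated category vocabularies of the Empath
lexicon (which run to roughly 75-130 member terms per category and are
not redistributed here). Each file is a small synthetic stand-in seeded
from the ten most frequently occurring member terms of the corresponding
category as observed in crisis-chat text, plus a few canonical example
terms (e.g. "hopeful", "perseverance", "progress" for optimism). They are
sufficient to exercise the scoring pipeline end to end; absolute scores
computed with them are not comparable to scores from the full lists.

Format: one raw term per line; '#' starts a comment line. Terms are
normalized (lowercased, Porter-stemmed) at load time.
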