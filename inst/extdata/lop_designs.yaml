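# Between-subjects levels-of-processing recognition experiments.
# e1: concrete words in coloured fonts; e2: door-scene photographs.
e1:
  label: words
  conditions:
    colour: 27
    category: 26
  trials_per_class:
    target: 27
    category_lure: 9
    colour_lure: 9
    critical_lure: 9
e2:
  label: pictures
  conditions:
    colour: 35
    category: 36
  trials_per_class:
    target: 18
    category_lure: 6
    colour_lure: 6
    critical_lure: 9
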