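ice:
  low: 3087.0
  high: 3162.0
  initial: 3125.0
  assignment: OH stretching
protein:
  low: 1610.0
  high: 1710.0
  initial: 1660.0
  assignment: Amide I/alkyl C=C stretching
dmso:
  low: 650.0
  high: 740.0
  initial: 673.0
  assignment: Symmetric CS stretching
dna:
  low: 760.0
  high: 810.0
  initial: 785.0
  assignment: O-P-O stretching of DNA
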