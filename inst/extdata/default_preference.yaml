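name: default
objectives:
- feature: full_screen
  direction: maximize
- feature: RNASeq_LFC
  direction: maximize
- feature: clinical_ES1
  direction: maximize
- feature: clinical_ES2
  direction: maximize
- feature: clinical_ES3
  direction: maximize
- feature: lit_EGFR
  direction: maximize
- feature: lit_NSCLC
  direction: maximize
- feature: pagerank
  direction: maximize
- feature: betweenness
  direction: maximize
- feature: RNASeq_pval
  direction: maximize
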