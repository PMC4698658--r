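# Gene sets defining the EMT score:
#   score = sum(mesenchymal log2 expression) - sum(epithelial log2 expression).
# The commonly printed mesenchymal list repeats ZEB2; the shipped default
# deduplicates to 8 genes rather than guessing a replacement.
mesenchymal:
  - CDH2
  - FN1
  - SNAI1
  - SNAI2
  - VIM
  - TWIST1
  - TWIST2
  - ZEB2
epithelial:
  - CDH1
  - CLDN4
  - CLDN7
  - MUC1
  - TJP3
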