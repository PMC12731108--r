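# Consequence term -> variant class map (editable).
# Loss-of-function covers premature stop gain, start/stop loss, frameshift
# and canonical splice-site disruption. "start_gained" is deliberately not
# listed: 5'UTR start-gain annotations are not reliably protein-truncating,
# so they fall through to "other"; add the term here to include it.
lof:
  - stop_gained
  - stop_lost
  - start_lost
  - frameshift_variant
  - splice_acceptor_variant
  - splice_donor_variant
missense:
  - missense_variant
synonymous:
  - synonymous_variant
inframe_indel:
  - inframe_insertion
  - inframe_deletion
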