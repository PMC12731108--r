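# Template for the ASCO colorectal cancer risk gene panel (21 genes).
# The curated panel is not redistributed here; paste one gene symbol per
# line from the clinical guideline. See also roles_template.tsv.
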