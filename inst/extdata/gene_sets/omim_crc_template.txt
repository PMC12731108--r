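# Template for the OMIM-derived colorectal cancer risk gene set (42 genes:
# 21 oncogenes, 21 tumor suppressor genes). Paste one gene symbol per line.
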