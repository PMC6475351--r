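# Example pipeline configuration. The CPI values below are illustrative
# placeholders, not an official Uganda CPI series; supply the real index for
# production runs. Amounts are deflated to base_year prices.
cpi:
  2005: 53.1
  2009: 87.3
  2010: 100
base_year: 2010
pack_size: 20
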