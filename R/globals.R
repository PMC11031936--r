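# data.table non-standard-evaluation columns
utils::globalVariables(c(
  "q", "s", "ov", "bs", "tx_len", "label", "gene_id", "tx_id", "a", "g",
  "r", "off", "peak", "m", "w", "v", "start", "end", "value", "chrom",
  "first_in_block", "V7", "n_contributing", "mean_value"))
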