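.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "read", "chrom", "strand", "spos", "send", "ext", "clen", "rl",
  "maxext", "n_candidates", "query_start", "query_end", "ref_start",
  "ref_end", "read_id", "in_repeat", "alt", "prey_category", "label",
  "prey_chrom", "prey_break", "bait_chrom", "bait_break", "bait_strand",
  "prey_strand", "query_gap", "prey_region_label", "bait_qend",
  "prey_qstart", "prey_rstart", "prey_rend", "pos", "bin_start", "bin_end",
  "count", "bait", "J", "left_break", "right_break", "span", "mapq"
))
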