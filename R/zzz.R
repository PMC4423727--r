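.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".SD", "read_id", "pair_id", "mate", "contig", "start", "end",
  "strand", "mult", "keep", "c_a", "e_a", "c_b", "e_b", "weight", "gap",
  "excluded", "status", "detail1", "detail2", "gap_sum", "c1", "c2", "a", "b",
  "missing_edges", "conflict_count", "total_support", "hap", "frag_start",
  "insert", "contig_a", "contig_b", "n_links", "het", "depth", "id",
  "contig_x", "contig_y", "start_x", "start_y", "end_x", "end_y",
  "strand_x", "strand_y", "mult_x", "mult_y", "partner", "p_end",
  "partner_5", "partner_3", "p_end_5", "p_end_3", "fk1", "fk2", "fkey",
  "degree", "library", "n", "s", "e", "bases", "hos", "hoe"))
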