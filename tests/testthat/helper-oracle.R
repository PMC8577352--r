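# Independent brute-force rendering of the marker classification decision
# table, written directly from the rule statement and kept free of package
# internals: it takes per-cell type vectors of per-source scores and a
# precomputed cell type -> higher-level group map, and walks the table
# literally. Used only as an oracle against classify_gene().
oracle_classify <- function(scores_by_ct, group_of,
                            rule = c("mean", "two_thirds"),
                            policy = c("allow", "forbid"),
                            max_types = 2L) {
  rule <- match.arg(rule); policy <- match.arg(policy)
  is_sig <- vapply(scores_by_ct, function(v) {
    if (rule == "mean") mean(v) >= 0.5 else mean(v >= 0.5) >= 2 / 3
  }, logical(1))
  sig <- sort(names(scores_by_ct)[is_sig])
  X <- length(sig)
  if (X == 0L) return(list(label = "non_marker", cts = character(0)))
  if (X == 1L) return(list(label = "marker", cts = sig))
  grp <- sort(unique(unname(group_of[sig])))
  if (length(grp) == 1L) {
    return(list(label = "higher_level_marker", cts = grp))
  }
  if (policy == "allow" && X <= max_types) {
    return(list(label = "marker", cts = sig))
  }
  list(label = "non_marker", cts = character(0))
}
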