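## Shared fixtures, generated in code: a fixed reference realization and the
## rendered sequences of all 13 ITS types.

test_ref <- make_reference(seed = 42)

test_type_seqs <- local({
  defs <- its_type_defs()
  vapply(defs$label,
         function(l) as.character(render_type_sequence(l, test_ref)),
         character(1))
})

## independent composition lookup used by the lineage brute-force oracles:
## reads the packaged definition table directly, no typing-module helpers
type_compositions <- function(label) {
  defs <- its_type_defs()
  row <- defs[defs$label == label, ]
  lapply(stats::setNames(c(row$b122, row$b135, row$b226, row$b500),
                         c("122", "135", "226", "500")),
         function(code) iupac_bases(code))
}
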