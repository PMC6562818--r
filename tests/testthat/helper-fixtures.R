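# A hand-built overlapping-gene fixture in the style of the chicken
# MHC-B situation: a nested gene whose 3'UTR lies inside the host
# gene's intron, so one deletion must be reported under both genes.
overlap_fixture <- function() {
  host <- gene_model("BF1like", "c16", "+",
                     exons = data.frame(start = c(1000L, 9000L),
                                        end = c(1400L, 9900L)),
                     cds = data.frame(start = c(1100L, 9000L),
                                      end = c(1400L, 9397L)))
  nested <- gene_model("TAP1like", "c16", "+",
                       exons = data.frame(start = c(3000L, 4000L),
                                          end = c(3500L, 5000L)),
                       cds = data.frame(start = c(3100L, 4000L),
                                        end = c(3500L, 4597L)))
  list(host = host, nested = nested)
}
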