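# IUPAC nucleotide codes and the unambiguous bases each one stands for
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# symmetric lookup: do two IUPAC codes share at least one base?
IUPAC_COMPAT <- local({
  sets <- lapply(IUPAC_CODES, function(s) strsplit(s, "")[[1]])
  m <- outer(seq_along(sets), seq_along(sets), Vectorize(function(i, j) {
    length(intersect(sets[[i]], sets[[j]])) > 0L
  }))
  dimnames(m) <- list(names(IUPAC_CODES), names(IUPAC_CODES))
  m
})
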