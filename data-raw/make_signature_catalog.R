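# Builds the bundled *synthetic* 30-signature reference catalog
# (inst/extdata/signature_catalog_v2_synthetic.tsv).
#
# The catalog mimics the shape of the classic 30-signature SBS reference:
# 96 pyrimidine-centered trinucleotide channels x 30 column-stochastic
# signatures.  The probabilities are NOT the published reference values
# (those are not redistributable here); they are generated deterministically
# with realistic structure for the signatures the analysis cares about:
#   Sig1  - CpG C>T (spontaneous deamination / aging)
#   Sig2  - TpC C>T (APOBEC)         Sig13 - TpC C>G (APOBEC)
#   Sig4  - C>A enriched (smoking)   Sig5  - T>C enriched (clock-like)
#   Sig7  - dipyrimidine C>T (UV)    Sig10 - T[C>A]T spike (POLE)
# Remaining columns are sparse random spectra.  Rerunning this script
# reproduces the file byte-for-byte.

sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    out <- character(0)
    for (f5 in bases) for (f3 in bases) {
      out <- c(out, paste0(f5, "[", s, "]", f3))
    }
    out
  }))
}

set.seed(20240607)
ch <- sbs96_channels()
mid_sub <- sub("^.\\[(.+)\\].$", "\\1", ch)
f5 <- substr(ch, 1, 1)
f3 <- substr(ch, nchar(ch), nchar(ch))

S <- matrix(rgamma(96 * 30, shape = 0.12, rate = 1), nrow = 96,
            dimnames = list(ch, paste0("Sig", 1:30)))

# aging: C>T at NpCpG
S[mid_sub == "C>T" & f3 == "G", 1] <- S[mid_sub == "C>T" & f3 == "G", 1] +
  c(2.6, 3.4, 2.9, 3.1)
# APOBEC: C>T / C>G at TpCpA and TpCpT
S[ch %in% c("T[C>T]A", "T[C>T]T"), 2] <- S[ch %in% c("T[C>T]A", "T[C>T]T"), 2] + 3
S[ch %in% c("T[C>G]A", "T[C>G]T"), 13] <- S[ch %in% c("T[C>G]A", "T[C>G]T"), 13] + 3
# smoking: broad C>A
S[mid_sub == "C>A", 4] <- S[mid_sub == "C>A", 4] + 0.30
# clock-like: broad T>C
S[mid_sub == "T>C", 5] <- S[mid_sub == "T>C", 5] + 0.25
# UV: C>T at dipyrimidines
S[mid_sub == "C>T" & f5 %in% c("C", "T"), 7] <-
  S[mid_sub == "C>T" & f5 %in% c("C", "T"), 7] + 0.45
# POLE: T[C>A]T spike
S["T[C>A]T", 10] <- S["T[C>A]T", 10] + 4

S <- sweep(S, 2, colSums(S), "/")
# keep the file compact while keeping each column sum exactly 1
S <- round(S, 8)
for (j in seq_len(ncol(S))) {
  i <- which.max(S[, j])
  S[i, j] <- S[i, j] + (1 - sum(S[, j]))
}

out <- data.frame(context = rownames(S), S, check.names = FALSE)
write.table(out, "inst/extdata/signature_catalog_v2_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
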