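#!/usr/bin/env Rscript
# Generate a planted 7TM receptor locus and write its artifacts (genome
# FASTA, transcript GTF, canonical record, truth labels) for inspection.
# The locus mimics the opioid-receptor architecture: exon 1 = start + TM1,
# exons 2-3 = TM2..TM7, plus a PTC-bearing cassette exon between 1 and 2.

suppressPackageStartupMessages(library(sixtm))

out <- "results/locus_seed1"
loc <- gen_receptor_locus(seed = 1, out_dir = out)

message("locus written to ", out)
message("genome: ", BiocGenerics::width(loc$genome)[1], " nt; protein: ",
        nchar(loc$protein), " aa")
for (m in loc$models) {
  message(sprintf("  %-22s %d exon(s): %s", m$id, nrow(m$exons),
                  paste(m$exons$label, collapse = " + ")))
}
message("truth: ", paste(names(loc$truth$transcripts), "=",
                         vapply(loc$truth$transcripts,
                                function(t) paste(t$products, collapse = "+"),
                                ""), collapse = "; "))
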