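# Shared enumerations used across modules (collated first).

CONSEQUENCES <- c("MISSENSE", "FRAMESHIFT", "DELETION", "SPLICE_SITE", "NONSENSE")

# Suffix tokens recognised after "p.<Wt><pos>" for non-missense changes.
CONSEQUENCE_TOKENS <- c(
  fs  = "FRAMESHIFT",
  del = "DELETION",
  Ter = "NONSENSE",
  "*" = "NONSENSE"
)

SEVERITY_METHODS <- c("sift", "polyphen2", "mutation_assessor",
                      "fathmm", "condel", "cadd")

GENES <- c("SLC3A1", "SLC7A9")

# Inheritance model per gene: SLC7A9 (b(0+)AT) is autosomal dominant with
# incomplete penetrance; SLC3A1 (rBAT) is autosomal recessive.
GENE_MODEL <- c(SLC3A1 = "RECESSIVE_MIN", SLC7A9 = "DOMINANT_SUM")
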