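Package: bgcbound
Title: Integrated Boundary Delimitation of Fungal Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delimits secondary-metabolite biosynthetic gene cluster (BGC)
    boundaries by integrating three lines of evidence: a motif-independent
    comparative-genomics prediction (Smith-Waterman protein similarities,
    Karlin-Altschul E-value filtering, synteny seed detection, fixed-width
    extension and cumulative-score boundary trimming), comparative-CT
    (delta-delta-CT) differential expression against a pathway-regulator
    knockout with one-way ANOVA, and knockout metabolite-profile phenotypes.
    A rule-based consensus caller combines the three into a final cluster
    call with per-gene evidence. Seeded generators produce synthetic genome
    pairs, qPCR CT tables and metabolite profiles emulating the Monascus
    ruber M7 azaphilone pigment locus and its Talaromyces marneffei
    counterpart, so the whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
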