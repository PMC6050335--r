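# Shared fixtures: hand-labelled structures for the motif classifier and a
# seeded random-sequence generator for the folding oracle suites.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Each fixture was labelled by hand-applying the classification rules to the
# drawn structure. Coverage: all eight categories, bulges on both strands and
# both sides of the focal A, G-U closing pairs, multi-nucleotide bulges,
# focal A on the 5' and on the 3' strand of its pair.
classifier_fixtures <- function() {
  list(
    # junctional A-U, single 5' bulge (the canonical 5'B-[A-U] motif)
    list(seq = "GGCGACUUUCGAGUGCC", db = "(((.(((....))))))", a = 5L,
         cat = "fiveB_AU", side = "5prime", len = 1L),
    # 5' bulge of two nucleotides
    list(seq = "GGCCCAGCAAAAGCUGCC", db = "(((..(((....))))))", a = 6L,
         cat = "fiveB_AU", side = "5prime", len = 2L),
    # 5' bulge with a G-U closing pair below the junction
    list(seq = "GGGGACUUUCGAGUUCC", db = "(((.(((....))))))", a = 5L,
         cat = "fiveB_AU", side = "5prime", len = 1L),
    # focal A on the 3' strand, bulge 5' of A
    list(seq = "GGCUGCAAAAGCCAGCC", db = "((((((....)).))))", a = 14L,
         cat = "fiveB_AU", side = "5prime", len = 1L),
    # A-U buried mid-helix
    list(seq = "GGCACGGUUCGCCGUGCC", db = "(((((((....)))))))", a = 4L,
         cat = "duplex_AU"),
    # A-U mid-helix flanked by a G-U wobble (wobble counts as canonical)
    list(seq = "GGAUGAAAACAUUC", db = "(((((....)))))", a = 3L,
         cat = "duplex_AU"),
    # A in an apical loop
    list(seq = "GGCGCAAUAAGCGCC", db = "(((((.....)))))", a = 6L,
         cat = "unpaired"),
    # A alone in a one-sided bulge (no facing nucleotide, no imputation)
    list(seq = "GGCAGCAAAAAGCGCC", db = "(((.((.....)))))", a = 4L,
         cat = "unpaired"),
    # A in a multiloop junction (two branches; imputation rejected)
    list(seq = "GGGCAAAAAGCAGGAAAACCCACACC",
         db = "((((.....)).((....))....))", a = 12L, cat = "unpaired"),
    # A dangling in the 3' exterior tail
    list(seq = "GGGGAAAACCCCAA", db = "((((....))))..", a = 13L,
         cat = "unpaired"),
    # junctional A-U, single bulge 3' of A
    list(seq = "GGCAUGGCUUCGGCCUGCC", db = "((((.(((....)))))))", a = 4L,
         cat = "AU_threeB", side = "3prime", len = 1L),
    # 3' bulge of two nucleotides
    list(seq = "GGCAUUGGCUUCGGCCUGCC", db = "((((..(((....)))))))", a = 4L,
         cat = "AU_threeB", side = "3prime", len = 2L),
    # focal A on the 3' strand, bulge 3' of A
    list(seq = "GGCUGCAAAAAGCACGCC", db = "((((((.....))).)))", a = 14L,
         cat = "AU_threeB", side = "3prime", len = 1L),
    # bulge adjacent to the partner, interior side
    list(seq = "GGCAGCGAAAAGCAUGCC", db = "((((((.....)).))))", a = 4L,
         cat = "partner_bulge", side = "partner", len = 1L),
    # bulge adjacent to the partner, exterior side
    list(seq = "GGCAGCAAAAAGCUAGCC", db = "((((((.....))).)))", a = 4L,
         cat = "partner_bulge", side = "partner", len = 1L),
    # two-nucleotide partner-side bulge
    list(seq = "GGCAGCAAAAAGCAAUGCC", db = "((((((.....))..))))", a = 4L,
         cat = "partner_bulge", side = "partner", len = 2L),
    # focal A on the 3' strand, bulge adjacent to the 5'-strand partner
    list(seq = "GGCUAGCAAAAGCAGCC", db = "((((.((....))))))", a = 14L,
         cat = "partner_bulge", side = "partner", len = 1L),
    # imputed A-C mismatch in a 1x1 internal loop: duplex context
    list(seq = "GGCAGCGAAAGCCGCC", db = "(((.((....)).)))", a = 4L,
         cat = "duplex_AY"),
    # imputed mismatch with a G-U pair as the adjacent canonical pair
    list(seq = "GGCAGGAAAACUCGCC", db = "(((.((....)).)))", a = 4L,
         cat = "duplex_AY"),
    # imputed mismatch with an extra unpaired nucleotide 5' of A
    list(seq = "GGCAAGCAAAAGCCGCC", db = "(((..((....)).)))", a = 5L,
         cat = "fiveB_AY", side = "5prime", len = 1L),
    # same loop read from the other focal A: bulge 3' of A
    list(seq = "GGCAAGCAAAAGCCGCC", db = "(((..((....)).)))", a = 4L,
         cat = "AY_threeB", side = "3prime", len = 1L),
    # hairpin-closing A-U: loop is 3' of A, classified as a 3' bulge context
    list(seq = "GGCAUUCGUGCC", db = "((((....))))", a = 4L,
         cat = "AU_threeB", side = "3prime", len = 4L)
  )
}
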