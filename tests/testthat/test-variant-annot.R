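# Variant consequence annotation and haplotype grouping.

test_that("gene model validation enforces a clean CDS", {
  expect_error(gene_model("g", data.frame(start = 10, end = 5), 10, 5, "ACGT"),
               "end before start")
  expect_error(toy_gene(n_codons = 60, codons = list(`1` = "GTG")), "ATG")
  expect_error(toy_gene(n_codons = 60, codons = list(`60` = "GGG")), "stop")
})

test_that("coding SNVs translate to the documented substitutions", {
  g <- toy_gene(n_codons = 60, codons = list(`42` = "TGC", `52` = "TGG"))
  cds_start <- g$cds_start
  # C42Y: TGC -> TAC (G>A at codon position 2)
  v1 <- annotate_variant(g, cds_start + 41 * 3 + 1, "G", "A")
  expect_equal(v1$category, "missense")
  expect_equal(v1$protein_change, "C42Y")
  # W52S: TGG -> TCG (G>C at codon position 2)
  v2 <- annotate_variant(g, cds_start + 51 * 3 + 1, "G", "C")
  expect_equal(v2$category, "missense")
  expect_equal(v2$protein_change, "W52S")
  # synonymous: GCT -> GCC at codon 10
  v3 <- annotate_variant(g, cds_start + 9 * 3 + 2, "T", "C")
  expect_equal(v3$category, "synonymous")
  # reference mismatch names the observed base
  expect_error(annotate_variant(g, cds_start + 41 * 3 + 1, "T", "A"),
               "reference mismatch")
})

test_that("coding indels split into frameshift and in-frame by length mod 3", {
  g7 <- toy_multiexon_gene()
  ex7 <- g7$exons[7, ]
  # 5-bp deletion at the beginning of exon 7, anchored in the intron
  anchor <- ex7$start - 1
  ref <- anthomap:::ref_base(g7, anchor, 6)
  v <- annotate_variant(g7, anchor, ref, substr(ref, 1, 1))
  expect_equal(v$category, "frameshift")
  expect_match(v$protein_change, "fs$")
  # 3-bp deletion aligned to a codon boundary is in-frame
  g <- toy_gene(60)
  p <- g$cds_start + 9 * 3 - 1 # last base of codon 9 anchors codon 10
  ref3 <- anthomap:::ref_base(g, p, 4)
  v3 <- annotate_variant(g, p, ref3, substr(ref3, 1, 1))
  expect_equal(v3$category, "inframe_indel")
})

test_that("promoter, intronic and splice-adjacent positions classify correctly", {
  g <- toy_gene(60, cds_start = 1001)
  # TA insertion 411 bp upstream of the A of ATG
  p <- 1001 - 411
  ref <- anthomap:::ref_base(g, p)
  v <- annotate_variant(g, p, ref, paste0(ref, "TA"))
  expect_equal(v$category, "promoter_indel")
  expect_equal(v$promoter_offset, -411L)
  # adjacent base convention: one base 5' of the ATG is -1
  v1 <- annotate_variant(g, 1000, anthomap:::ref_base(g, 1000),
                         paste0(anthomap:::ref_base(g, 1000), "TA"))
  expect_equal(v1$promoter_offset, -1L)
  # beyond the promoter window: intergenic
  far <- annotate_variant(g, 300, anthomap:::ref_base(g, 300),
                          paste0(anthomap:::ref_base(g, 300), "TA"),
                          promoter_window = 500)
  expect_equal(far$category, "intergenic")

  g7 <- toy_multiexon_gene()
  mid_intron <- g7$exons$end[1] + 10
  vi <- annotate_variant(g7, mid_intron, "T", "A")
  expect_equal(vi$category, "intronic")
  vs <- annotate_variant(g7, g7$exons$end[1] + 1, "T", "A")
  expect_equal(vs$category, "splice_adjacent")
})

test_that("minus-strand annotation equals plus-strand annotation of the mirror", {
  # plus-strand toy gene and its reverse-complement twin
  g <- toy_gene(30, cds_start = 201, codons = list(`10` = "TGC"))
  L <- nchar(g$seq)
  rc <- anthomap:::revcomp(g$seq)
  gm <- gene_model("mirror",
                   exons = data.frame(start = L - g$cds_end + 1,
                                      end = L - g$cds_start + 1),
                   cds_start = L - g$cds_end + 1,
                   cds_end = L - g$cds_start + 1,
                   seq = rc, seq_start = 1L, strand = "-")
  pos <- g$cds_start + 9 * 3 + 1 # codon 10, position 2 (G of TGC)
  v_plus <- annotate_variant(g, pos, "G", "A")
  mirror_pos <- L - pos + 1
  v_minus <- annotate_variant(gm, mirror_pos, "C", "T")
  expect_equal(v_minus$category, v_plus$category)
  expect_equal(v_minus$protein_change, v_plus$protein_change)
  # promoter offsets agree too (upstream of a minus-strand gene is to the right)
  vp_plus <- annotate_variant(g, 191, anthomap:::ref_base(g, 191),
                              paste0(anthomap:::ref_base(g, 191), "TA"))
  vp_minus <- annotate_variant(gm, L - 191 + 1,
                               anthomap:::ref_base(gm, L - 191 + 1),
                               paste0(anthomap:::ref_base(gm, L - 191 + 1), "AC"))
  expect_equal(vp_minus$category, "promoter_indel")
  expect_equal(vp_minus$promoter_offset, vp_plus$promoter_offset)
})

test_that("protein_change handles identity, substitutions and frameshifts", {
  expect_length(protein_change("ATGTGCTAA", "ATGTGCTAA"), 0)
  expect_equal(protein_change("ATGTGCTAA", "ATGTACTAA"), "C2Y")
  # V134D in a long CDS: GTT -> GAT
  body <- rep("GCT", 140); body[1] <- "ATG"; body[134] <- "GTT"; body[140] <- "TAA"
  ref <- paste(body, collapse = "")
  alt_body <- body; alt_body[134] <- "GAT"
  expect_equal(protein_change(ref, paste(alt_body, collapse = "")), "V134D")
  # 5-base deletion at codon 5 shifts the frame from residue 5
  del <- paste0(substr(ref, 1, 12), substr(ref, 18, nchar(ref)))
  expect_match(protein_change(ref, del), "^A5fs$|^.5fs$")
  expect_error(protein_change("ATGXXX", "ATG"), "A/C/G/T")
})

test_that("translation agrees with an independent codon-table oracle", {
  skip_if_not_installed("seqinr")
  set.seed(5)
  for (i in 1:200) {
    n <- sample(2:50, 1) * 3
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    ours <- anthomap:::translate_dna(s)
    oracle <- paste(seqinr::translate(strsplit(s, "")[[1]]), collapse = "")
    oracle <- gsub("\\*", "*", oracle)
    expect_equal(ours, oracle)
  }
})

test_that("frameshift classification is exactly the mod-3 CDS-overlap predicate", {
  g <- toy_gene(60, cds_start = 1001)
  set.seed(8)
  for (i in 1:50) {
    len <- sample(1:7, 1)
    pos <- sample(seq(g$cds_start + 3, g$cds_end - 12), 1)
    ref <- anthomap:::ref_base(g, pos, len + 1)
    v <- annotate_variant(g, pos, ref, substr(ref, 1, 1))
    expected <- if (len %% 3 == 0) "inframe_indel" else "frameshift"
    expect_equal(v$category, expected)
  }
})

test_that("haplotype grouping is an order-invariant partition", {
  df <- data.frame(
    genotype = c("g1", "g2", "g3", "g4", "g5"),
    sequence = c("ACGTACGT", "acgtacgt", "ACGAACGT", "ACGTACGT", "ACRTACGT")
  )
  grp <- group_haplotypes(df)
  expect_equal(attr(grp, "n_groups"), 3)
  expect_equal(grp$group[1], grp$group[2]) # case-insensitive identity
  expect_equal(grp$group[1], grp$group[4])
  expect_true(grp$multi_homolog[5])        # IUPAC R flags multiple homologs
  expect_false(any(grp$multi_homolog[1:4]))
  # partition: every sequence in exactly one group; count is order-invariant
  expect_equal(length(grp$group), nrow(df))
  perm <- df[sample(nrow(df)), ]
  expect_equal(attr(group_haplotypes(perm), "n_groups"), 3)
  expect_error(group_haplotypes(df[0, ]), "no sequences")
  # single-site difference makes two groups
  two <- group_haplotypes(data.frame(genotype = c("a", "b"),
                                     sequence = c("AAAA", "AATA")))
  expect_equal(attr(two, "n_groups"), 2)
})
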